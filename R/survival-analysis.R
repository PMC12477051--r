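#' Kaplan-Meier estimate for one or more groups
#'
#' Product-limit survival curves, computed with [survival::survfit()].
#'
#' @param table Data frame with columns `time` (>= 0), `event` (1 = event,
#'   0 = censored) and optionally `group`.
#' @param group Optional group level to restrict to.
#' @return Data frame `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`: one row per distinct observed time within each group, with the
#'   product-limit estimate after that time.
#' @export
km_estimate <- function(table, group = NULL) {
  check_survival_table(table)
  if (!is.null(group)) {
    if (!"group" %in% names(table)) stop("no group column to restrict on")
    table <- table[table$group == group, , drop = FALSE]
    if (!nrow(table)) stop("group ", group, " is empty")
  }
  has_groups <- "group" %in% names(table) && length(unique(table$group)) > 1
  fit <- if (has_groups) {
    survival::survfit(survival::Surv(time, event) ~ group, data = table)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  }
  s <- summary(fit, censored = TRUE)
  grp <- if (has_groups) sub("^group=", "", as.character(s$strata))
         else rep(if ("group" %in% names(table))
                    as.character(table$group[1]) else "all",
                  length(s$time))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor, surv = s$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared statistic on 1 degree of freedom, via
#' [survival::survdiff()].
#'
#' @param table Data frame with columns `time`, `event` and a two-level
#'   `group`.
#' @return List with `statistic` and `p`.
#' @export
logrank_test <- function(table) {
  check_survival_table(table)
  if (!"group" %in% names(table)) stop("group column required")
  groups <- unique(table$group[!is.na(table$group)])
  if (length(groups) != 2) {
    stop("log-rank test requires exactly two non-empty groups (found ",
         length(groups), ")")
  }
  if (sum(table$event) < 1) stop("at least one event required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = table)
  list(statistic = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

check_survival_table <- function(table) {
  req <- c("time", "event")
  if (!all(req %in% names(table))) stop("need columns time and event")
  if (any(table$time < 0)) stop("negative survival time")
  if (!all(table$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(table)
}

#' Join clinical follow-up to score groups and write KM/log-rank outputs
#'
#' @param clinical Data frame `sample`, `time`, `event`.
#' @param scores A `score_result` from [compute_scores()] (or any data frame
#'   with `sample` and `group`).
#' @return List with `table` (joined survival table), `km` (per-group KM
#'   estimate) and `logrank`.
#' @export
survival_by_score <- function(clinical, scores) {
  merged <- merge(clinical[, c("sample", "time", "event")],
                  scores[, c("sample", "group")], by = "sample")
  if (!nrow(merged)) stop("no samples shared between clinical and scores")
  list(table = merged, km = km_estimate(merged), logrank = logrank_test(merged))
}
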