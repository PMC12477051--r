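#' Dichotomise one gene's expression into top/bottom halves
#'
#' Samples in the top 50% of expression for the gene receive +1, the bottom
#' 50% receive -1.  The split is rank-based: samples are ordered by value and
#' the lowest `floor(n/2)` receive -1.  Ties are broken by stable sample
#' order; with `tie_policy = "low"` the earlier of two tied samples is ranked
#' lower (and so is more likely to fall in the bottom half), with `"high"`
#' the later one is.
#'
#' @param values Numeric vector of per-sample expression for a single gene.
#' @param tie_policy `"low"` (default) or `"high"`; see Details.
#' @return Integer vector of +1/-1 indicators, same length and names as
#'   `values`.
#' @examples
#' dichotomize_gene(c(1, 2, 3, 4))  # -1 -1 +1 +1
#' @export
dichotomize_gene <- function(values, tie_policy = c("low", "high")) {
  tie_policy <- match.arg(tie_policy)
  n <- length(values)
  if (n < 2) stop("need at least 2 samples to dichotomise")
  if (anyNA(values)) stop("missing expression values")
  if (max(values) == min(values)) {
    stop("constant expression vector: all ranks tied; ",
         "no top/bottom split exists (see tie_policy for boundary ties)")
  }
  tiebreak <- if (tie_policy == "low") seq_len(n) else rev(seq_len(n))
  ord <- order(values, tiebreak)
  ind <- rep.int(1L, n)
  ind[ord[seq_len(n %/% 2)]] <- -1L
  names(ind) <- names(values)
  ind
}

#' Compute the ALDH1A3-network score for every sample
#'
#' For each network gene the cohort is split into top/bottom expression
#' halves (+1/-1, see [dichotomize_gene()]); the per-sample score is the sum
#' of the eight indicators weighted by the connectivity-derived coefficients,
#' so scores lie in \[-1, +1\].  Samples are then split into High/Low groups
#' at the median score ([assign_groups()]).
#'
#' Indicators are computed relative to the analysed sample set, so the score
#' is cohort-relative and invariant under any strictly increasing per-gene
#' transform of expression.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns.
#' @param coefficients A `coefficient_vector` from [derive_coefficients()];
#'   defaults to the eight-gene network coefficients.
#' @param tie_policy Passed to [dichotomize_gene()].
#' @param median_policy Passed to [assign_groups()].
#' @return A `score_result`: data frame with one row per sample, +1/-1
#'   indicator columns named `ind_<gene>`, `score`, and `group`
#'   (`"High"`/`"Low"`).
#' @examples
#' expr <- matrix(rnorm(8 * 20), 8, 20,
#'                dimnames = list(gene_network()$genes, paste0("s", 1:20)))
#' head(compute_scores(expr))
#' @export
compute_scores <- function(expr,
                           coefficients = derive_coefficients(gene_network()),
                           tie_policy = "low", median_policy = "low") {
  stopifnot(inherits(coefficients, "coefficient_vector"))
  expr <- as.matrix(expr)
  genes <- names(coefficients$coefficient)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("expression matrix lacks network gene(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(colnames(expr))) stop("duplicate sample identifiers")
  ind <- vapply(genes,
                function(g) dichotomize_gene(expr[g, ], tie_policy),
                integer(ncol(expr)))
  score <- drop(ind %*% coefficients$coefficient[genes])
  res <- data.frame(sample = colnames(expr), ind,
                    row.names = NULL, check.names = FALSE)
  names(res)[seq_along(genes) + 1L] <- paste0("ind_", genes)
  res$score <- unname(score)
  res$group <- assign_groups(res$score, median_policy)
  class(res) <- c("score_result", class(res))
  res
}

#' Split samples into High/Low groups at the median score
#'
#' Scores strictly above the cohort median are High, strictly below are Low;
#' scores exactly at the median go to Low under the default policy
#' (conservative toward the high-risk call) or High with
#' `median_policy = "high"`.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param median_policy `"low"` (default) or `"high"`: side that receives
#'   samples tied with the median.
#' @return Factor with levels `Low`, `High`.
#' @export
assign_groups <- function(scores, median_policy = c("low", "high")) {
  median_policy <- match.arg(median_policy)
  if (!length(scores)) stop("no scores supplied")
  m <- median(scores)
  if (all(scores == m)) {
    warning("all scores equal; every sample assigned to the '",
            if (median_policy == "low") "Low" else "High", "' group")
  }
  high <- if (median_policy == "low") scores > m else scores >= m
  factor(ifelse(high, "High", "Low"), levels = c("Low", "High"))
}

#' Write a score table as TSV
#'
#' @param scores A `score_result` from [compute_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
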