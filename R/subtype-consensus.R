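#' Define a subtype classification scheme
#'
#' A scheme is a named collection of disjoint per-subtype signature gene
#' lists, the number of clusters `k` it implies, and which subtype counts as
#' unfavorable (aggressive).  Published PDAC schemes use k = 2 (basal-like
#' vs classical), k = 3 (quasi-mesenchymal / classical / exocrine-like) and
#' k = 4 (squamous / progenitor / ADEX / immunogenic); their gene lists are
#' supplied by the user as GMT, while [default_schemes()] ships synthetic
#' stand-ins matched to [simulate_cohort()].
#'
#' @param name Scheme identifier.
#' @param genes Named list of per-subtype signature gene vectors (disjoint,
#'   non-empty).
#' @param aggressive_label Name of the unfavorable subtype; must be one of
#'   `names(genes)`.
#' @return A `signature_scheme` list with `name`, `k`, `subtypes`, `genes`,
#'   `aggressive_label`.
#' @export
signature_scheme <- function(name, genes, aggressive_label) {
  if (length(genes) < 2) stop("scheme needs k >= 2 subtypes")
  if (is.null(names(genes)) || any(!nzchar(names(genes)))) {
    stop("per-subtype gene lists must be named")
  }
  if (any(lengths(genes) == 0)) stop("empty signature gene list")
  all_genes <- unlist(genes)
  if (anyDuplicated(all_genes)) {
    stop("signature gene lists must be disjoint within a scheme")
  }
  if (!aggressive_label %in% names(genes)) {
    stop("aggressive_label must name one of the subtypes")
  }
  structure(list(name = name, k = length(genes), subtypes = names(genes),
                 genes = genes, aggressive_label = aggressive_label),
            class = "signature_scheme")
}

#' Synthetic default classification schemes
#'
#' Three schemes shaped like the published PDAC systems (k = 2, 3, 4 with
#' aggressive subtypes basal-like, quasi-mesenchymal and squamous) but with
#' synthetic signature genes matching the blocks planted by
#' [simulate_cohort()].  The published Moffitt/Collisson/Bailey gene lists
#' are not redistributed; load them from GMT with [read_schemes_gmt()] for
#' real cohorts.
#'
#' @param genes_per_subtype Signature genes per subtype for the k = 2/3/4
#'   schemes.
#' @return Named list of [signature_scheme()] objects.
#' @export
default_schemes <- function(genes_per_subtype = c(24, 20, 25)) {
  blocks <- function(prefix, subtypes, m) {
    setNames(lapply(seq_along(subtypes), function(i) {
      sprintf("%s_%s_%02d", prefix, gsub("[^A-Za-z]", "", subtypes[i]),
              seq_len(m))
    }), subtypes)
  }
  list(
    scheme_k2 = signature_scheme(
      "scheme_k2",
      blocks("K2", c("basal-like", "classical"), genes_per_subtype[1]),
      "basal-like"),
    scheme_k3 = signature_scheme(
      "scheme_k3",
      blocks("K3", c("quasi-mesenchymal", "classical", "exocrine-like"),
             genes_per_subtype[2]),
      "quasi-mesenchymal"),
    scheme_k4 = signature_scheme(
      "scheme_k4",
      blocks("K4", c("squamous", "progenitor", "ADEX", "immunogenic"),
             genes_per_subtype[3]),
      "squamous")
  )
}

#' Classify samples into k subtypes by NMF on signature genes
#'
#' Restricts the expression matrix to the scheme's signature genes (shifting
#' to non-negative if needed), fits rank-k NMF ([nmf_fit()]), assigns each
#' sample to the factor with the largest coefficient, then names the factors
#' after subtypes via [map_clusters_to_subtypes()].
#'
#' @param expr Numeric matrix, genes x samples.
#' @param scheme A [signature_scheme()].
#' @param seed Integer seed for the NMF restarts.
#' @param n_restarts Number of NMF restarts (default 20).
#' @return Factor of subtype labels per sample (levels = scheme subtypes),
#'   with attributes `cluster` (raw factor index per sample) and `matched`
#'   (number of signature genes found in `expr`).
#' @export
nmf_classify <- function(expr, scheme, seed = 1L, n_restarts = 20) {
  stopifnot(inherits(scheme, "signature_scheme"))
  expr <- as.matrix(expr)
  sig <- unlist(scheme$genes)
  matched <- intersect(sig, rownames(expr))
  if (length(matched) < 10) {
    stop("insufficient signature-gene overlap for scheme ", scheme$name,
         ": only ", length(matched), " of ", length(sig),
         " genes with a unique match in the data (need >= 10)")
  }
  x <- expr[matched, , drop = FALSE]
  if (min(x) < 0) x <- x - min(x)
  fit <- nmf_fit(x, k = scheme$k, n_restarts = n_restarts, seed = seed)
  cluster <- apply(fit$H, 2, which.max)
  mapping <- map_clusters_to_subtypes(
    centroids = vapply(seq_len(scheme$k), function(cl) {
      if (any(cluster == cl)) rowMeans(x[, cluster == cl, drop = FALSE])
      else fit$W[, cl]
    }, numeric(nrow(x))),
    scheme = scheme, genes = matched)
  out <- factor(mapping[cluster], levels = scheme$subtypes)
  names(out) <- colnames(expr)
  attr(out, "cluster") <- cluster
  attr(out, "matched") <- length(matched)
  out
}

#' Map NMF clusters to named subtypes by centroid correlation
#'
#' Correlates each cluster centroid (over the matched signature genes) with
#' each subtype's signature indicator vector (1 for that subtype's genes, 0
#' otherwise) and picks the one-to-one assignment maximising the total
#' correlation, by exhaustive search over the k! permutations (k <= 8).
#'
#' @param centroids Numeric matrix, matched signature genes x k clusters.
#' @param scheme A [signature_scheme()].
#' @param genes Character vector of the matched genes (rows of `centroids`).
#' @return Character vector of length k: subtype label per cluster.
#' @export
map_clusters_to_subtypes <- function(centroids, scheme, genes) {
  stopifnot(inherits(scheme, "signature_scheme"))
  centroids <- as.matrix(centroids)
  k <- scheme$k
  if (ncol(centroids) != k) stop("need one centroid per subtype")
  if (k > 8) stop("exhaustive assignment supported for k <= 8")
  if (any(apply(centroids, 2, sd) == 0)) {
    stop("degenerate (constant) cluster centroid")
  }
  indicator <- vapply(scheme$subtypes,
                      function(st) as.numeric(genes %in% scheme$genes[[st]]),
                      numeric(length(genes)))
  corr <- suppressWarnings(cor(centroids, indicator))
  corr[is.na(corr)] <- 0
  perms <- permutations_of(k)
  totals <- vapply(seq_len(nrow(perms)), function(i) {
    sum(corr[cbind(seq_len(k), perms[i, ])])
  }, numeric(1))
  scheme$subtypes[perms[which.max(totals), ]]
}

# All permutations of 1..n as rows (n small).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Consensus-aggressive call across classification schemes
#'
#' A sample is consensus-aggressive when at least `threshold` schemes label
#' it with their unfavorable subtype.
#'
#' @param calls Data frame or named list: one column/element per scheme with
#'   per-sample subtype labels.
#' @param schemes The [signature_scheme()] objects matching `calls` (used
#'   for the aggressive label of each scheme); defaults to
#'   [default_schemes()] entries named in `calls`.
#' @param threshold Minimum number of unfavorable calls (default 3).
#' @return List with `aggressive_count` (integer per sample) and
#'   `consensus_aggressive` (logical per sample).
#' @export
consensus_aggressive <- function(calls, schemes = default_schemes(),
                                 threshold = 3) {
  calls <- as.data.frame(calls)
  schemes <- schemes[names(calls)]
  if (anyNA(names(schemes))) stop("scheme definitions missing for some calls")
  if (threshold > ncol(calls)) {
    stop("threshold (", threshold, ") exceeds number of schemes (",
         ncol(calls), ")")
  }
  unfav <- vapply(names(calls), function(nm) {
    as.character(calls[[nm]]) == schemes[[nm]]$aggressive_label
  }, logical(nrow(calls)))
  if (!is.matrix(unfav)) unfav <- t(as.matrix(unfav))
  count <- rowSums(unfav)
  list(aggressive_count = as.integer(count),
       consensus_aggressive = count >= threshold)
}

#' Association between score groups and consensus-aggressive status
#'
#' Builds the 2x2 contingency table of High/Low score group versus
#' consensus-aggressive flag and tests independence with the chi-squared
#' test (no continuity correction), falling back to Fisher's exact test when
#' any expected cell is below 5.  Also compares the continuous scores
#' between aggressive and non-aggressive samples with Welch's t-test.
#'
#' @param groups Factor `Low`/`High` per sample (from [assign_groups()]).
#' @param flags Logical consensus-aggressive per sample.
#' @param scores Numeric scores per sample.
#' @return List: `table` (2x2), `test` (`"chisq"` or `"fisher"`),
#'   `statistic`, `p`, `t_statistic`, `t_p`.
#' @export
association_tests <- function(groups, flags, scores) {
  groups <- factor(groups, levels = c("Low", "High"))
  flags <- as.logical(flags)
  if (length(unique(groups[!is.na(groups)])) < 2 ||
      length(unique(flags)) < 2) {
    stop("degenerate margin: both High/Low and aggressive/other required")
  }
  tab <- table(group = groups, aggressive = flags)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    ct <- list(test = "fisher", statistic = unname(ft$estimate),
               p = ft$p.value)
  } else {
    cs <- chisq.test(tab, correct = FALSE)
    ct <- list(test = "chisq", statistic = unname(cs$statistic),
               p = cs$p.value)
  }
  tt <- t.test(scores[flags], scores[!flags])
  c(list(table = tab), ct,
    list(t_statistic = unname(tt$statistic), t_p = tt$p.value))
}
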