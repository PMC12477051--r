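#' Split samples by anchor-gene expression with 1-D k-means (k = 2)
#'
#' Clusters samples on the expression of a single anchor gene (default
#' ALDH1A3) with k-means, k = 2, 10 restarts; the cluster with the higher
#' centroid is labelled `positive`.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param anchor_gene Gene symbol used for the split.
#' @param seed Integer seed for the k-means restarts.
#' @return Factor of `negative`/`positive` per sample, named by sample.
#' @export
kmeans_anchor_split <- function(expr, anchor_gene = "ALDH1A3", seed = 1L) {
  expr <- as.matrix(expr)
  if (!anchor_gene %in% rownames(expr)) {
    stop("anchor gene ", anchor_gene, " absent from expression matrix")
  }
  if (ncol(expr) < 4) stop("need at least 4 samples")
  v <- expr[anchor_gene, ]
  if (max(v) == min(v)) stop("anchor gene expression is constant")
  km <- withr::with_seed(as.integer(seed),
                         kmeans(matrix(v, ncol = 1), centers = 2, nstart = 10))
  pos_cluster <- which.max(km$centers)
  out <- factor(ifelse(km$cluster == pos_cluster, "positive", "negative"),
                levels = c("negative", "positive"))
  names(out) <- colnames(expr)
  out
}

#' Differential genes between two sample groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test with Benjamini-Hochberg
#' correction; the effect size is the difference of group means on the
#' (assumed log2) input scale.  A gene is called differential when its
#' adjusted p-value falls below `alpha` and its absolute log2 difference
#' reaches `lfc_min`.
#'
#' @param expr Numeric matrix, genes x samples (log2 scale).
#' @param labels Two-level factor (or coercible) over samples; the second
#'   level is treated as the "positive" group and log2 differences are
#'   positive-group minus negative-group.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param lfc_min Minimum absolute log2 mean difference (default 1).
#' @return Data frame `gene`, `log2_diff`, `p`, `padj`, `direction`
#'   (`up`/`down`, relative to the positive group) containing only the
#'   differential genes, ordered by `padj`.
#' @export
differential_genes <- function(expr, labels, alpha = 0.05, lfc_min = 1) {
  expr <- as.matrix(expr)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (length(labels) != ncol(expr)) stop("one label per sample required")
  a <- labels == levels(labels)[1]
  b <- labels == levels(labels)[2]
  if (sum(a) < 3 || sum(b) < 3) {
    stop("each group needs at least 3 samples (have ", sum(a), " and ",
         sum(b), ")")
  }
  p <- apply(expr, 1, function(x) {
    suppressWarnings(wilcox.test(x[b], x[a], exact = FALSE)$p.value)
  })
  lfc <- rowMeans(expr[, b, drop = FALSE]) - rowMeans(expr[, a, drop = FALSE])
  padj <- p.adjust(p, method = "BH")
  keep <- !is.na(padj) & padj < alpha & abs(lfc) >= lfc_min
  out <- data.frame(gene = rownames(expr)[keep], log2_diff = unname(lfc[keep]),
                    p = unname(p[keep]), padj = unname(padj[keep]),
                    direction = ifelse(lfc[keep] > 0, "up", "down"))
  out[order(out$padj, out$gene), , drop = FALSE]
}

#' Intersect marker sets across datasets with full Venn accounting
#'
#' @param sets Named list (>= 2) of character vectors of gene identifiers.
#' @return List with `consensus` (genes present in every set, sorted),
#'   `regions` (data frame of every non-empty Venn region: membership
#'   pattern, count, genes) and `membership` (logical matrix gene x set).
#' @export
intersect_marker_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (!is.matrix(membership)) membership <- t(as.matrix(membership))
  rownames(membership) <- universe
  pattern <- apply(membership, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  regions <- do.call(rbind, lapply(split(universe, pattern), function(g) {
    data.frame(region = pattern[g[1]], count = length(g),
               genes = paste(sort(g), collapse = ","))
  }))
  rownames(regions) <- NULL
  list(consensus = universe[rowSums(membership) == length(sets)],
       regions = regions[order(-regions$count, regions$region), ],
       membership = membership)
}

#' Spearman correlation matrix with BH-adjusted p-values
#'
#' @param expr Numeric matrix, genes x samples.
#' @param genes Genes to correlate (default: the eight network genes).
#' @return List with `rho` (symmetric Spearman correlation matrix, unit
#'   diagonal) and `padj` (BH-adjusted two-sided p-values over the
#'   off-diagonal pairs; diagonal `NA`).
#' @export
correlation_matrix <- function(expr, genes = NETWORK_GENES) {
  expr <- as.matrix(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("expression matrix lacks gene(s): ", paste(missing, collapse = ", "))
  }
  if (ncol(expr) < 5) stop("need at least 5 samples")
  x <- t(expr[genes, , drop = FALSE])
  rho <- cor(x, method = "spearman")
  k <- length(genes)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pv <- suppressWarnings(
        cor.test(x[, i], x[, j], method = "spearman", exact = FALSE)$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  }
  up <- upper.tri(p)
  padj <- p
  padj[up] <- p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(rho = rho, padj = padj)
}
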