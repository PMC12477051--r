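# Shared fixtures and small independent oracles used across test files.

# Expression matrix containing the eight network genes plus background rows.
toy_network_expr <- function(n_samples = 20, seed = 42) {
  withr::with_seed(seed, {
    genes <- c(gene_network()$genes, sprintf("BG%02d", 1:4))
    m <- matrix(rnorm(length(genes) * n_samples, mean = 6), length(genes),
                n_samples, dimnames = list(genes,
                                           sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

# Sort-based oracle for the top/bottom-half indicator: stable ordering by
# (value, index) and the lowest floor(n/2) entries marked -1.
oracle_dichotomize <- function(values) {
  n <- length(values)
  ord <- order(values, seq_len(n))
  out <- rep(1L, n)
  out[ord[seq_len(n %/% 2)]] <- -1L
  out
}

# Adjusted Rand index between two label vectors (closed-form from the
# pair-counting contingency table).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  exp_idx <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / choose(n, 2)
  max_idx <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  (idx - exp_idx) / (max_idx - exp_idx)
}

# Brute-force nearest-TSS assignment with strand-aware signed distance.
oracle_nearest_tss <- function(peaks, ann) {
  mid <- floor((peaks$start + peaks$end) / 2)
  t(vapply(seq_len(nrow(peaks)), function(i) {
    on_chr <- which(ann$chrom == peaks$chrom[i])
    d <- abs(ann$tss[on_chr] - mid[i])
    j <- on_chr[which.min(d)]
    signed <- (mid[i] - ann$tss[j]) * if (ann$strand[j] == "+") 1 else -1
    c(gene = j, distance = signed)
  }, c(gene = 0, distance = 0)))
}
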