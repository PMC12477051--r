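test_that("scheme construction enforces disjoint non-empty signatures", {
  expect_error(signature_scheme("s", list(a = "g1"), "a"), "k >= 2")
  expect_error(signature_scheme("s", list(a = "g1", b = "g1"), "a"),
               "disjoint")
  expect_error(signature_scheme("s", list(a = "g1", b = character(0)), "a"),
               "empty")
  expect_error(signature_scheme("s", list(a = "g1", b = "g2"), "c"),
               "aggressive_label")
  sc <- signature_scheme("s", list(a = c("g1", "g2"), b = "g3"), "a")
  expect_equal(sc$k, 2)
})

test_that("NMF recovers planted blocks and rejects thin gene overlap", {
  withr::with_seed(23, {
    # block-diagonal planted matrix, k = 2
    sc <- signature_scheme("toy",
                           list(a = sprintf("ga%02d", 1:15),
                                b = sprintf("gb%02d", 1:15)), "a")
    n <- 60
    truth <- rep(c("a", "b"), each = n / 2)
    x <- matrix(abs(rnorm(30 * n, mean = 1)), 30, n,
                dimnames = list(unlist(sc$genes), sprintf("s%02d", 1:n)))
    x[sc$genes$a, truth == "a"] <- x[sc$genes$a, truth == "a"] + 4
    x[sc$genes$b, truth == "b"] <- x[sc$genes$b, truth == "b"] + 4
    call <- nmf_classify(x, sc, seed = 23, n_restarts = 10)
    expect_gte(adjusted_rand_index(as.character(call), truth), 0.9)
    # duplicated samples co-cluster with their originals
    x2 <- cbind(x, x[, 1:5])
    colnames(x2) <- make.unique(colnames(x2))
    call2 <- nmf_classify(x2, sc, seed = 23, n_restarts = 10)
    expect_equal(as.character(call2[61:65]), as.character(call2[1:5]))
    # insufficient overlap reports the matched count
    expect_error(nmf_classify(x[1:5, ], sc, seed = 1),
                 "only 5 of 30 genes")
  })
})

test_that("NMF rank below 2 is rejected", {
  x <- matrix(runif(20), 4, 5)
  expect_error(nmf_fit(x, k = 1), "k must be >= 2")
  expect_error(nmf_fit(-x, k = 2), "non-negative")
})

test_that("cluster labelling matches brute-force permutation search", {
  sc <- signature_scheme("toy", list(a = c("g1", "g2"), b = c("g3", "g4"),
                                     c = c("g5", "g6")), "a")
  genes <- sprintf("g%d", 1:6)
  indicator <- vapply(sc$genes, function(g) as.numeric(genes %in% g),
                      numeric(6))
  # centroids equal to the indicators: identity mapping
  expect_equal(map_clusters_to_subtypes(indicator, sc, genes),
               c("a", "b", "c"))
  # permuted centroids: permutation recovered
  expect_equal(map_clusters_to_subtypes(indicator[, c(3, 1, 2)], sc, genes),
               c("c", "a", "b"))
  # random centroids: best of the 6 permutations, enumerated independently
  withr::with_seed(31, {
    for (rep in 1:10) {
      cent <- matrix(runif(18), 6, 3)
      got <- map_clusters_to_subtypes(cent, sc, genes)
      corr <- cor(cent, indicator)
      perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1))
      totals <- vapply(perms, function(p) sum(corr[cbind(1:3, p)]),
                       numeric(1))
      best <- sc$subtypes[perms[[which.max(totals)]]]
      expect_equal(got, best)
    }
  })
  expect_error(map_clusters_to_subtypes(matrix(1, 6, 3), sc, genes),
               "degenerate")
})

test_that("consensus-aggressive counting matches the exhaustive truth table", {
  schemes <- default_schemes()
  aggr <- vapply(schemes, `[[`, "", "aggressive_label")
  other <- vapply(schemes, function(s) setdiff(s$subtypes,
                                               s$aggressive_label)[1], "")
  # all 2^3 patterns of unfavorable calls across the three schemes
  for (mask in 0:7) {
    bits <- as.logical(bitwAnd(mask, c(1, 2, 4)))
    calls <- as.data.frame(as.list(ifelse(bits, aggr, other)))
    names(calls) <- names(schemes)
    cons <- consensus_aggressive(calls, schemes, threshold = 3)
    expect_equal(cons$aggressive_count, sum(bits))
    expect_equal(cons$consensus_aggressive, sum(bits) >= 3)
  }
  expect_error(consensus_aggressive(
    as.data.frame(as.list(aggr)) |> setNames(names(schemes)),
    schemes, threshold = 4), "exceeds")
})

test_that("association uses chi-squared or Fisher as the table demands", {
  # perfectly associated table: overwhelming evidence
  groups <- factor(rep(c("High", "Low"), each = 10), levels = c("Low", "High"))
  flags <- rep(c(TRUE, FALSE), each = 10)
  scores <- c(rnorm(10, 1), rnorm(10, -1))
  at <- association_tests(groups, flags, scores)
  expect_lt(at$p, 1e-4)
  # small table triggers the exact test; p matches hypergeometric enumeration
  g2 <- factor(c(rep("High", 4), rep("Low", 4)), levels = c("Low", "High"))
  f2 <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  at2 <- association_tests(g2, f2, rnorm(8))
  expect_equal(at2$test, "fisher")
  dens <- dhyper(0:4, 4, 4, 4)
  p_exact <- sum(dens[dens <= dens[4] + 1e-12])  # observed x = 3
  expect_equal(at2$p, p_exact)
  expect_error(association_tests(factor(rep("High", 8),
                                        levels = c("Low", "High")),
                                 f2, rnorm(8)),
               "degenerate")
})

test_that("chi-squared p-values are uniform under independent margins", {
  withr::with_seed(41, {
    ps <- replicate(400, {
      g <- factor(sample(c("Low", "High"), 80, replace = TRUE),
                  levels = c("Low", "High"))
      f <- sample(c(TRUE, FALSE), 80, replace = TRUE)
      tab <- table(g, f)
      if (any(outer(rowSums(tab), colSums(tab)) / 80 < 5)) NA_real_
      else chisq.test(tab, correct = FALSE)$p.value
    })
    ps <- ps[!is.na(ps)]
    # ties are expected: 2x2 tables have discrete p-value support
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  })
})

test_that("end-to-end consensus agrees with planted truth and score groups", {
  sim <- simulate_cohort(cohort_spec(n_samples = 120, module_effect = 1.5,
                                     seed = 44))
  schemes <- default_schemes()
  calls <- as.data.frame(lapply(schemes, function(sc) {
    as.character(nmf_classify(sim$expression, sc, seed = 44, n_restarts = 8))
  }))
  names(calls) <- names(schemes)
  cons <- consensus_aggressive(calls, schemes, threshold = 3)
  expect_gte(mean(cons$consensus_aggressive == sim$truth$basal), 0.9)
  sc <- compute_scores(sim$expression)
  at <- association_tests(sc$group, cons$consensus_aggressive, sc$score)
  expect_lt(at$p, 0.01)
})
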