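# toy two-gene genome used across several blocks
toy_ann <- data.frame(
  gene = c("GA", "GB"),
  chrom = c("chr1", "chr1"),
  tss = c(10000L, 50000L),
  strand = c("+", "-"),
  body_start = c(10000L, 30000L),
  body_end = c(20000L, 50001L))

test_that("peak annotation assigns nearest TSS with strand-aware distance", {
  peaks <- data.frame(
    chrom = "chr1",
    start = c(9950L, 10990L, 45000L, 52000L),
    end = c(10050L, 11010L, 45100L, 52100L))
  ap <- annotate_peaks(peaks, toy_ann, promoter_window = 2000)
  # midpoint exactly at the TSS: distance 0, promoter
  expect_equal(ap$gene[1], "GA")
  expect_equal(ap$distance[1], 0)
  expect_equal(as.character(ap$feature[1]), "promoter")
  # downstream of GA on + strand: positive distance
  expect_equal(ap$distance[2], 1000)
  # inside GB's body, upstream-of-TSS side handled by - strand sign
  expect_equal(ap$gene[3], "GB")
  expect_equal(ap$distance[3], 50000 - 45050)
  expect_equal(as.character(ap$feature[3]), "intronic")
  # beyond GB's TSS on - strand: negative (upstream) distance
  expect_equal(ap$distance[4], -(52050 - 50000))
})

test_that("distal peaks and unannotated chromosomes are classified safely", {
  peaks <- data.frame(chrom = c("chr1", "chrX"),
                      start = c(200000L, 5L), end = c(200100L, 105L))
  expect_warning(ap <- annotate_peaks(peaks, toy_ann), "unassigned")
  expect_equal(as.character(ap$feature), c("distal_intergenic", "unassigned"))
  expect_true(is.na(ap$gene[2]))
  expect_error(annotate_peaks(peaks[0, ], toy_ann), "empty")
})

test_that("exon annotation promotes gene-body peaks to exonic", {
  exons <- data.frame(gene = "GB", chrom = "chr1",
                      start = 44990L, end = 45150L)
  peaks <- data.frame(chrom = "chr1", start = 45000L, end = 45100L)
  ap <- annotate_peaks(peaks, toy_ann, exons = exons)
  expect_equal(as.character(ap$feature), "exonic")
})

test_that("random peaks match the brute-force nearest-TSS oracle", {
  withr::with_seed(61, {
    ps <- simulate_peaks(peak_sim_spec(n_chromosomes = 2, chrom_length = 1e6,
                                       n_genes = 20, n_peaks = 40,
                                       n_de_genes = 5, seed = 61))
    ap <- annotate_peaks(ps$peaks, ps$annotation)
    oracle <- oracle_nearest_tss(ps$peaks, ps$annotation)
    # the assignment distance is a true minimum over all genes
    expect_equal(abs(ap$distance), abs(oracle[, "distance"]))
    expect_equal(ap$distance, oracle[, "distance"])
    expect_equal(ap$gene, ps$annotation$gene[oracle[, "gene"]])
  })
})

test_that("TSS distance profile summarises medians and log10 bins", {
  ap <- data.frame(distance = rep(1000, 5))
  pr <- tss_distance_profile(ap)
  expect_equal(pr$median, 1000)
  expect_equal(sum(pr$histogram$count > 0), 1)
  pr2 <- tss_distance_profile(data.frame(distance = c(10, 1000, 100000)))
  expect_equal(pr2$median, 1000)
  expect_equal(sum(pr2$histogram$count), 3)
  # log-uniform distances: empirical median near the generative median
  withr::with_seed(62, {
    d <- 10^runif(20000, 2, 6)  # generative median 10^4
    pr3 <- tss_distance_profile(data.frame(distance = d))
    expect_lt(abs(pr3$median - 1e4) / 1e4, 0.1)
  })
  expect_error(tss_distance_profile(data.frame(distance = NA_real_)),
               "no assigned peaks")
})

test_that("feature distribution test agrees with the direct chi-squared formula", {
  a <- c(promoter = 30, exonic = 10, intronic = 40, distal_intergenic = 20)
  # identical proportions: statistic 0
  same <- feature_distribution_test(a, a * 3)
  expect_equal(same$statistic, 0)
  # disjoint categories: overwhelming evidence
  b <- c(promoter = 0, exonic = 0, intronic = 0, distal_intergenic = 100)
  a2 <- c(promoter = 100, exonic = 0, intronic = 0, distal_intergenic = 0)
  expect_warning(dis <- feature_distribution_test(a2, b), "empty feature")
  expect_lt(dis$p, 1e-6)
  # random 2 x 4 table equals the hand Sum (O-E)^2 / E computation
  withr::with_seed(63, {
    x <- setNames(rpois(4, 40) + 1, names(a))
    y <- setNames(rpois(4, 60) + 1, names(a))
    ft <- feature_distribution_test(x, y)
    tab <- rbind(x, y)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(ft$statistic, sum((tab - expected)^2 / expected))
    expect_equal(ft$df, 3)
  })
})

test_that("overlap fraction counts memberships exactly", {
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b", "c"))$fraction, 1)
  expect_error(overlap_fraction(character(0), "a"), "empty")
  withr::with_seed(64, {
    for (rep in 1:10) {
      de <- sample(LETTERS, 10)
      pk <- sample(LETTERS, 12)
      ov <- overlap_fraction(de, pk)
      expect_equal(ov$overlap, sum(de %in% pk))
      expect_equal(ov$fraction, mean(de %in% pk))
      # adding a peak gene never decreases the fraction
      ov2 <- overlap_fraction(de, c(pk, de[1]))
      expect_gte(ov2$fraction, ov$fraction)
    }
  })
})

test_that("multi-way intersection surfaces shared candidates", {
  sets <- list(rna_up = c("RUNX2", "CD55", "MAP2K3"),
               atac_open = c("RUNX2", "CD55", "EGFR"),
               fosl2 = c("RUNX2", "CD55", "NFKB1"))
  res <- multiway_intersection(sets)
  expect_equal(res$gene, c("CD55", "RUNX2"))
  expect_true(all(res$n_sets == 3))
  # min_sets = 1 returns the union
  expect_setequal(multiway_intersection(sets, min_sets = 1)$gene,
                  unique(unlist(sets)))
  # random sets match brute-force counting
  withr::with_seed(65, {
    for (rep in 1:10) {
      rs <- lapply(1:4, function(i) sample(LETTERS, sample(2:10, 1)))
      names(rs) <- paste0("s", 1:4)
      k <- sample(2:4, 1)
      res <- multiway_intersection(rs, min_sets = k)
      brute <- Filter(function(g) {
        sum(vapply(rs, function(s) g %in% s, logical(1))) >= k
      }, unique(unlist(rs)))
      expect_setequal(res$gene, brute)
    }
  })
})
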