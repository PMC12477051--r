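test_that("anchor k-means separates bimodal expression and labels by centroid", {
  expr <- rbind(ALDH1A3 = c(0, 0, 0, 10, 10), OTHER = rnorm(5))
  colnames(expr) <- paste0("s", 1:5)
  lab <- kmeans_anchor_split(expr)
  expect_equal(as.character(lab),
               c("negative", "negative", "negative", "positive", "positive"))
  expect_error(kmeans_anchor_split(rbind(ALDH1A3 = rep(1, 6))), "constant")
  expect_error(kmeans_anchor_split(expr, anchor_gene = "NOPE"), "NOPE")
})

test_that("anchor k-means recovers a well-separated Gaussian mixture", {
  withr::with_seed(7, {
    truth <- rep(c(0, 1), each = 100)
    v <- rnorm(200, mean = 4 * truth)
    expr <- rbind(ALDH1A3 = v, BG = rnorm(200))
    colnames(expr) <- paste0("s", 1:200)
    lab <- kmeans_anchor_split(expr, seed = 7)
    agree <- mean((lab == "positive") == (truth == 1))
    expect_gte(agree, 0.95)
  })
})

test_that("differential testing controls the null and recovers planted shifts", {
  withr::with_seed(11, {
    # null: identical group distributions
    expr <- matrix(rnorm(200 * 40), 200, 40,
                   dimnames = list(sprintf("g%03d", 1:200), NULL))
    labels <- rep(c("a", "b"), each = 20)
    de0 <- differential_genes(expr, labels, alpha = 0.05, lfc_min = 0)
    expect_lte(nrow(de0), 0.05 * 200 + 3)  # BH keeps false calls near zero
    # planted 2-fold shift in 20 genes, n = 50 vs 50
    expr2 <- matrix(rnorm(200 * 100), 200, 100,
                    dimnames = list(sprintf("g%03d", 1:200), NULL))
    labels2 <- rep(c("a", "b"), each = 50)
    expr2[1:20, labels2 == "b"] <- expr2[1:20, labels2 == "b"] + 1
    de <- differential_genes(expr2, labels2, alpha = 0.05, lfc_min = 0.5)
    expect_gte(sum(sprintf("g%03d", 1:20) %in% de$gene), 18)
    expect_true(all(de$direction[de$gene %in% sprintf("g%03d", 1:20)] == "up"))
    # infinite fold-change threshold empties the result
    expect_equal(nrow(differential_genes(expr2, labels2, lfc_min = Inf)), 0)
    expect_error(differential_genes(expr2[, 1:5],
                                    c("a", "a", "b", "b", "b")[1:5]),
                 "at least 3")
  })
})

test_that("group-label swap flips directions but keeps the gene set", {
  withr::with_seed(12, {
    expr <- matrix(rnorm(50 * 30), 50, 30,
                   dimnames = list(sprintf("g%02d", 1:50), NULL))
    expr[1:5, 16:30] <- expr[1:5, 16:30] + 3
    lab <- factor(rep(c("a", "b"), each = 15))
    de_ab <- differential_genes(expr, lab, lfc_min = 0.5)
    de_ba <- differential_genes(expr, factor(lab, levels = c("b", "a")),
                                lfc_min = 0.5)
    expect_setequal(de_ab$gene, de_ba$gene)
    m <- match(de_ab$gene, de_ba$gene)
    expect_equal(de_ab$log2_diff, -de_ba$log2_diff[m])
  })
})

test_that("marker-set intersection matches brute-force Venn accounting", {
  sets <- list(pdx = c("A", "B", "C", "D"), lines = c("B", "C", "E"),
               tissue = c("A", "B", "C"))
  res <- intersect_marker_sets(sets)
  expect_equal(res$consensus, c("B", "C"))
  expect_equal(sum(res$regions$count), length(unique(unlist(sets))))
  # disjoint sets have an empty consensus
  expect_equal(intersect_marker_sets(list(a = "X", b = "Y"))$consensus,
               character(0))
  # random sets: region counts equal brute-force membership enumeration
  withr::with_seed(14, {
    for (rep in 1:10) {
      rs <- lapply(1:3, function(i) sample(LETTERS, sample(3:12, 1)))
      names(rs) <- c("s1", "s2", "s3")
      res <- intersect_marker_sets(rs)
      for (g in unique(unlist(rs))) {
        pattern <- paste(names(rs)[vapply(rs, function(s) g %in% s,
                                          logical(1))], collapse = "&")
        row <- res$regions[res$regions$region == pattern, ]
        expect_true(g %in% strsplit(row$genes, ",")[[1]])
      }
      expect_equal(sum(res$regions$count), length(unique(unlist(rs))))
    }
  })
})

test_that("Spearman matrix matches the exhaustive rank-formula oracle", {
  withr::with_seed(15, {
    expr <- matrix(rnorm(4 * 6), 4, 6,
                   dimnames = list(c("w", "x", "y", "z"), paste0("s", 1:6)))
    cm <- correlation_matrix(expr, genes = c("w", "x", "y", "z"))
    expect_equal(diag(cm$rho), setNames(rep(1, 4), c("w", "x", "y", "z")))
    expect_true(isSymmetric(cm$rho))
    # direct Spearman formula on ranks (no ties at n = 6 continuous data)
    for (i in 1:3) for (j in (i + 1):4) {
      d <- rank(expr[i, ]) - rank(expr[j, ])
      rho_formula <- 1 - 6 * sum(d^2) / (6 * (6^2 - 1))
      expect_equal(unname(cm$rho[i, j]), rho_formula)
    }
  })
})

test_that("anti-monotone pairs correlate at exactly -1", {
  expr <- rbind(up = 1:10, down = exp(-(1:10)), noise = rnorm(10))
  colnames(expr) <- paste0("s", 1:10)
  cm <- correlation_matrix(expr, genes = c("up", "down"))
  expect_equal(unname(cm$rho["up", "down"]), -1)
  expect_error(correlation_matrix(expr, genes = c("up", "gone")), "gone")
})
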