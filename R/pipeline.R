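#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages in order `simulate` -> `discover` -> `score`
#' -> `subtype` -> `survival` -> `integrate`, writing each stage's outputs
#' under the configured output directory before the next stage starts, and
#' finishes with a manifest listing every artifact with its MD5 checksum.
#'
#' The configuration is a plain-text `key = value` file with `[paths]`,
#' `[stages]`, `[params]` and `[output]` sections (or an equivalent named
#' list; see [demo_config()] for a complete example).  With the `simulate`
#' stage enabled the expression, clinical, peak and annotation inputs are
#' generated by the synthetic-data module; otherwise they are read from the
#' configured paths.
#'
#' @param config Path to a config file, or a named list of config values.
#' @return Invisibly, a list with `outputs` (named file paths), `results`
#'   (in-memory stage results) and `manifest` (data frame `artifact`,
#'   `path`, `md5`); the manifest is also written as `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config) && length(config) == 1) {
    read_kv_config(config)
  } else {
    as.list(config)
  }
  get <- function(key, default = NULL) {
    if (!is.null(cfg[[key]])) cfg[[key]] else default
  }
  num <- function(key, default) as.numeric(get(key, default))
  flag <- function(key, default = "true") {
    tolower(get(key, default)) %in% c("true", "yes", "1")
  }
  out_dir <- get("output.dir")
  if (is.null(out_dir)) stop("config must set output.dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(num("params.seed", 1))
  stages <- c("simulate", "discover", "score", "subtype", "survival",
              "integrate")
  enabled <- setNames(vapply(stages, function(s) {
    flag(paste0("stages.", s))
  }, logical(1)), stages)

  # validate inputs before any stage runs
  if (!enabled[["simulate"]]) {
    need <- c(if (any(enabled[c("discover", "score", "subtype")]))
                "paths.expression",
              if (enabled[["survival"]]) "paths.clinical",
              if (enabled[["integrate"]]) c("paths.peaks", "paths.annotation"))
    for (key in need) {
      p <- get(key)
      if (is.null(p) || !file.exists(p)) {
        stop("required input missing before any stage ran: ", key,
             if (!is.null(p)) paste0(" (", p, ")"))
      }
    }
  }

  network <- if (!is.null(get("paths.network_config"))) {
    read_network_config(get("paths.network_config"))
  } else {
    gene_network()
  }
  schemes <- if (!is.null(get("paths.schemes_gmt"))) {
    read_schemes_gmt(get("paths.schemes_gmt"), get("paths.schemes_config"))
  } else {
    default_schemes()
  }

  outputs <- character(0)
  results <- list()
  emit <- function(name, path) outputs[[name]] <<- path
  step <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  de_genes_path <- get("paths.de_genes")
  if (enabled[["simulate"]]) {
    step("simulate", function() {
      sim <- simulate_cohort(cohort_spec(
        n_samples = num("params.n_samples", 150),
        subtype_fraction = num("params.subtype_fraction", 0.3),
        module_effect = num("params.module_effect", 1),
        module_correlation = num("params.module_correlation", 0.5),
        seed = seed), schemes = schemes)
      expr_path <- file.path(out_dir, "expression.tsv")
      write_expression_tsv(sim$expression, expr_path)
      emit("expression", expr_path)
      truth_path <- file.path(out_dir, "sample_truth.tsv")
      write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit("sample_truth", truth_path)
      surv <- simulate_survival(
        setNames(as.integer(sim$truth$basal), sim$truth$sample),
        survival_spec(hazard_ratio = num("params.hazard_ratio", 2),
                      seed = seed))
      clin_path <- file.path(out_dir, "clinical.tsv")
      write_survival_tsv(surv[, c("sample", "time", "event")], clin_path)
      emit("clinical", clin_path)
      ps <- simulate_peaks(peak_sim_spec(
        planted_overlap_fraction = num("params.planted_overlap_fraction", 0.5),
        tss_window = num("params.tss_window", 2000), seed = seed))
      peaks_path <- file.path(out_dir, "peaks.bed")
      write_peaks_bed(ps$peaks, peaks_path)
      emit("peaks", peaks_path)
      ann_path <- file.path(out_dir, "annotation.tsv")
      write_annotation_tsv(ps$annotation, ann_path)
      emit("annotation", ann_path)
      de_path <- file.path(out_dir, "de_genes.txt")
      writeLines(ps$de_genes, de_path)
      emit("de_genes", de_path)
      cfg[["paths.expression"]] <<- expr_path
      cfg[["paths.clinical"]] <<- clin_path
      cfg[["paths.peaks"]] <<- peaks_path
      cfg[["paths.annotation"]] <<- ann_path
      de_genes_path <<- de_path
      results$simulate <<- sim
    })
  }

  expr <- NULL
  if (any(enabled[c("discover", "score", "subtype")])) {
    if (is.null(get("paths.expression"))) {
      stop("required input missing before any stage ran: paths.expression")
    }
    expr <- read_expression_tsv(get("paths.expression"))
  }

  if (enabled[["discover"]]) {
    step("discover", function() {
      labels <- kmeans_anchor_split(expr,
                                    anchor_gene = get("params.anchor_gene",
                                                      "ALDH1A3"),
                                    seed = seed)
      de <- differential_genes(expr, labels,
                               alpha = num("params.alpha", 0.05),
                               lfc_min = num("params.lfc_min", 1))
      de_path <- file.path(out_dir, "differential_genes.tsv")
      write.table(de, de_path, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("differential_genes", de_path)
      cm <- correlation_matrix(expr, intersect(network$genes, rownames(expr)))
      cm_path <- file.path(out_dir, "correlation_matrix.tsv")
      write.table(data.frame(gene = rownames(cm$rho), cm$rho,
                             check.names = FALSE),
                  cm_path, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("correlation_matrix", cm_path)
      results$discover <<- list(labels = labels, de = de, correlation = cm)
    })
  }

  scores <- NULL
  if (enabled[["score"]]) {
    step("score", function() {
      scores <<- compute_scores(expr, derive_coefficients(network))
      score_path <- file.path(out_dir, "scores.tsv")
      write_scores_tsv(scores, score_path)
      emit("scores", score_path)
      results$score <<- scores
    })
  }

  if (enabled[["subtype"]]) {
    step("subtype", function() {
      calls <- as.data.frame(lapply(schemes, function(sc) {
        as.character(nmf_classify(expr, sc, seed = seed))
      }))
      names(calls) <- names(schemes)
      cons <- consensus_aggressive(
        calls, schemes, threshold = num("params.consensus_threshold", 3))
      calls$aggressive_count <- cons$aggressive_count
      calls$consensus_aggressive <- cons$consensus_aggressive
      calls <- cbind(sample = colnames(expr), calls)
      call_path <- file.path(out_dir, "subtype_calls.tsv")
      write.table(calls, call_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit("subtype_calls", call_path)
      results$subtype <<- calls
      if (!is.null(scores)) {
        assoc <- association_tests(scores$group, cons$consensus_aggressive,
                                   scores$score)
        assoc_path <- file.path(out_dir, "association.json")
        jsonlite::write_json(
          list(test = assoc$test, statistic = assoc$statistic, p = assoc$p,
               t_statistic = assoc$t_statistic, t_p = assoc$t_p),
          assoc_path, auto_unbox = TRUE, digits = NA)
        emit("association", assoc_path)
        results$association <<- assoc
      }
    })
  }

  if (enabled[["survival"]]) {
    step("survival", function() {
      if (is.null(scores)) stop("survival stage requires the score stage")
      clin <- read_survival_tsv(get("paths.clinical"))
      sv <- survival_by_score(clin, scores)
      km_path <- file.path(out_dir, "km_estimate.tsv")
      write.table(sv$km, km_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit("km_estimate", km_path)
      lr_path <- file.path(out_dir, "logrank.json")
      jsonlite::write_json(sv$logrank, lr_path, auto_unbox = TRUE, digits = NA)
      emit("logrank", lr_path)
      results$survival <<- sv
    })
  }

  if (enabled[["integrate"]]) {
    step("integrate", function() {
      peaks <- read_peaks_bed(get("paths.peaks"))
      ann <- read_annotation_tsv(get("paths.annotation"))
      annotated <- annotate_peaks(
        peaks, ann, promoter_window = num("params.promoter_window", 2000))
      ann_path <- file.path(out_dir, "annotated_peaks.tsv")
      write.table(annotated, ann_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit("annotated_peaks", ann_path)
      profile <- tss_distance_profile(annotated)
      integ <- list(tss_distance_median = profile$median,
                    feature_counts = as.list(table(annotated$feature)))
      if (!is.null(de_genes_path) && file.exists(de_genes_path)) {
        de <- readLines(de_genes_path)
        ov <- overlap_fraction(
          de, tss_proximal_genes(annotated,
                                 tss_window = num("params.tss_window", 2000)))
        integ$overlap <- ov[c("overlap", "total", "fraction")]
      }
      integ_path <- file.path(out_dir, "integration.json")
      jsonlite::write_json(integ, integ_path, auto_unbox = TRUE, digits = NA)
      emit("integration", integ_path)
      results$integrate <<- list(annotated = annotated, summary = integ)
    })
  }

  manifest <- data.frame(artifact = names(outputs),
                         path = unname(unlist(outputs)),
                         md5 = unname(tools::md5sum(unlist(outputs))))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(outputs = outputs, results = results, manifest = manifest))
}

#' Write a self-contained demonstration configuration
#'
#' Produces a config that runs every stage on synthetic data, suitable for a
#' deterministic end-to-end smoke run of [run_pipeline()].
#'
#' @param dir Directory for the config and pipeline outputs.
#' @param seed Integer seed shared by every stage.
#' @param n_samples Synthetic cohort size.
#' @return Path to the written config file.
#' @export
demo_config <- function(dir = tempfile("aldnet-demo-"), seed = 1L,
                        n_samples = 60) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "demo.cfg")
  writeLines(c(
    "[stages]",
    "simulate = true", "discover = true", "score = true",
    "subtype = true", "survival = true", "integrate = true",
    "[params]",
    paste("seed =", seed),
    paste("n_samples =", n_samples),
    "module_effect = 1.5",
    "hazard_ratio = 2",
    "planted_overlap_fraction = 0.5",
    "[output]",
    paste("dir =", file.path(dir, "out"))
  ), path)
  path
}
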