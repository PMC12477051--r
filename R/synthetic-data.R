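#' Specification of a synthetic two-subtype expression cohort
#'
#' Parameters of the generative model used by [simulate_cohort()].  The
#' cohort mimics the structure the scoring and subtyping stages assume: a
#' latent basal-like axis shared by the eight network genes, plus planted
#' signature-gene blocks for the k = 2/3/4 subtype classification schemes.
#'
#' @param n_samples Number of samples (>= 8).
#' @param n_background_genes Number of unstructured background genes.
#' @param subtype_fraction Fraction of samples that are basal-like, in (0,1).
#' @param module_effect Log2 expression shift of the eight network genes in
#'   basal-like samples.
#' @param module_correlation Target pairwise (Pearson) correlation of the
#'   eight network genes induced by a shared latent factor, in \[0, 1).
#' @param noise_sd Standard deviation of log2-expression noise (> 0).
#' @param block_effect Log2 up-shift of each planted signature block in its
#'   own subtype's samples.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 150, n_background_genes = 200,
                        subtype_fraction = 0.3, module_effect = 1,
                        module_correlation = 0.5, noise_sd = 1,
                        block_effect = 2, seed = 1L) {
  spec <- list(n_samples = n_samples,
               n_background_genes = n_background_genes,
               subtype_fraction = subtype_fraction,
               module_effect = module_effect,
               module_correlation = module_correlation,
               noise_sd = noise_sd, block_effect = block_effect,
               seed = as.integer(seed))
  if (n_samples < 8) stop("invalid cohort_spec: n_samples must be >= 8")
  if (subtype_fraction <= 0 || subtype_fraction >= 1) {
    stop("invalid cohort_spec: subtype_fraction must lie strictly in (0, 1)")
  }
  if (module_correlation < 0 || module_correlation >= 1) {
    stop("invalid cohort_spec: module_correlation must lie in [0, 1)")
  }
  if (noise_sd <= 0) stop("invalid cohort_spec: noise_sd must be > 0")
  structure(spec, class = "cohort_spec")
}

#' Simulate an expression cohort with a planted basal-like module
#'
#' Generates a log2-scale genes x samples matrix containing (i) unstructured
#' background genes, (ii) the eight network genes sharing a latent Gaussian
#' factor with loading `sqrt(module_correlation)` (so the target pairwise
#' Pearson correlation is `module_correlation`) and shifted upward by
#' `module_effect` in basal-like samples, and (iii) one signature-gene block
#' per subtype of each default classification scheme, up-shifted by
#' `block_effect` in the samples of that subtype.  Basal-like samples map to
#' the aggressive subtype of every scheme; the remaining samples are split
#' uniformly among the scheme's other subtypes.  Values are truncated at
#' zero so the matrix feeds NMF without further transformation.
#'
#' @param spec A [cohort_spec()].
#' @param schemes Signature schemes whose subtype blocks are planted;
#'   defaults to [default_schemes()].
#' @return A list with `expression` (numeric matrix, genes x samples) and
#'   `truth` (data frame: `sample`, `basal` flag, one true-label column per
#'   scheme).  Deterministic given `spec$seed`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_samples = 24, seed = 7))
#' dim(sim$expression)
#' @export
simulate_cohort <- function(spec, schemes = default_schemes()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    samples <- sprintf("S%03d", seq_len(n))
    n_basal <- max(1L, min(n - 1L, round(spec$subtype_fraction * n)))
    basal <- seq_len(n) %in% sample.int(n, n_basal)

    truth <- data.frame(sample = samples, basal = basal)
    for (sc in schemes) {
      lab <- character(n)
      lab[basal] <- sc$aggressive_label
      others <- setdiff(sc$subtypes, sc$aggressive_label)
      lab[!basal] <- sample(others, sum(!basal), replace = TRUE)
      truth[[sc$name]] <- lab
    }

    # background genes: gene-specific baseline + noise
    n_bg <- spec$n_background_genes
    bg_mu <- runif(n_bg, 4, 10)
    bg <- matrix(rnorm(n_bg * n, mean = bg_mu, sd = spec$noise_sd), n_bg, n)
    rownames(bg) <- sprintf("BG%04d", seq_len(n_bg))

    # eight network genes: shared latent factor + basal shift
    rho <- spec$module_correlation
    latent <- rnorm(n)
    net <- t(vapply(NETWORK_GENES, function(g) {
      eps <- rnorm(n)
      6 + spec$noise_sd * (sqrt(rho) * latent + sqrt(1 - rho) * eps) +
        spec$module_effect * basal
    }, numeric(n)))

    # planted signature blocks per scheme subtype
    blocks <- lapply(schemes, function(sc) {
      b <- matrix(rnorm(length(unlist(sc$genes)) * n, mean = 5,
                        sd = spec$noise_sd),
                  nrow = length(unlist(sc$genes)), ncol = n,
                  dimnames = list(unlist(sc$genes), NULL))
      for (st in sc$subtypes) {
        in_st <- truth[[sc$name]] == st
        b[sc$genes[[st]], in_st] <- b[sc$genes[[st]], in_st] + spec$block_effect
      }
      b
    })

    expr <- rbind(net, do.call(rbind, blocks), bg)
    colnames(expr) <- samples
    expr <- pmax(expr, 0)
    list(expression = expr, truth = truth)
  })
}

#' Specification of simulated survival follow-up
#'
#' @param baseline_hazard Event rate per time unit in the reference group
#'   (> 0).
#' @param hazard_ratio Multiplicative hazard in the high-risk group (> 0).
#' @param censor_rate Rate of independent exponential censoring (>= 0; 0
#'   means no censoring).
#' @param seed Integer seed.
#' @return A `survival_spec` list.
#' @export
survival_spec <- function(baseline_hazard = 0.05, hazard_ratio = 2,
                          censor_rate = 0.02, seed = 1L) {
  if (baseline_hazard <= 0) {
    stop("invalid survival_spec: baseline_hazard must be > 0")
  }
  if (hazard_ratio <= 0) stop("invalid survival_spec: hazard_ratio must be > 0")
  if (censor_rate < 0) stop("invalid survival_spec: censor_rate must be >= 0")
  structure(list(baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio, censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "survival_spec")
}

#' Simulate exponential survival with group-dependent hazard
#'
#' Event times are exponential with hazard `baseline_hazard` in group 0 and
#' `baseline_hazard * hazard_ratio` in group 1; censoring times are
#' independent exponential with rate `censor_rate`.
#'
#' @param groups Per-sample binary labels: logical, 0/1 numeric, or a factor
#'   whose second level is the high-risk group.  Names, if present, become
#'   sample identifiers.
#' @param spec A [survival_spec()].
#' @return Data frame `sample`, `time`, `event` (1 = event, 0 = censored),
#'   `group`.
#' @export
simulate_survival <- function(groups, spec) {
  stopifnot(inherits(spec, "survival_spec"))
  if (!length(groups)) stop("groups must be non-empty")
  g <- if (is.factor(groups)) as.integer(groups) - 1L else as.integer(groups)
  if (!all(g %in% c(0L, 1L))) stop("groups must be binary")
  n <- length(g)
  ids <- names(groups)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  withr::with_seed(spec$seed, {
    hz <- spec$baseline_hazard * ifelse(g == 1L, spec$hazard_ratio, 1)
    t_event <- rexp(n, rate = hz)
    t_cens <- if (spec$censor_rate > 0) rexp(n, rate = spec$censor_rate)
              else rep(Inf, n)
    data.frame(sample = ids,
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               group = g)
  })
}

#' Specification of a simulated genome with planted TSS-proximal peaks
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_genes Number of genes, placed non-overlapping.
#' @param n_peaks Total number of peaks.
#' @param n_de_genes Size of the designated differentially-expressed gene
#'   set (defaults to 30% of genes).
#' @param planted_overlap_fraction Fraction of DE genes whose TSS window
#'   receives a peak, in \[0, 1\].
#' @param tss_window Half-width of the TSS window in bases (> 0).
#' @param peak_width Width of each simulated peak in bases.
#' @param seed Integer seed.
#' @return A `peak_sim_spec` list.
#' @export
peak_sim_spec <- function(n_chromosomes = 3, chrom_length = 5e6,
                          n_genes = 300, n_peaks = 500,
                          n_de_genes = round(0.3 * n_genes),
                          planted_overlap_fraction = 0.5,
                          tss_window = 2000, peak_width = 400, seed = 1L) {
  if (planted_overlap_fraction < 0 || planted_overlap_fraction > 1) {
    stop("invalid peak_sim_spec: planted_overlap_fraction must lie in [0, 1]")
  }
  if (tss_window <= 0) stop("invalid peak_sim_spec: tss_window must be > 0")
  if (n_de_genes > n_genes) {
    stop("invalid peak_sim_spec: n_de_genes cannot exceed n_genes")
  }
  structure(list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
                 n_genes = n_genes, n_peaks = n_peaks,
                 n_de_genes = n_de_genes,
                 planted_overlap_fraction = planted_overlap_fraction,
                 tss_window = tss_window, peak_width = peak_width,
                 seed = as.integer(seed)),
            class = "peak_sim_spec")
}

#' Simulate a gene annotation and a peak set with a planted overlap fraction
#'
#' Genes are laid out non-overlapping on `n_chromosomes` chromosomes with
#' random strand; the TSS is the 5' end of the gene body.  A DE-gene subset
#' of size `n_de_genes` is designated, and exactly
#' `round(planted_overlap_fraction * n_de_genes)` of them receive one peak
#' whose midpoint lies inside TSS +/- `tss_window`.  All remaining peaks are
#' placed with midpoints outside every TSS window, so the fraction of DE
#' genes with a TSS-proximal peak is exact by construction.  Coordinates are
#' 0-based half-open (BED convention).
#'
#' @param spec A [peak_sim_spec()].
#' @return List with `peaks` (data frame: `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`), `annotation` (data frame: `gene`, `chrom`, `tss`,
#'   `strand`, `body_start`, `body_end`) and `de_genes` (character vector).
#' @export
simulate_peaks <- function(spec) {
  stopifnot(inherits(spec, "peak_sim_spec"))
  withr::with_seed(spec$seed, {
    per_chrom <- diff(round(seq(0, spec$n_genes,
                                length.out = spec$n_chromosomes + 1)))
    slot <- floor(spec$chrom_length / max(per_chrom))
    min_body <- 2000L
    if (slot < min_body + 2L * spec$tss_window + 10L) {
      stop("infeasible placement: chromosomes too short for ", spec$n_genes,
           " genes with tss_window ", spec$tss_window)
    }
    ann <- do.call(rbind, lapply(seq_len(spec$n_chromosomes), function(ci) {
      k <- per_chrom[ci]
      if (k == 0) return(NULL)
      slot_start <- (seq_len(k) - 1L) * slot
      body_len <- round(runif(k, min_body, min(20000, slot - 2 * spec$tss_window - 10)))
      margin <- spec$tss_window + 5
      body_start <- slot_start + margin +
        round(runif(k, 0, slot - body_len - 2 * margin))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      data.frame(chrom = paste0("chr", ci),
                 strand = strand,
                 body_start = body_start,
                 body_end = body_start + body_len)
    }))
    ann$gene <- sprintf("G%04d", seq_len(nrow(ann)))
    ann$tss <- ifelse(ann$strand == "+", ann$body_start, ann$body_end - 1L)
    ann <- ann[, c("gene", "chrom", "tss", "strand", "body_start", "body_end")]

    de_genes <- sort(sample(ann$gene, spec$n_de_genes))
    n_hit <- round(spec$planted_overlap_fraction * spec$n_de_genes)
    if (n_hit > spec$n_peaks) {
      stop("infeasible placement: planted peaks (", n_hit,
           ") exceed n_peaks (", spec$n_peaks, ")")
    }
    hit_genes <- sample(de_genes, n_hit)
    hit_ann <- ann[match(hit_genes, ann$gene), ]
    half <- floor(spec$peak_width / 2)
    # planted peaks: midpoint strictly inside the TSS window
    offs <- round(runif(n_hit, -spec$tss_window * 0.9, spec$tss_window * 0.9))
    hit_mid <- hit_ann$tss + offs
    planted <- data.frame(chrom = hit_ann$chrom, start = hit_mid - half,
                          end = hit_mid + half)

    # background peaks: rejection-sample midpoints outside all TSS windows
    n_bg <- spec$n_peaks - n_hit
    bg <- NULL
    if (n_bg > 0) {
      tss_by_chrom <- split(ann$tss, ann$chrom)
      got <- 0L
      acc_chrom <- character(0); acc_mid <- numeric(0)
      tries <- 0L
      while (got < n_bg) {
        tries <- tries + 1L
        if (tries > 200L) stop("infeasible placement: could not place ",
                               n_bg, " peaks outside TSS windows")
        m <- 2L * (n_bg - got)
        ci <- sample(spec$n_chromosomes, m, replace = TRUE)
        mid <- round(runif(m, half + 1, spec$chrom_length - half - 1))
        ok <- vapply(seq_len(m), function(i) {
          tss <- tss_by_chrom[[paste0("chr", ci[i])]]
          is.null(tss) || all(abs(tss - mid[i]) > spec$tss_window + half)
        }, logical(1))
        keep <- which(ok)[seq_len(min(sum(ok), n_bg - got))]
        acc_chrom <- c(acc_chrom, paste0("chr", ci[keep]))
        acc_mid <- c(acc_mid, mid[keep])
        got <- length(acc_mid)
      }
      bg <- data.frame(chrom = acc_chrom, start = acc_mid - half,
                       end = acc_mid + half)
    }
    peaks <- rbind(planted, bg)
    peaks$name <- sprintf("peak%04d", seq_len(nrow(peaks)))
    peaks$score <- round(runif(nrow(peaks), 10, 1000))
    peaks$strand <- "."
    ord <- order(peaks$chrom, peaks$start)
    peaks <- peaks[ord, ]
    rownames(peaks) <- NULL
    list(peaks = peaks, annotation = ann, de_genes = de_genes)
  })
}
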