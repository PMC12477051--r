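#' Annotate peaks with their nearest-TSS gene and genomic feature class
#'
#' Each peak is represented by its midpoint and assigned to the gene with
#' the nearest TSS on the same chromosome.  The signed distance is
#' strand-aware: positive downstream of the TSS in the gene's direction of
#' transcription, negative upstream.  Feature classes are exclusive, with
#' precedence promoter > exonic > intronic > distal intergenic: a midpoint
#' within `promoter_window` of the assigned TSS is `promoter`; otherwise a
#' midpoint inside any gene body is `exonic` if inside an annotated exon and
#' `intronic` if not (with no exon annotation, gene-body hits are
#' `intronic`); everything else is `distal_intergenic`.
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`; e.g. from [simulate_peaks()] or
#'   [read_peaks_bed()].
#' @param ann Gene annotation data frame: `gene`, `chrom`, `tss`, `strand`,
#'   `body_start`, `body_end` (0-based).
#' @param promoter_window Promoter half-width around the TSS in bp
#'   (default 2000).
#' @param exons Optional data frame `gene`, `chrom`, `start`, `end` of exon
#'   intervals (0-based half-open).
#' @return Data frame: peak columns plus `midpoint`, `gene`, `distance`
#'   (signed bp to the assigned TSS) and `feature` (factor).  Peaks on
#'   chromosomes absent from the annotation are returned with `NA` gene and
#'   feature `unassigned`, with a warning.
#' @export
annotate_peaks <- function(peaks, ann, promoter_window = 2000, exons = NULL) {
  if (!nrow(ann)) stop("gene annotation is empty")
  if (!nrow(peaks)) stop("peak set is empty")
  if (any(peaks$start >= peaks$end)) stop("peak intervals need start < end")
  mid <- floor((peaks$start + peaks$end) / 2)

  shared <- peaks$chrom %in% ann$chrom
  if (!all(shared)) {
    warning(sum(!shared), " peak(s) on chromosomes absent from the ",
            "annotation left unassigned")
  }

  gene_idx <- rep(NA_integer_, nrow(peaks))
  if (any(shared)) {
    mid_gr <- GenomicRanges::GRanges(
      peaks$chrom[shared], IRanges::IRanges(mid[shared] + 1L, width = 1L))
    tss_gr <- GenomicRanges::GRanges(
      ann$chrom, IRanges::IRanges(ann$tss + 1L, width = 1L))
    hit <- GenomicRanges::nearest(mid_gr, tss_gr)
    gene_idx[shared] <- hit
  }

  distance <- rep(NA_real_, nrow(peaks))
  ok <- !is.na(gene_idx)
  raw <- mid[ok] - ann$tss[gene_idx[ok]]
  distance[ok] <- ifelse(ann$strand[gene_idx[ok]] == "+", raw, -raw)

  feature <- rep("distal_intergenic", nrow(peaks))
  feature[!ok] <- "unassigned"
  feature[ok & abs(distance) <= promoter_window] <- "promoter"

  in_body <- rep(FALSE, nrow(peaks))
  if (any(shared)) {
    body_gr <- GenomicRanges::GRanges(
      ann$chrom, IRanges::IRanges(ann$body_start + 1L, ann$body_end))
    mid_all <- GenomicRanges::GRanges(
      peaks$chrom[shared], IRanges::IRanges(mid[shared] + 1L, width = 1L))
    in_body[shared] <-
      IRanges::overlapsAny(mid_all, body_gr)
  }
  in_exon <- rep(FALSE, nrow(peaks))
  if (!is.null(exons) && nrow(exons) && any(shared)) {
    exon_gr <- GenomicRanges::GRanges(
      exons$chrom, IRanges::IRanges(exons$start + 1L, exons$end))
    mid_all <- GenomicRanges::GRanges(
      peaks$chrom[shared], IRanges::IRanges(mid[shared] + 1L, width = 1L))
    in_exon[shared] <- IRanges::overlapsAny(mid_all, exon_gr)
  }
  gene_body <- feature == "distal_intergenic" & in_body
  feature[gene_body & in_exon] <- "exonic"
  feature[gene_body & !in_exon] <- "intronic"

  out <- peaks
  out$midpoint <- mid
  out$gene <- ifelse(ok, ann$gene[gene_idx], NA_character_)
  out$distance <- distance
  out$feature <- factor(feature, levels = c("promoter", "exonic", "intronic",
                                            "distal_intergenic", "unassigned"))
  out
}

#' Distance-to-TSS profile of annotated peaks
#'
#' Summarises absolute peak-to-TSS distances: median, deciles, and a
#' histogram over log10 bins with edges at integer powers of 10 (the usual
#' QC display for enhancer-mark peak sets, whose median typically falls
#' between 10^3 and 10^5 bp).
#'
#' @param annotated Output of [annotate_peaks()].
#' @return List with `median`, `deciles` (10%..90%), and `histogram` (data
#'   frame `bin`, lower/upper bp bounds, `count`).  Distances below 1 bp are
#'   pooled into the first bin.
#' @export
tss_distance_profile <- function(annotated) {
  d <- abs(annotated$distance[!is.na(annotated$distance)])
  if (!length(d)) stop("no assigned peaks")
  lo <- floor(log10(min(pmax(d, 1))))
  hi <- floor(log10(max(pmax(d, 1)))) + 1L
  edges <- 10^(lo:hi)
  bins <- cut(pmax(d, 1), breaks = c(0, edges), right = FALSE,
              labels = c(paste0("<1e", lo),
                         paste0("1e", lo:(hi - 1), "-1e", (lo + 1):hi)))
  hist_df <- as.data.frame(table(bin = bins))
  names(hist_df)[2] <- "count"
  list(median = median(d),
       deciles = quantile(d, probs = seq(0.1, 0.9, by = 0.1)),
       histogram = hist_df)
}

#' Compare genomic-feature distributions of two peak sets
#'
#' Chi-squared test on the 2 x k contingency table of feature-class counts
#' (e.g. open vs closed peaks over promoter/exonic/intronic/distal).
#' Categories whose expected count is zero in both sets are dropped with a
#' warning.
#'
#' @param classes_a,classes_b Named integer vectors of counts per feature
#'   class, over the same categories.
#' @return List with `statistic`, `df`, `p`, `table`.
#' @export
feature_distribution_test <- function(classes_a, classes_b) {
  cats <- union(names(classes_a), names(classes_b))
  a <- setNames(rep(0, length(cats)), cats)
  b <- a
  a[names(classes_a)] <- classes_a
  b[names(classes_b)] <- classes_b
  if (sum(a) == 0 || sum(b) == 0) stop("each peak set needs positive total")
  zero <- (a + b) == 0
  if (any(zero)) {
    warning("dropping empty feature categories: ",
            paste(cats[zero], collapse = ", "))
    a <- a[!zero]; b <- b[!zero]
  }
  tab <- rbind(a = a, b = b)
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(cs$statistic), df = unname(cs$parameter),
       p = cs$p.value, table = tab)
}

#' Fraction of differential genes carrying a differential peak
#'
#' @param de_genes Character vector of differential (e.g. upregulated)
#'   genes; must be non-empty.
#' @param peak_genes Character vector of genes associated with differential
#'   peaks (e.g. genes whose TSS window holds an increased H3K27ac peak).
#' @return List with `overlap` (count), `total` (|de_genes|), `fraction`
#'   and `genes` (the overlapping genes, sorted).
#' @export
overlap_fraction <- function(de_genes, peak_genes) {
  de_genes <- unique(de_genes)
  if (!length(de_genes)) stop("empty differential gene set")
  hit <- sort(intersect(de_genes, unique(peak_genes)))
  list(overlap = length(hit), total = length(de_genes),
       fraction = length(hit) / length(de_genes), genes = hit)
}

#' Genes whose assigned peak lies within a TSS window
#'
#' Convenience selector for [overlap_fraction()]: genes from
#' [annotate_peaks()] output whose assigned peak midpoint falls within
#' `tss_window` of the TSS.
#'
#' @param annotated Output of [annotate_peaks()].
#' @param tss_window Window half-width in bp.
#' @return Character vector of gene identifiers.
#' @export
tss_proximal_genes <- function(annotated, tss_window = 2000) {
  ok <- !is.na(annotated$distance) & abs(annotated$distance) <= tss_window
  unique(annotated$gene[ok])
}

#' Multi-way intersection of named gene sets
#'
#' @param sets Named list (>= 2) of character vectors.
#' @param min_sets Minimum number of sets a gene must appear in (default:
#'   all of them).
#' @return Data frame `gene`, `n_sets`, one logical membership column per
#'   set; rows are genes present in at least `min_sets` sets, sorted by
#'   descending membership count then gene name.
#' @export
multiway_intersection <- function(sets, min_sets = length(sets)) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  if (min_sets < 1 || min_sets > length(sets)) {
    stop("min_sets must lie in 1..", length(sets))
  }
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (!is.matrix(membership)) membership <- t(as.matrix(membership))
  n_sets <- rowSums(membership)
  keep <- n_sets >= min_sets
  out <- data.frame(gene = universe[keep], n_sets = as.integer(n_sets[keep]))
  out <- cbind(out, as.data.frame(membership[keep, , drop = FALSE],
                                  row.names = NULL))
  out[order(-out$n_sets, out$gene), , drop = FALSE]
}
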