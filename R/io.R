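#' Read and write expression matrices as TSV
#'
#' Genes in rows (first column = gene identifier), samples in columns with a
#' header line.
#'
#' @param path File path.
#' @return `read_expression_tsv`: numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene identifiers in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers in ", path)
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param expr Numeric matrix, genes x samples.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write survival tables as TSV
#'
#' Columns `sample`, `time`, `event` (and optionally `group`).
#'
#' @param path File path.
#' @export
read_survival_tsv <- function(path) {
  df <- read.delim(path)
  check_survival_table(df)
  df
}

#' @rdname read_survival_tsv
#' @param table Survival data frame.
#' @export
write_survival_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write peak sets as 6-column BED
#'
#' BED is 0-based half-open; the in-memory data frame keeps the same
#' convention (`start` 0-based inclusive, `end` exclusive).
#'
#' @param path File path.
#' @return `read_peaks_bed`: data frame `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, sorted by chromosome then start.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name else
                     sprintf("peak%04d", seq_along(gr)),
                   score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
                   strand = as.character(GenomicRanges::strand(gr)))
  df$strand[df$strand == "*"] <- "."
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$start >= df$end)) stop("invalid interval (start >= end) in ", path)
  df
}

#' @rdname read_peaks_bed
#' @param peaks Peak data frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`).
#' @export
write_peaks_bed <- function(peaks, path) {
  strand <- peaks$strand
  strand[is.na(strand) | strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(peaks$start + 1L, peaks$end),
    strand = strand,
    name = if (!is.null(peaks$name)) peaks$name else
      sprintf("peak%04d", seq_len(nrow(peaks))),
    score = if (!is.null(peaks$score)) peaks$score else 0)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write gene annotations as TSV
#'
#' Columns `gene`, `chrom`, `tss`, `strand`, `body_start`, `body_end`;
#' coordinates 0-based half-open, matching the BED convention.
#'
#' @param path File path.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path)
  req <- c("gene", "chrom", "tss", "strand", "body_start", "body_end")
  if (!all(req %in% names(df))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  bad <- df$tss < df$body_start | df$tss > df$body_end
  if (any(bad)) stop("TSS outside gene body for: ",
                     paste(df$gene[bad], collapse = ", "))
  df
}

#' @rdname read_annotation_tsv
#' @param ann Annotation data frame.
#' @export
write_annotation_tsv <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' @param path File path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Optional per-set description (second GMT column).
#' @export
write_gmt <- function(sets, path, description = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read subtype classification schemes from GMT plus a scheme config
#'
#' The GMT file holds one gene set per subtype, named `scheme.subtype`; the
#' config (key = value lines) maps each scheme name to its aggressive
#' subtype, e.g. `scheme_k2 = basal-like`.
#'
#' @param gmt_path Path to the GMT file of per-subtype signatures.
#' @param config_path Path to the scheme config.
#' @return Named list of [signature_scheme()] objects.
#' @export
read_schemes_gmt <- function(gmt_path, config_path) {
  sets <- read_gmt(gmt_path)
  parts <- strsplit(names(sets), ".", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("GMT set names must be of the form scheme.subtype")
  }
  scheme_of <- vapply(parts, `[`, "", 1)
  subtype_of <- vapply(parts, `[`, "", 2)
  cfg <- read_kv_config(config_path)
  lapply(setNames(nm = unique(scheme_of)), function(sc) {
    genes <- setNames(sets[scheme_of == sc], subtype_of[scheme_of == sc])
    if (is.null(cfg[[sc]])) stop("no aggressive label configured for ", sc)
    signature_scheme(sc, genes, cfg[[sc]])
  })
}

# Minimal key = value config reader ('#' comments, [section] headers kept as
# "section.key" prefixes).
read_kv_config <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    out[[key]] <- trimws(kv[2])
  }
  out
}
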