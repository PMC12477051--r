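#' The eight-gene ALDH1A3 interaction network
#'
#' Constructs the gene network used for connectivity-weighted scoring.  Each
#' gene carries a non-negative weight numerator derived from its connectivity
#' in the interaction graph: a double-headed (mutual) edge contributes 1 split
#' equally between its endpoints, a single-headed edge contributes 0.5 to its
#' target.  The default network encodes the published 13-edge graph through
#' its per-gene numerators (3, 2.5, 2, 1.5, 1.5, 1, 1, 0.5 over a total of
#' 13); the edge list itself is optional and used only for validation, since
#' the numerators are the authoritative quantity.
#'
#' Two published weightings of the same graph differ only in that EMP1 and
#' PMEPA1 exchange numerators; `figure1f_weights = TRUE` selects the variant
#' in which EMP1 takes 2/13 and PMEPA1 takes 1.5/13.
#'
#' @param gene_weights Named numeric vector of non-negative per-gene weight
#'   numerators.  Defaults to the eight-gene network weights.
#' @param edges Optional data frame of edges with columns `gene_a`, `gene_b`,
#'   `kind` (`"double"` or `"single"`); for single-headed edges `gene_b` is
#'   the target.  Retained for [validate_edge_list()].
#' @param figure1f_weights Logical; swap the EMP1 and PMEPA1 numerators
#'   (ignored when `gene_weights` is supplied explicitly).
#'
#' @return An object of class `gene_network` with elements `genes`,
#'   `gene_weights`, `total_weight` and `edges`.
#' @examples
#' net <- gene_network()
#' net$total_weight  # 13
#' @seealso [derive_coefficients()], [validate_edge_list()]
#' @export
gene_network <- function(gene_weights = NULL, edges = NULL,
                         figure1f_weights = FALSE) {
  if (is.null(gene_weights)) {
    gene_weights <- c(ALDH1A3 = 3, EMP1 = 1.5, FAM3C = 2.5, IRS2 = 1,
                      MAML2 = 1, MCC = 1.5, PMEPA1 = 2, SP100 = 0.5)
    if (isTRUE(figure1f_weights)) {
      gene_weights[c("EMP1", "PMEPA1")] <- gene_weights[c("PMEPA1", "EMP1")]
    }
  }
  if (is.null(names(gene_weights)) || anyNA(names(gene_weights)) ||
      any(names(gene_weights) == "")) {
    stop("gene_weights must be a fully named numeric vector")
  }
  if (anyDuplicated(names(gene_weights))) {
    stop("duplicate gene names in gene_weights")
  }
  if (any(gene_weights < 0)) stop("gene_weights must be non-negative")
  total <- sum(gene_weights)
  if (total <= 0) stop("total network weight must be positive")
  if (!is.null(edges)) {
    edges <- as.data.frame(edges)
    required <- c("gene_a", "gene_b", "kind")
    if (!all(required %in% names(edges))) {
      stop("edges must have columns gene_a, gene_b, kind")
    }
    unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)),
                       names(gene_weights))
    if (length(unknown)) {
      stop("unknown gene(s) in edge list: ", paste(unknown, collapse = ", "))
    }
    if (!all(edges$kind %in% c("double", "single"))) {
      stop("edge kind must be 'double' or 'single'")
    }
  }
  structure(
    list(genes = names(gene_weights), gene_weights = gene_weights,
         total_weight = total, edges = edges),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene network:", length(x$genes), "genes, total weight",
      format(x$total_weight), "\n")
  print(x$gene_weights)
  if (!is.null(x$edges)) cat(nrow(x$edges), "edges attached\n")
  invisible(x)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive per-gene scoring coefficients from network connectivity
#'
#' Normalises each gene's weight numerator by the total network weight.  The
#' percentage form is rounded half-up to two decimals, matching the usual
#' reporting convention for the pie-chart weights of the eight-gene network
#' (ALDH1A3 23.08%, FAM3C 19.23%, ..., SP100 3.85%).
#'
#' @param network A [gene_network()].
#' @return An object of class `coefficient_vector`: a list with `coefficient`
#'   (named proportions summing to 1) and `percent` (rounded to 2 decimals).
#' @examples
#' co <- derive_coefficients(gene_network())
#' co$percent["ALDH1A3"]  # 23.08
#' @export
derive_coefficients <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  if (network$total_weight <= 0) stop("total network weight must be positive")
  coefficient <- network$gene_weights / network$total_weight
  stopifnot(abs(sum(coefficient) - 1) < 1e-9)
  structure(
    list(coefficient = coefficient,
         percent = round_half_up(coefficient * 100, 2)),
    class = "coefficient_vector"
  )
}

#' @export
print.coefficient_vector <- function(x, ...) {
  cat("Network coefficients (%):\n")
  print(x$percent)
  invisible(x)
}

#' Check an explicit edge list against the per-gene numerators
#'
#' Applies the weight-allocation rule to the network's edge list and compares
#' the reconstructed per-gene weights with the stored numerators.  Under the
#' default rule (`"split"`) a double-headed edge contributes 0.5 to each
#' endpoint (1 in total) and a single-headed edge contributes 0.5 to its
#' target — the only allocation family under which the default eight-gene
#' numerators can total 13 over 13 edges.
#'
#' @param network A [gene_network()] (with or without an edge list).
#' @param allocation Allocation rule name; only `"split"` is defined.
#' @return A list with `status` (`"ok"`, `"mismatch"` or `"no_edges"`),
#'   `reconstructed` per-gene weights, `total`, and a `mismatches` data frame.
#' @export
validate_edge_list <- function(network, allocation = "split") {
  stopifnot(inherits(network, "gene_network"))
  allocation <- match.arg(allocation)
  if (is.null(network$edges)) {
    return(list(status = "no_edges",
                message = "edge list absent; numerators taken as authoritative",
                reconstructed = NULL, total = NA_real_,
                mismatches = data.frame()))
  }
  w <- setNames(numeric(length(network$genes)), network$genes)
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    if (e$kind == "double") {
      w[e$gene_a] <- w[e$gene_a] + 0.5
      w[e$gene_b] <- w[e$gene_b] + 0.5
    } else {
      w[e$gene_b] <- w[e$gene_b] + 0.5
    }
  }
  diffs <- w - network$gene_weights[names(w)]
  bad <- which(abs(diffs) > 1e-9)
  mism <- data.frame(gene = names(w)[bad],
                     expected = unname(network$gene_weights[names(w)[bad]]),
                     reconstructed = unname(w[bad]))
  list(status = if (nrow(mism)) "mismatch" else "ok",
       reconstructed = w, total = sum(w), mismatches = mism)
}

#' Read a network configuration file
#'
#' Plain-text `key = value` format: each line names a gene and its weight
#' numerator.  An optional `[edges]` section lists edges as
#' `gene_a <-> gene_b` (double-headed) or `gene_a -> gene_b` (single-headed).
#' Blank lines and `#` comments are ignored.
#'
#' @param path Path to the configuration file.
#' @return A [gene_network()].
#' @export
read_network_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  edge_start <- match("[edges]", lines)
  if (is.na(edge_start)) {
    weight_lines <- lines
    edge_lines <- character()
  } else {
    weight_lines <- lines[seq_len(edge_start - 1)]
    edge_lines <- lines[-seq_len(edge_start)]
  }
  kv <- strsplit(weight_lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed weight line in ", path)
  weights <- setNames(as.numeric(trimws(vapply(kv, `[`, "", 2))),
                      trimws(vapply(kv, `[`, "", 1)))
  if (anyNA(weights)) stop("non-numeric weight in ", path)
  edges <- NULL
  if (length(edge_lines)) {
    double <- grepl("<->", edge_lines, fixed = TRUE)
    parts <- ifelse(double,
                    strsplit(edge_lines, "<->", fixed = TRUE),
                    strsplit(edge_lines, "->", fixed = TRUE))
    edges <- data.frame(
      gene_a = trimws(vapply(parts, `[`, "", 1)),
      gene_b = trimws(vapply(parts, `[`, "", 2)),
      kind = ifelse(double, "double", "single")
    )
  }
  gene_network(gene_weights = weights, edges = edges)
}

#' Write coefficients as TSV
#'
#' @param coefficients A `coefficient_vector` from [derive_coefficients()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficients_tsv <- function(coefficients, path) {
  stopifnot(inherits(coefficients, "coefficient_vector"))
  df <- data.frame(gene = names(coefficients$coefficient),
                   coefficient = unname(coefficients$coefficient),
                   percent = unname(coefficients$percent))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
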