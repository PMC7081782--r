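#' Construct a reference network from an edge table
#'
#' Edges are undirected gene pairs with a confidence score in [0, 1]. The
#' constructor canonicalizes each pair so that `gene_a < gene_b`
#' (lexicographically), drops self-loops with a warning, and merges
#' duplicate/reversed-duplicate pairs keeping the maximum score.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `score`.
#' @return An object of class `reference_network`: a data frame of canonical
#'   edges sorted by (gene_a, gene_b).
#' @export
reference_network <- function(edges) {
  need <- c("gene_a", "gene_b", "score")
  miss <- setdiff(need, names(edges))
  if (length(miss)) .stop_fmt("edge table lacks columns: %s", .id_list(miss))
  a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
  s <- as.numeric(edges$score)
  if (anyNA(s) || any(s < 0 | s > 1)) .stop_fmt("confidence scores must lie in [0, 1]")
  loop <- a == b
  if (any(loop)) {
    .warn_fmt("dropping %d self-loop(s): %s", sum(loop), .id_list(unique(a[loop])))
    a <- a[!loop]; b <- b[!loop]; s <- s[!loop]
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  # keep the maximum score among duplicated (possibly reversed) pairs
  s <- vapply(split(s, key), max, 0)
  key <- names(s)
  parts <- strsplit(key, "\r", fixed = TRUE)
  df <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                   gene_b = vapply(parts, `[`, "", 2L),
                   score = unname(s), stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("reference_network", "data.frame")
  df
}

#' Read a STRING-dialect interaction file
#'
#' Parses a whitespace- or tab-delimited edge list in the
#' `protein1 protein2 combined_score` dialect (a header line is detected and
#' skipped automatically; gzip is handled transparently). STRING ships
#' integer combined scores on a 0--1000 scale; with
#' `score_scale = "raw-1000"` (the default) scores are divided by 1000 so
#' that confidence thresholds are always expressed on [0, 1]. Files that are
#' already on the unit scale are read with `score_scale = "unit"`.
#'
#' @param path Path to the edge-list file.
#' @param score_scale `"raw-1000"` or `"unit"`.
#' @param aliases Optional named character vector mapping the file's
#'   identifiers (e.g. STRING protein ids) to gene symbols; unmapped
#'   identifiers pass through unchanged.
#' @return A `reference_network`.
#' @export
read_string_edges <- function(path, score_scale = c("raw-1000", "unit"), aliases = NULL) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) .stop_fmt("network file not found: %s", path)
  lines <- readLines(con <- gzfile(path)); close(con)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .stop_fmt("empty network file: %s", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) .stop_fmt("line %d has fewer than 3 fields", which(nf < 3L)[1L])
  first_score <- suppressWarnings(as.numeric(fields[[1L]][3L]))
  start <- if (is.na(first_score)) 2L else 1L  # header detection
  if (start > length(fields)) .stop_fmt("network file has a header but no data lines")
  rows <- fields[start:length(fields)]
  a <- vapply(rows, `[`, "", 1L)
  b <- vapply(rows, `[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3L)))
  bad <- which(is.na(s))
  if (length(bad)) .stop_fmt("non-numeric score on line %d", bad[1L] + start - 1L)
  if (score_scale == "raw-1000") {
    out <- which(s < 0 | s > 1000)
    if (length(out))
      .stop_fmt("score %g on line %d outside the 0-1000 scale", s[out[1L]], out[1L] + start - 1L)
    s <- s / 1000
  } else {
    out <- which(s < 0 | s > 1)
    if (length(out))
      .stop_fmt("score %g on line %d outside the unit scale", s[out[1L]], out[1L] + start - 1L)
  }
  if (!is.null(aliases)) {
    a <- ifelse(a %in% names(aliases), unname(aliases[a]), a)
    b <- ifelse(b %in% names(aliases), unname(aliases[b]), b)
  }
  reference_network(data.frame(gene_a = a, gene_b = b, score = s))
}

#' Keep edges above a confidence cutoff
#'
#' Retains edges whose confidence score is strictly greater than `cutoff`
#' (a pair is considered connected only when its score exceeds the cutoff).
#'
#' @param net A `reference_network`.
#' @param cutoff Confidence cutoff in [0, 1]; default 0.6.
#' @return The filtered `reference_network`.
#' @export
filter_by_confidence <- function(net, cutoff = 0.6) {
  stopifnot(inherits(net, "reference_network"), .is_prob(cutoff))
  out <- net[net$score > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reference_network", "data.frame")
  out
}

#' Restrict a network to a gene universe
#'
#' Keeps only edges whose both endpoints are in `genes` — typically the
#' genes measured in the expression dataset.
#'
#' @param net A `reference_network`.
#' @param genes Character vector of gene identifiers.
#' @return The restricted `reference_network`.
#' @export
restrict_to_genes <- function(net, genes) {
  stopifnot(inherits(net, "reference_network"))
  out <- net[net$gene_a %in% genes & net$gene_b %in% genes, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reference_network", "data.frame")
  out
}

#' Genes spanned by a network
#' @param net A `reference_network`.
#' @return Sorted character vector of all edge endpoints.
#' @export
network_genes <- function(net) sort(unique(c(net$gene_a, net$gene_b)))

#' Write a network as canonical TSV
#' @param net A `reference_network`.
#' @param path Output path (`.gz` for gzip).
#' @export
write_network_edges <- function(net, path) {
  stopifnot(inherits(net, "reference_network"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines("gene_a\tgene_b\tscore", con)
  if (nrow(net))
    writeLines(paste(net$gene_a, net$gene_b,
                     format(net$score, digits = 15, trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  invisible(path)
}

#' @export
print.reference_network <- function(x, ...) {
  cat(sprintf("Reference network: %d edges over %d genes\n",
              nrow(x), length(network_genes(x))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... and %d more edges\n", nrow(x) - 5L))
  invisible(x)
}
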