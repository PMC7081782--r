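#' Read a gene expression matrix from delimited text
#'
#' Reads a genes-by-samples matrix of (already normalized, log2-scale)
#' expression values. The first column holds feature identifiers and the
#' header row holds sample identifiers. Gzip-compressed files are read
#' transparently. Parsing is locale-independent: the decimal separator is
#' always the point.
#'
#' @param path Path to a delimited text file (optionally gzipped).
#' @param sep Field separator, tab by default.
#' @return A numeric matrix with feature identifiers as row names and sample
#'   identifiers as column names.
#' @seealso [write_expression()] for the inverse operation.
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) .stop_fmt("expression file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", dec = ".")
  if (ncol(df) < 2L) .stop_fmt("expression file needs a feature-id column plus >= 1 sample column")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) .stop_fmt("duplicated feature ids: %s", .id_list(dup))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]))
      if (length(bad)) {
        .stop_fmt("non-numeric value '%s' at row %d (feature %s), column '%s'",
                  vals[[j]][bad[1L]], bad[1L], ids[bad[1L]], names(vals)[j])
      }
      vals[[j]] <- num
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  validate_expression(mat)
  mat
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with 15 significant digits so that a write/read
#' round-trip preserves them to at least 12 significant digits.
#'
#' @param mat Numeric matrix, features in rows, samples in columns.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param sep Field separator.
#' @export
write_expression <- function(mat, path, sep = "\t") {
  validate_expression(mat)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(mat)), collapse = sep), con)
  body <- apply(mat, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = sep))
  writeLines(paste(rownames(mat), body, sep = sep), con)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric, all values finite, unique
#' non-empty row (feature) and column (sample) identifiers.
#'
#' @param mat Matrix to validate.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) .stop_fmt("expression matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    .stop_fmt("expression matrix needs feature row names and sample column names")
  dupr <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dupr)) .stop_fmt("duplicated feature ids: %s", .id_list(dupr))
  dupc <- unique(colnames(mat)[duplicated(colnames(mat))])
  if (length(dupc)) .stop_fmt("duplicated sample ids: %s", .id_list(dupc))
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    .stop_fmt("non-finite expression value at feature %s, sample %s",
              rownames(mat)[bad[1L]], colnames(mat)[bad[2L]])
  }
  invisible(mat)
}

#' Read longitudinal sample annotations
#'
#' Expects a delimited table with columns `sample_id`, `patient_id`,
#' `timepoint` and `group`. Group labels are normalized to the canonical
#' `R` (responder) / `NR` (non-responder) pair, optionally through a
#' user-supplied alias map such as `c(responder = "R", "non-responder" = "NR")`.
#'
#' @param path Path to a delimited text file (optionally gzipped).
#' @param sep Field separator.
#' @param group_aliases Named character vector mapping input group labels to
#'   `"R"` or `"NR"`; applied before validation.
#' @return A data frame of validated annotations (one row per sample).
#' @export
read_annotations <- function(path, sep = "\t", group_aliases = NULL) {
  if (!file.exists(path)) .stop_fmt("annotation file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("sample_id", "patient_id", "timepoint", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stop_fmt("annotation file lacks columns: %s", .id_list(miss))
  ann <- data.frame(sample_id = as.character(df$sample_id),
                    patient_id = as.character(df$patient_id),
                    timepoint = df$timepoint,
                    group = as.character(df$group),
                    stringsAsFactors = FALSE)
  validate_annotations(ann, group_aliases = group_aliases)
}

#' Validate (and normalize) sample annotations
#'
#' @param ann Data frame with columns sample_id, patient_id, timepoint, group.
#' @param group_aliases Optional named character vector of label aliases.
#' @return The normalized annotation data frame.
#' @export
validate_annotations <- function(ann, group_aliases = NULL) {
  if (!is.null(group_aliases)) {
    hit <- ann$group %in% names(group_aliases)
    ann$group[hit] <- unname(group_aliases[ann$group[hit]])
  }
  bad <- setdiff(unique(ann$group), c("R", "NR"))
  if (length(bad))
    .stop_fmt("unknown group label(s): %s (expected R/NR or an alias mapping to them)",
              .id_list(bad))
  if (anyNA(suppressWarnings(tp <- as.integer(ann$timepoint))))
    .stop_fmt("timepoint column must be integer indices")
  ann$timepoint <- tp
  dup <- duplicated(ann$sample_id)
  if (any(dup)) .stop_fmt("duplicated sample ids: %s", .id_list(unique(ann$sample_id[dup])))
  key <- paste(ann$patient_id, ann$timepoint, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    .stop_fmt("more than one sample for (patient, timepoint): %s",
              .id_list(unique(gsub("\r", " @ t", key[dup]))))
  pg <- unique(ann[, c("patient_id", "group")])
  if (any(duplicated(pg$patient_id)))
    .stop_fmt("patient(s) assigned to both groups: %s",
              .id_list(pg$patient_id[duplicated(pg$patient_id)]))
  for (g in c("R", "NR")) {
    n <- length(unique(ann$patient_id[ann$group == g]))
    if (n < 3L)
      .stop_fmt("group %s has %d patient(s); at least 3 are required for rank correlations", g, n)
  }
  ann
}

#' Collapse feature-level rows to gene-level rows
#'
#' Microarray platforms carry several probe sets per gene; downstream edge
#' statistics are defined on genes. Features mapped to the same gene are
#' collapsed either by keeping the probe with the largest mean expression
#' across samples (`"max-mean"`, the default) or by averaging per sample
#' (`"mean"`). Unmapped features are dropped.
#'
#' @param mat Expression matrix (features x samples).
#' @param feature_to_gene Named character vector: names are feature ids,
#'   values are gene ids. Features absent from the map are dropped.
#' @param method `"max-mean"` or `"mean"`.
#' @return A gene-level expression matrix (one row per gene).
#' @export
collapse_features <- function(mat, feature_to_gene, method = c("max-mean", "mean")) {
  method <- match.arg(method)
  validate_expression(mat)
  if (length(feature_to_gene) == 0L) .stop_fmt("empty feature-to-gene mapping")
  if (is.null(names(feature_to_gene))) .stop_fmt("feature_to_gene must be a named character vector")
  keep <- rownames(mat)[rownames(mat) %in% names(feature_to_gene)]
  if (!length(keep)) .stop_fmt("no feature id in the matrix is present in the mapping")
  mat <- mat[keep, , drop = FALSE]
  gene <- unname(feature_to_gene[keep])
  if (method == "max-mean") {
    rowm <- rowMeans(mat)
    # within each gene keep the single probe with the largest mean
    ord <- order(gene, -rowm)
    first <- !duplicated(gene[ord])
    out <- mat[ord[first], , drop = FALSE]
    rownames(out) <- gene[ord][first]
  } else {
    out <- rowsum(mat, group = gene) / as.vector(table(gene)[sort(unique(gene))])
    out <- out[sort(unique(gene)), , drop = FALSE]
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  validate_expression(out)
  out
}

#' Assemble a longitudinal two-group dataset
#'
#' Joins an expression matrix with sample annotations into the container the
#' edge statistics operate on. The sample sets of the two inputs must match
#' exactly; nothing is dropped silently. The design is flagged `complete`
#' when, within each group, the same patients are observed at every
#' timepoint; incomplete designs are allowed (with a warning) and
#' per-timepoint correlations then use the patients present at each
#' timepoint.
#'
#' @param mat Gene-level expression matrix.
#' @param ann Validated annotation data frame (see [read_annotations()]).
#' @return An object of class `longitudinal_dataset`: a list with elements
#'   `matrix`, `annotations`, `timepoints`, `groups`, `complete`.
#' @export
assemble_dataset <- function(mat, ann) {
  validate_expression(mat)
  ann <- validate_annotations(ann)
  only_m <- setdiff(colnames(mat), ann$sample_id)
  only_a <- setdiff(ann$sample_id, colnames(mat))
  if (length(only_m) || length(only_a))
    .stop_fmt("sample sets differ: %d only in matrix (%s); %d only in annotations (%s)",
              length(only_m), .id_list(only_m), length(only_a), .id_list(only_a))
  ann <- ann[order(ann$group, ann$patient_id, ann$timepoint), , drop = FALSE]
  rownames(ann) <- NULL
  mat <- mat[, ann$sample_id, drop = FALSE]
  tps <- sort(unique(ann$timepoint))
  complete <- TRUE
  for (g in c("R", "NR")) {
    pats <- lapply(tps, function(t) sort(ann$patient_id[ann$group == g & ann$timepoint == t]))
    if (length(unique(vapply(pats, paste, "", collapse = "\r"))) > 1L) complete <- FALSE
  }
  if (!complete)
    .warn_fmt("incomplete longitudinal design: per-timepoint correlations will use the patients present at each timepoint")
  structure(list(matrix = mat, annotations = ann, timepoints = tps,
                 groups = c("R", "NR"), complete = complete),
            class = "longitudinal_dataset")
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  np <- table(unique(x$annotations[, c("patient_id", "group")])$group)
  cat("Longitudinal two-group expression dataset\n")
  cat(sprintf("  genes: %d   samples: %d\n", nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  patients: %d R + %d NR   timepoints: %s\n",
              np[["R"]], np[["NR"]], paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  complete design: %s\n", x$complete))
  invisible(x)
}

#' Genes of a longitudinal dataset
#' @param data A `longitudinal_dataset`.
#' @return Character vector of gene identifiers.
#' @export
dataset_genes <- function(data) rownames(data$matrix)
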