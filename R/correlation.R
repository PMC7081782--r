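#' Spearman rank correlation
#'
#' The Pearson correlation of mid-ranks (tied values receive their average
#' rank). A constant input vector has no rank ordering; the coefficient is
#' then undefined and `NA` is returned rather than an error, so callers can
#' exclude the affected cell explicitly.
#'
#' @param x,y Numeric vectors of equal length (>= 3), all values finite.
#' @return A correlation in [-1, 1], or `NA` when either vector is constant.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) .stop_fmt("x and y must have equal length")
  if (length(x) < 3L) .stop_fmt("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) .stop_fmt("inputs must be finite")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# ---- vectorized per-cell engine ------------------------------------------
#
# The whole method reduces to: for every (group, timepoint) cell, rank each
# gene across the patients in the cell and take Pearson correlations of rank
# columns for the edges of interest. Ranking once per cell and correlating
# all edges by column products makes the permutation test tractable.

# Column-standardized mid-ranks of M (genes x patients), restricted to
# columns `cols`. Returns patients x genes; constant genes give NaN columns.
.rank_z <- function(M, cols) {
  n <- length(cols)
  R <- apply(M[, cols, drop = FALSE], 1L, rank)  # patients x genes
  ctr <- sweep(R, 2L, colMeans(R))
  sdv <- sqrt(colSums(ctr^2) / (n - 1L))
  sweep(ctr, 2L, sdv, "/")
}

# Spearman coefficients for edges (ia, ib index gene rows of M) over the
# patient columns `cols`. NA when n < 3 or a gene is constant in the cell.
.cell_scc <- function(M, cols, ia, ib) {
  n <- length(cols)
  if (n < 3L) return(rep(NA_real_, length(ia)))
  Z <- .rank_z(M, cols)
  out <- colSums(Z[, ia, drop = FALSE] * Z[, ib, drop = FALSE]) / (n - 1L)
  out[!is.finite(out)] <- NA_real_
  unname(out)
}

# Precompute, per timepoint, the submatrix of genes touched by the edges and
# the patient id of every sample column. Shared by profiling and permutation.
.edge_prep <- function(data, net) {
  genes <- sort(unique(c(net$gene_a, net$gene_b)))
  missing <- setdiff(genes, dataset_genes(data))
  if (length(missing))
    .stop_fmt("network gene(s) absent from dataset: %s (restrict the network first)",
              .id_list(missing))
  ia <- match(net$gene_a, genes)
  ib <- match(net$gene_b, genes)
  ann <- data$annotations
  per_t <- lapply(data$timepoints, function(t) {
    sel <- ann$timepoint == t
    list(M = data$matrix[genes, ann$sample_id[sel], drop = FALSE],
         patient = ann$patient_id[sel])
  })
  names(per_t) <- as.character(data$timepoints)
  list(genes = genes, ia = ia, ib = ib, per_t = per_t,
       timepoints = data$timepoints)
}

# Evaluate all cells for one patient->group assignment (named char vector).
# Returns list(scc = list[[group]][[t]] numeric vector, n = matrix).
.profile_assignment <- function(prep, assignment, groups = c("R", "NR")) {
  scc <- list(); n_used <- list()
  for (g in groups) {
    scc[[g]] <- list(); n_used[[g]] <- list()
    for (tn in names(prep$per_t)) {
      cell <- prep$per_t[[tn]]
      cols <- which(assignment[cell$patient] == g)
      scc[[g]][[tn]] <- .cell_scc(cell$M, cols, prep$ia, prep$ib)
      n_used[[g]][[tn]] <- length(cols)
    }
  }
  list(scc = scc, n = n_used)
}

.group_assignment <- function(data) {
  pg <- unique(data$annotations[, c("patient_id", "group")])
  stats::setNames(pg$group, pg$patient_id)
}

#' Per-edge, per-cell Spearman correlation profiles
#'
#' For every edge of the reference network, computes the Spearman
#' correlation of the two genes separately within each group at each
#' timepoint, using the patients present in that (group, timepoint) cell.
#' Cells with fewer than 3 patients or a constant gene are undefined (`NA`).
#'
#' @param data A `longitudinal_dataset`.
#' @param net A `reference_network` already restricted to the dataset's
#'   genes (an error is raised otherwise).
#' @return An `edge_profiles` data frame: `gene_a`, `gene_b`, one
#'   `scc_<group>_t<t>` column per cell, and matching `n_<group>_t<t>`
#'   patient counts. Rows follow the canonical edge order of the network.
#' @export
profile_edges <- function(data, net) {
  stopifnot(inherits(data, "longitudinal_dataset"), inherits(net, "reference_network"))
  if (!nrow(net)) {
    out <- data.frame(gene_a = character(), gene_b = character())
    return(structure(out, class = c("edge_profiles", "data.frame"),
                     groups = data$groups, timepoints = data$timepoints))
  }
  prep <- .edge_prep(data, net)
  prof <- .profile_assignment(prep, .group_assignment(data), data$groups)
  out <- data.frame(gene_a = net$gene_a, gene_b = net$gene_b,
                    stringsAsFactors = FALSE)
  for (g in data$groups) for (tn in names(prep$per_t))
    out[[sprintf("scc_%s_t%s", g, tn)]] <- prof$scc[[g]][[tn]]
  for (g in data$groups) for (tn in names(prep$per_t))
    out[[sprintf("n_%s_t%s", g, tn)]] <- prof$n[[g]][[tn]]
  structure(out, class = c("edge_profiles", "data.frame"),
            groups = data$groups, timepoints = data$timepoints)
}

#' Coerce a table of per-cell correlations to `edge_profiles`
#'
#' Useful for published tables: a data frame with `gene_a`, `gene_b` and
#' `scc_R_t*` / `scc_NR_t*` columns becomes a profile object that
#' [detect_consistent()] accepts.
#'
#' @param df Data frame with `gene_a`, `gene_b` and `scc_<group>_t<t>` columns.
#' @param groups Group labels, default `c("R", "NR")`.
#' @param timepoints Integer timepoints; inferred from column names if `NULL`.
#' @return An `edge_profiles` object.
#' @export
as_edge_profiles <- function(df, groups = c("R", "NR"), timepoints = NULL) {
  if (is.null(timepoints)) {
    tt <- regmatches(names(df), regexec(sprintf("^scc_%s_t(\\d+)$", groups[1L]), names(df)))
    timepoints <- sort(as.integer(vapply(tt[lengths(tt) == 2L], `[`, "", 2L)))
    if (!length(timepoints)) .stop_fmt("no scc_%s_t<t> columns found", groups[1L])
  }
  for (g in groups) for (t in timepoints) {
    cn <- sprintf("scc_%s_t%d", g, t)
    if (is.null(df[[cn]])) .stop_fmt("missing column %s", cn)
  }
  structure(as.data.frame(df), class = c("edge_profiles", "data.frame"),
            groups = groups, timepoints = timepoints)
}

#' Write edge profiles as TSV
#'
#' Correlations are printed with 3 decimals (the dialect of published
#' tables); full precision is preserved in the in-memory object.
#'
#' @param profiles An `edge_profiles` object.
#' @param path Output path.
#' @export
write_edge_profiles <- function(profiles, path) {
  df <- as.data.frame(profiles)
  for (j in grep("^scc_", names(df))) df[[j]] <- round(df[[j]], 3L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
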