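#' Flag differentially correlated edges at one timepoint
#'
#' An edge is differentially correlated (a DCE) at timepoint `t` when the
#' absolute difference between its within-group correlations exceeds the
#' threshold `tau` (strictly, at full precision). When re-checking values
#' published at 3 decimals, a rounding tolerance `epsilon` relaxes the
#' comparison to `|delta| >= tau - epsilon`; it is 0 (off) by default.
#'
#' @param profiles An `edge_profiles` object.
#' @param t Timepoint index (must be one of the profiled timepoints).
#' @param tau Threshold on the absolute correlation difference, in (0, 2].
#' @param epsilon Rounding tolerance for published 3-decimal values
#'   (use 0.0005 for such tables); default 0.
#' @return Logical vector, one flag per edge row.
#' @export
flag_timepoint <- function(profiles, t, tau = 0.6, epsilon = 0) {
  stopifnot(inherits(profiles, "edge_profiles"), tau > 0, tau <= 2, epsilon >= 0)
  groups <- attr(profiles, "groups")
  if (!t %in% attr(profiles, "timepoints")) .stop_fmt("timepoint %s was not profiled", t)
  r <- profiles[[sprintf("scc_%s_t%d", groups[1L], t)]]
  nr <- profiles[[sprintf("scc_%s_t%d", groups[2L], t)]]
  if (anyNA(r) || anyNA(nr))
    .stop_fmt("undefined correlation cell(s) at timepoint %d; exclude those edges upstream (see detect_consistent)", t)
  d <- abs(r - nr)
  if (epsilon > 0) d >= tau - epsilon else d > tau
}

#' Detect consistent differentially correlated edges
#'
#' Applies the per-timepoint DCE flag at every timepoint and intersects:
#' an edge is a *consistent* DCE when it is differentially correlated at all
#' timepoints. Equivalently, the consistency statistic — the minimum over
#' timepoints of the absolute between-group correlation difference — exceeds
#' `tau`. Edges with any undefined cell are excluded from the table and
#' reported in the `"excluded"` attribute.
#'
#' @param profiles An `edge_profiles` object.
#' @param tau Threshold on the absolute correlation difference; default 0.6.
#' @param epsilon Rounding tolerance for published 3-decimal inputs; default 0.
#' @return A `dce_table` data frame with columns `gene_a`, `gene_b`,
#'   `delta_t<t>` (signed difference, first group minus second), per-timepoint
#'   flags `dce_t<t>`, `stat` (min over timepoints of `|delta|`),
#'   `consistent`, `category` (`same-sign`/`opposite-sign`/`mixed`, the sign
#'   relation of the two group correlations across timepoints) and `p_value`
#'   (`NA` until filled by [permutation_test()]). Attribute `"excluded"`
#'   lists edges dropped for undefined cells.
#' @export
detect_consistent <- function(profiles, tau = 0.6, epsilon = 0) {
  stopifnot(inherits(profiles, "edge_profiles"), tau >= 0, tau <= 2, epsilon >= 0)
  groups <- attr(profiles, "groups")
  tps <- attr(profiles, "timepoints")
  n <- nrow(profiles)
  out <- data.frame(gene_a = profiles$gene_a, gene_b = profiles$gene_b,
                    stringsAsFactors = FALSE)
  if (n == 0L) {
    empty <- structure(cbind(out, stat = numeric(0), consistent = logical(0),
                             category = character(0), p_value = numeric(0)),
                       class = c("dce_table", "data.frame"),
                       excluded = out, tau = tau, timepoints = tps)
    return(empty)
  }
  delta <- matrix(NA_real_, n, length(tps))
  samesign <- matrix(NA, n, length(tps))
  for (k in seq_along(tps)) {
    r <- profiles[[sprintf("scc_%s_t%d", groups[1L], tps[k])]]
    nr <- profiles[[sprintf("scc_%s_t%d", groups[2L], tps[k])]]
    delta[, k] <- r - nr
    samesign[, k] <- sign(r) * sign(nr)
  }
  defined <- rowSums(is.na(delta)) == 0L
  excluded <- out[!defined, , drop = FALSE]
  rownames(excluded) <- NULL
  out <- out[defined, , drop = FALSE]
  delta <- delta[defined, , drop = FALSE]
  samesign <- samesign[defined, , drop = FALSE]
  absd <- abs(delta)
  flags <- if (epsilon > 0) absd >= tau - epsilon else absd > tau
  stat <- apply(absd, 1L, min)
  for (k in seq_along(tps)) out[[sprintf("delta_t%d", tps[k])]] <- delta[, k]
  for (k in seq_along(tps)) out[[sprintf("dce_t%d", tps[k])]] <- flags[, k]
  out$stat <- stat
  out$consistent <- rowSums(flags) == length(tps)
  out$category <- ifelse(rowSums(samesign > 0) == length(tps), "same-sign",
                  ifelse(rowSums(samesign < 0) == length(tps), "opposite-sign", "mixed"))
  out$p_value <- NA_real_
  rownames(out) <- NULL
  structure(out, class = c("dce_table", "data.frame"),
            excluded = excluded, tau = tau, epsilon = epsilon, timepoints = tps)
}

#' Genes implicated by a set of edges
#'
#' @param records A `dce_table` (or any data frame with `gene_a`, `gene_b`
#'   and optionally `consistent`).
#' @param only_consistent Keep only rows flagged `consistent` (default TRUE;
#'   ignored if the column is absent).
#' @return Sorted character vector of distinct endpoint genes.
#' @export
unique_genes <- function(records, only_consistent = TRUE) {
  if (only_consistent && !is.null(records$consistent))
    records <- records[records$consistent, , drop = FALSE]
  sort(unique(c(records$gene_a, records$gene_b)))
}

#' Write a DCE table as TSV
#'
#' Mirrors the layout of published consistency tables: per-cell correlations
#' at 3 decimals, then the consistency statistic, flag, sign category and
#' permutation p-value.
#'
#' @param records A `dce_table`.
#' @param profiles The `edge_profiles` the table was derived from.
#' @param path Output path.
#' @export
write_dce_table <- function(records, profiles, path) {
  stopifnot(inherits(records, "dce_table"), inherits(profiles, "edge_profiles"))
  groups <- attr(profiles, "groups"); tps <- attr(profiles, "timepoints")
  key <- paste(profiles$gene_a, profiles$gene_b)
  idx <- match(paste(records$gene_a, records$gene_b), key)
  df <- data.frame(gene_a = records$gene_a, gene_b = records$gene_b,
                   stringsAsFactors = FALSE)
  for (t in tps) for (g in groups)
    df[[sprintf("scc_%s_t%d", g, t)]] <- round(profiles[[sprintf("scc_%s_t%d", g, t)]][idx], 3L)
  df$stat <- round(records$stat, 4L)
  df$consistent <- records$consistent
  df$category <- records$category
  df$p_value <- records$p_value
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
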