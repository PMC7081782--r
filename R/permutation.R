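#' Permute group labels at the patient level
#'
#' Reassigns the responder / non-responder labels across patients, keeping
#' the group sizes fixed. A patient's whole trajectory moves as a unit, so
#' within-patient dependence across timepoints is preserved under the null.
#' Uses the current RNG state.
#'
#' @param data A `longitudinal_dataset`.
#' @return A `longitudinal_dataset` with permuted group labels.
#' @export
permute_labels <- function(data) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  assign0 <- .group_assignment(data)
  perm <- stats::setNames(sample(unname(assign0)), names(assign0))
  ann <- data$annotations
  ann$group <- unname(perm[ann$patient_id])
  out <- data
  out$annotations <- ann
  out
}

# B random patient->group assignments (columns), sizes preserved.
.random_assignments <- function(assign0, B) {
  vapply(seq_len(B),
         function(i) stats::setNames(sample(unname(assign0)), names(assign0)),
         assign0)
}

# All C(n, n_R) distinct assignments (includes the observed one).
.all_assignments <- function(assign0) {
  patients <- names(assign0)
  nR <- sum(assign0 == "R")
  sets <- utils::combn(length(patients), nR)
  apply(sets, 2L, function(ix) {
    a <- stats::setNames(rep("NR", length(patients)), patients)
    a[ix] <- "R"
    a
  })
}

# Consistency statistic (min over timepoints of |delta scc|) for every edge
# under one assignment. NA when any cell is undefined.
.assignment_stats <- function(prep, assignment, groups = c("R", "NR")) {
  stat <- NULL
  for (tn in names(prep$per_t)) {
    cell <- prep$per_t[[tn]]
    colsR <- which(assignment[cell$patient] == groups[1L])
    colsN <- which(assignment[cell$patient] == groups[2L])
    d <- abs(.cell_scc(cell$M, colsR, prep$ia, prep$ib) -
             .cell_scc(cell$M, colsN, prep$ia, prep$ib))
    stat <- if (is.null(stat)) d else pmin(stat, d)
  }
  stat
}

#' Permutation test for consistent differential correlation
#'
#' For each candidate edge, compares the observed consistency statistic
#' (minimum over timepoints of the absolute between-group Spearman
#' difference) with its null distribution obtained by permuting patient
#' group labels and recomputing the statistic. One shared set of permuted
#' label assignments is evaluated for all edges by default
#' (`share_null = TRUE`); per-edge independent draws are available.
#'
#' With `exact = TRUE` all distinct label assignments are enumerated
#' (including the observed one) and the p-value is the exact proportion of
#' assignments whose statistic is at least the observed one; `B` is ignored.
#' If fewer distinct assignments exist than the requested `B`, Monte Carlo
#' mode falls back to full enumeration with a message. Permuted statistics
#' that are undefined (constant gene in a permuted cell) are counted as
#' exceedances, which is conservative.
#'
#' @param data A `longitudinal_dataset`.
#' @param net A `reference_network` restricted to the dataset's genes.
#' @param records A `dce_table` with the candidate edges (typically the
#'   consistent DCEs; any subset of profiled edges is accepted).
#' @param B Number of Monte Carlo permutations; default 10000.
#' @param mode `"add-one"` (p = (exceed + 1) / (B + 1), bounded away from 0)
#'   or `"plugin"` (p = exceed / B, can be exactly 0).
#' @param seed Integer seed; every random draw in the test flows from it.
#' @param exact Enumerate all label assignments instead of sampling.
#' @param share_null Evaluate one shared permutation set for all edges
#'   (default) or draw an independent set per edge.
#' @return A `permutation_results` data frame: `gene_a`, `gene_b`,
#'   `observed_stat`, `B` (permutations actually used), `exceed_count`,
#'   `p_value`, `mode`, `seed`.
#' @export
permutation_test <- function(data, net, records, B = 10000L,
                             mode = c("add-one", "plugin"), seed = 1L,
                             exact = FALSE, share_null = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "longitudinal_dataset"))
  if (!exact && !.is_count(B)) .stop_fmt("B must be a positive integer")
  if (nrow(records) == 0L)
    return(structure(data.frame(gene_a = character(), gene_b = character(),
                                observed_stat = numeric(), B = integer(),
                                exceed_count = integer(), p_value = numeric(),
                                mode = character(), seed = integer()),
                     class = c("permutation_results", "data.frame")))
  sub <- reference_network(data.frame(gene_a = records$gene_a,
                                      gene_b = records$gene_b, score = 1))
  # reference_network() sorts canonically; map rows back to `records` order
  prep <- .edge_prep(data, sub)
  ord <- match(paste(records$gene_a, records$gene_b),
               paste(sub$gene_a, sub$gene_b))
  assign0 <- .group_assignment(data)
  obs <- .assignment_stats(prep, assign0)[ord]

  n_all <- choose(length(assign0), sum(assign0 == "R"))
  if (!exact && n_all <= B) {
    message(sprintf("only %d distinct label assignments exist; enumerating all of them", n_all))
    exact <- TRUE
  }

  set.seed(seed)
  eval_block <- function(A) {
    # A: patients x assignments matrix; returns edges x assignments stats
    vapply(seq_len(ncol(A)), function(j) {
      a <- stats::setNames(A[, j], rownames(A))
      .assignment_stats(prep, a)[ord]
    }, numeric(length(ord)))
  }
  # Rank statistics are rational with coarse spacing; distinct assignments can
  # produce the same exact value through different floating-point paths, so
  # the exceedance comparison tolerates 1e-9 of rounding noise.
  count_exceed <- function(S, obs) {
    S[is.na(S)] <- Inf  # undefined permuted statistic counted as exceedance
    rowSums(S >= obs - 1e-9)
  }

  if (exact) {
    A <- .all_assignments(assign0)
    S <- matrix(eval_block(A), nrow = length(ord))
    exceed <- count_exceed(S, obs)
    used <- ncol(A)
    p <- exceed / used
    mode <- "exact"
  } else if (share_null) {
    A <- .random_assignments(assign0, B)
    S <- matrix(eval_block(A), nrow = length(ord))
    exceed <- count_exceed(S, obs)
    used <- B
    p <- if (mode == "add-one") (exceed + 1) / (B + 1) else exceed / B
  } else {
    exceed <- integer(length(ord))
    for (e in seq_along(ord)) {
      A <- .random_assignments(assign0, B)
      prep_e <- prep
      prep_e$ia <- prep$ia[ord[e]]; prep_e$ib <- prep$ib[ord[e]]
      S <- vapply(seq_len(B), function(j) {
        a <- stats::setNames(A[, j], rownames(A))
        .assignment_stats(prep_e, a)
      }, numeric(1L))
      S[is.na(S)] <- Inf
      exceed[e] <- sum(S >= obs[e] - 1e-9)
    }
    used <- B
    p <- if (mode == "add-one") (exceed + 1) / (B + 1) else exceed / B
  }

  structure(data.frame(gene_a = records$gene_a, gene_b = records$gene_b,
                       observed_stat = obs, B = used,
                       exceed_count = as.integer(exceed), p_value = p,
                       mode = mode, seed = as.integer(seed),
                       stringsAsFactors = FALSE),
            class = c("permutation_results", "data.frame"))
}

#' Select edges significant at a raw p-value cutoff
#'
#' Strict comparison `p < alpha`; no multiple-testing correction by default
#' (use [stats::p.adjust()] on the `p_value` column for a
#' Benjamini-Hochberg variant).
#'
#' @param results A `permutation_results` data frame (or a filled `dce_table`).
#' @param alpha Significance cutoff; default 0.01.
#' @return Data frame of significant edges (`gene_a`, `gene_b`).
#' @export
significant_edges <- function(results, alpha = 0.01) {
  stopifnot(.is_prob(alpha))
  keep <- !is.na(results$p_value) & results$p_value < alpha
  out <- data.frame(gene_a = results$gene_a[keep], gene_b = results$gene_b[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fill a DCE table's p-values from permutation results
#'
#' @param records A `dce_table`.
#' @param results A `permutation_results` data frame.
#' @param fdr Also add a Benjamini-Hochberg `q_value` column (default FALSE).
#' @return The `dce_table` with `p_value` (and optionally `q_value`) set for
#'   the tested edges.
#' @export
fill_p_values <- function(records, results, fdr = FALSE) {
  idx <- match(paste(records$gene_a, records$gene_b),
               paste(results$gene_a, results$gene_b))
  records$p_value <- results$p_value[idx]
  if (fdr) {
    records$q_value <- NA_real_
    records$q_value[!is.na(idx)] <- stats::p.adjust(results$p_value, "BH")[idx[!is.na(idx)]]
  }
  records
}
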