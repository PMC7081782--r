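#' Fit the consistent differential-correlation model
#'
#' The one-call interface to the whole edge-centric procedure:
#' \enumerate{
#'   \item keep reference edges with confidence strictly above
#'     `confidence` and both endpoints measured in the dataset;
#'   \item compute within-group Spearman correlations for every remaining
#'     edge at every timepoint;
#'   \item flag edges whose absolute between-group correlation difference
#'     exceeds `tau` at a timepoint, and call an edge a consistent
#'     differentially correlated edge (DCE) when it is flagged at every
#'     timepoint;
#'   \item assign each consistent DCE a permutation p-value by reshuffling
#'     patient group labels `B` times and recomputing the consistency
#'     statistic (the minimum over timepoints of the absolute difference);
#'   \item report the edges with `p < alpha` and the distinct genes they
#'     involve (the gene signature).
#' }
#'
#' @param data A `longitudinal_dataset` (see [assemble_dataset()]).
#' @param network A `reference_network` (see [read_string_edges()]).
#' @param tau Threshold on the absolute Spearman difference; default 0.6.
#' @param confidence Reference-network confidence cutoff; default 0.6.
#' @param B Number of permutations; default 10000.
#' @param alpha Significance cutoff on the permutation p-value; default 0.01.
#' @param mode Permutation p-value convention, `"add-one"` or `"plugin"`.
#' @param seed Integer seed driving the permutations.
#' @param epsilon Rounding tolerance for published 3-decimal inputs; default 0.
#' @param permute Set `FALSE` to skip the permutation stage (detection only).
#' @return An object of class `dce_fit` with elements `network` (the edges
#'   actually tested), `profiles`, `table` (the `dce_table`, p-values filled
#'   for consistent edges), `permutation` (`permutation_results` or `NULL`),
#'   `significant` (edges with `p < alpha`), `signature` (their distinct
#'   genes) and `config`.
#' @examples
#' spec <- synthetic_spec(n_patients = c(R = 9, NR = 9), n_timepoints = 5,
#'                        n_genes = 20, n_edges = 30,
#'                        planted = data.frame(gene_a = "G001", gene_b = "G002",
#'                                             rho_R = -0.8, rho_NR = 0.8),
#'                        seed = 7)
#' sim <- simulate_dce_study(spec)
#' fit <- dce(sim$dataset, sim$network, B = 99, seed = 7)
#' summary(fit)
#' @export
dce <- function(data, network, tau = 0.6, confidence = 0.6, B = 10000L,
                alpha = 0.01, mode = c("add-one", "plugin"), seed = 1L,
                epsilon = 0, permute = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "longitudinal_dataset"),
            inherits(network, "reference_network"))
  net <- restrict_to_genes(filter_by_confidence(network, confidence),
                           dataset_genes(data))
  profiles <- profile_edges(data, net)
  tab <- detect_consistent(profiles, tau = tau, epsilon = epsilon)
  cons <- tab[tab$consistent, , drop = FALSE]
  perm <- NULL
  if (permute && nrow(cons)) {
    perm <- permutation_test(data, net, cons, B = B, mode = mode, seed = seed)
    tab <- fill_p_values(tab, perm)
  }
  sig <- if (!is.null(perm)) significant_edges(perm, alpha) else
    data.frame(gene_a = character(), gene_b = character())
  structure(list(network = net, profiles = profiles, table = tab,
                 permutation = perm, significant = sig,
                 signature = sort(unique(c(sig$gene_a, sig$gene_b))),
                 config = list(tau = tau, confidence = confidence, B = B,
                               alpha = alpha, mode = mode, seed = seed,
                               epsilon = epsilon)),
            class = "dce_fit")
}

#' @export
print.dce_fit <- function(x, ...) {
  cat("Consistent differentially correlated edges (DCE) fit\n")
  cat(sprintf("  edges tested: %d (confidence > %g, %d excluded as undefined)\n",
              nrow(x$table), x$config$confidence, nrow(attr(x$table, "excluded"))))
  cat(sprintf("  consistent DCEs at tau = %g: %d\n",
              x$config$tau, sum(x$table$consistent)))
  if (!is.null(x$permutation))
    cat(sprintf("  significant at p < %g (%s, B = %d): %d edges, %d signature genes\n",
                x$config$alpha, x$config$mode, x$config$B,
                nrow(x$significant), length(x$signature)))
  invisible(x)
}

#' @export
summary.dce_fit <- function(object, ...) {
  tab <- object$table
  cons <- tab[tab$consistent, , drop = FALSE]
  out <- list(n_edges = nrow(tab),
              n_excluded = nrow(attr(tab, "excluded")),
              n_consistent = nrow(cons),
              n_significant = nrow(object$significant),
              signature = object$signature,
              categories = table(cons$category),
              config = object$config,
              top = cons[order(cons$p_value, -cons$stat), , drop = FALSE])
  class(out) <- "summary.dce_fit"
  out
}

#' @export
print.summary.dce_fit <- function(x, ...) {
  cat(sprintf("Edges tested: %d   excluded (undefined cells): %d\n",
              x$n_edges, x$n_excluded))
  cat(sprintf("Consistent DCEs (tau = %g): %d   significant (p < %g): %d\n",
              x$config$tau, x$n_consistent, x$config$alpha, x$n_significant))
  if (x$n_consistent) {
    cat("Sign categories among consistent DCEs:\n")
    print(x$categories)
    cat("Top consistent edges:\n")
    show <- utils::head(x$top[, c("gene_a", "gene_b", "stat", "category", "p_value")], 10L)
    print.data.frame(show, digits = 4)
  }
  if (length(x$signature))
    cat(sprintf("Signature (%d genes): %s\n", length(x$signature),
                .id_list(x$signature, 20L)))
  invisible(x)
}

#' Consistency statistics of a DCE fit
#'
#' @param object A `dce_fit`.
#' @param ... Unused.
#' @return Named numeric vector: per tested edge, the minimum over
#'   timepoints of the absolute between-group Spearman difference.
#' @export
coef.dce_fit <- function(object, ...) {
  stats::setNames(object$table$stat,
                  paste(object$table$gene_a, object$table$gene_b, sep = "--"))
}

#' Histogram of the consistency statistic
#'
#' Shows the distribution of the per-edge consistency statistic with the
#' detection threshold `tau` marked; consistent DCEs are the right tail.
#'
#' @param x A `dce_fit`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.dce_fit <- function(x, ...) {
  graphics::hist(x$table$stat, breaks = 30,
                 main = "Edge consistency statistic",
                 xlab = "min over timepoints of |Spearman difference|", ...)
  graphics::abline(v = x$config$tau, lty = 2)
  invisible(x)
}
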