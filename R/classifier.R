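#' Train a linear-margin classifier on a gene signature
#'
#' Fits a linear support vector machine on the signature genes, with one
#' training instance per sample (patient x timepoint) and features
#' standardized using training-set means and standard deviations only.
#' Posterior probabilities come from a Platt-style sigmoid fit to the
#' training decision scores (smoothed targets, so the fit stays finite on
#' separable data); the fit is fully deterministic.
#'
#' @param data A `longitudinal_dataset` (training set).
#' @param genes Signature gene identifiers; all must be present in `data`
#'   unless `on_missing = "intersect"`.
#' @param cost SVM regularization parameter C; default 1.
#' @param on_missing `"error"` (default) to fail listing absent genes, or
#'   `"intersect"` to drop them with a warning (validation platforms may
#'   lack genes).
#' @return An object of class `signature_model`: `genes`, `weights` (one per
#'   gene, on the standardized scale), `intercept`, `center`, `scale`,
#'   `calibration` (sigmoid intercept/slope on the decision score), `cost`.
#'   The decision rule is responder iff posterior >= 0.5.
#' @export
signature_svm <- function(data, genes, cost = 1,
                          on_missing = c("error", "intersect")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(data, "longitudinal_dataset"))
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) .stop_fmt("empty signature gene list")
  absent <- setdiff(genes, dataset_genes(data))
  if (length(absent)) {
    if (on_missing == "error")
      .stop_fmt("signature gene(s) absent from dataset: %s", .id_list(absent))
    .warn_fmt("dropping %d signature gene(s) absent from dataset: %s",
              length(absent), .id_list(absent))
    genes <- setdiff(genes, absent)
    if (!length(genes)) .stop_fmt("no signature gene is present in the dataset")
  }
  X <- t(data$matrix[genes, data$annotations$sample_id, drop = FALSE])
  y <- factor(data$annotations$group, levels = c("R", "NR"))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  fit <- e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)          # linear weights; positive score -> R
  b <- -fit$rho
  score <- drop(Xs %*% w) + b
  # Platt (1999) sigmoid with smoothed targets on the training scores
  nR <- sum(y == "R"); nN <- sum(y == "NR")
  targ <- ifelse(y == "R", (nR + 1) / (nR + 2), 1 / (nN + 2))
  cal <- suppressWarnings(stats::glm(targ ~ score, family = stats::quasibinomial()))
  cc <- unname(stats::coef(cal))
  if (cc[2L] < 0) {
    # libsvm's decision-value sign depends on label order; normalize so a
    # positive score always leans responder
    w <- -w; b <- -b; cc[2L] <- -cc[2L]
  }
  structure(list(genes = genes,
                 weights = stats::setNames(w[genes], genes),
                 intercept = b,
                 center = ctr[genes], scale = scl[genes],
                 calibration = stats::setNames(cc, c("intercept", "slope")),
                 cost = cost),
            class = "signature_model")
}

#' Score a longitudinal dataset with a signature model
#'
#' Scores every sample (patient x timepoint) of `newdata` and reports the
#' posterior probability of belonging to the responder group. A sample is
#' predicted responder iff its posterior is at least 0.5 (ties toward R).
#'
#' @param object A `signature_model`.
#' @param newdata A `longitudinal_dataset`.
#' @param on_missing `"error"` or `"intersect"` for genes the new platform
#'   lacks; with `"intersect"` the retained weights are used as-is, with a
#'   warning.
#' @param ... Unused.
#' @return A `prediction_report` data frame: `sample_id`, `patient_id`,
#'   `timepoint`, `true_group`, `posterior`, `predicted_group`; attributes
#'   `correct`, `total`, `accuracy`.
#' @export
predict.signature_model <- function(object, newdata,
                                    on_missing = c("error", "intersect"), ...) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(newdata, "longitudinal_dataset"))
  genes <- object$genes
  absent <- setdiff(genes, dataset_genes(newdata))
  if (length(absent)) {
    if (on_missing == "error")
      .stop_fmt("model gene(s) absent from new dataset: %s", .id_list(absent))
    .warn_fmt("scoring with %d of %d model genes (absent: %s)",
              length(genes) - length(absent), length(genes), .id_list(absent))
    genes <- setdiff(genes, absent)
    if (!length(genes)) .stop_fmt("no model gene resolvable in the new dataset")
  }
  ann <- newdata$annotations
  X <- t(newdata$matrix[genes, ann$sample_id, drop = FALSE])
  Xs <- scale(X, center = object$center[genes], scale = object$scale[genes])
  score <- drop(Xs %*% object$weights[genes]) + object$intercept
  cal <- object$calibration
  posterior <- stats::plogis(cal[["intercept"]] + cal[["slope"]] * score)
  predicted <- ifelse(posterior >= 0.5, "R", "NR")
  out <- data.frame(sample_id = ann$sample_id, patient_id = ann$patient_id,
                    timepoint = ann$timepoint, true_group = ann$group,
                    posterior = posterior, predicted_group = predicted,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  correct <- sum(out$predicted_group == out$true_group)
  structure(out, class = c("prediction_report", "data.frame"),
            correct = correct, total = nrow(out),
            accuracy = correct / nrow(out))
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Prediction report: %d / %d samples correct (accuracy %.2f%%)\n",
              attr(x, "correct"), attr(x, "total"), 100 * attr(x, "accuracy")))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more samples\n", nrow(x) - 10L))
  invisible(x)
}

#' Classification accuracy of a prediction report
#' @param report A `prediction_report`.
#' @return List with `correct`, `total`, `accuracy`.
#' @export
accuracy <- function(report) {
  list(correct = attr(report, "correct"), total = attr(report, "total"),
       accuracy = attr(report, "accuracy"))
}

#' @export
coef.signature_model <- function(object, ...) {
  c(object$weights, `(intercept)` = object$intercept)
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("Linear SVM signature model: %d genes, cost = %g\n",
              length(x$genes), x$cost))
  cat(sprintf("  genes: %s\n", .id_list(x$genes, 12L)))
  invisible(x)
}

#' Serialize a signature model to JSON
#' @param model A `signature_model`.
#' @param path Output path.
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  jsonlite::write_json(list(genes = model$genes,
                            weights = as.list(model$weights),
                            intercept = model$intercept,
                            center = as.list(model$center),
                            scale = as.list(model$scale),
                            calibration = as.list(model$calibration),
                            cost = model$cost),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature model from JSON
#' @param path Path written by [write_signature_model()].
#' @return A `signature_model`.
#' @export
read_signature_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(genes = j$genes,
                 weights = unlist(j$weights)[j$genes],
                 intercept = j$intercept,
                 center = unlist(j$center)[j$genes],
                 scale = unlist(j$scale)[j$genes],
                 calibration = unlist(j$calibration),
                 cost = j$cost),
            class = "signature_model")
}
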