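#' Assemble a run configuration
#'
#' Defaults follow the method's published operating point: correlation
#' difference threshold `tau = 0.6`, network confidence cutoff 0.6,
#' significance cutoff `alpha = 0.01`.
#'
#' @param expression,annotations,network Input file paths (TSV, optionally
#'   gzipped; see [read_expression()], [read_annotations()],
#'   [read_string_edges()]).
#' @param output_dir Directory for result files.
#' @param tau,confidence,B,alpha,mode,seed,epsilon See [dce()].
#' @param collapse Optional probe-collapsing method (`"max-mean"` or
#'   `"mean"`); requires `feature_map`.
#' @param feature_map Optional path to a two-column TSV mapping feature ids
#'   to gene ids.
#' @param score_scale Network score scale, `"raw-1000"` or `"unit"`.
#' @param group_aliases Named character vector of group-label aliases.
#' @return A `run_config` list.
#' @export
run_config <- function(expression, annotations, network, output_dir = ".",
                       tau = 0.6, confidence = 0.6, B = 10000L, alpha = 0.01,
                       mode = "add-one", seed = 1L, epsilon = 0,
                       collapse = NULL, feature_map = NULL,
                       score_scale = "unit", group_aliases = NULL) {
  cfg <- list(expression = expression, annotations = annotations,
              network = network, output_dir = output_dir, tau = tau,
              confidence = confidence, B = as.integer(B), alpha = alpha,
              mode = mode, seed = as.integer(seed), epsilon = epsilon,
              collapse = collapse, feature_map = feature_map,
              score_scale = score_scale, group_aliases = group_aliases)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' The file may contain any of the arguments of [run_config()]; `seed` is
#' mandatory.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) .stop_fmt("run config must set a seed")
  need <- c("expression", "annotations", "network")
  miss <- setdiff(need, names(y))
  if (length(miss)) .stop_fmt("run config lacks: %s", .id_list(miss))
  if (!is.null(y$group_aliases)) y$group_aliases <- unlist(y$group_aliases)
  do.call(run_config, y)
}

#' Run the full detection pipeline from files
#'
#' Reads the expression matrix, annotations and reference network, fits the
#' DCE model (see [dce()]) and writes the result files into
#' `config$output_dir`: `profiles.tsv` (per-cell correlations),
#' `dces.tsv` (DCE table with p-values), `signature_genes.txt`, and
#' `run_metadata.json` (configuration, package version, seed and input
#' checksums). All inputs are read and validated before any output file is
#' touched, so a failing run never partially overwrites previous results.
#'
#' @param config A `run_config` (or path to a YAML config file).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `dce_fit` and the output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("reading expression matrix: %s", config$expression)
  mat <- read_expression(config$expression)
  if (!is.null(config$collapse)) {
    if (is.null(config$feature_map)) .stop_fmt("collapse requested but no feature_map given")
    fm <- utils::read.table(config$feature_map, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    map <- stats::setNames(as.character(fm[[2L]]), as.character(fm[[1L]]))
    mat <- collapse_features(mat, map, method = config$collapse)
    say("collapsed to %d gene rows", nrow(mat))
  }
  ann <- read_annotations(config$annotations, group_aliases = config$group_aliases)
  data <- assemble_dataset(mat, ann)
  net <- read_string_edges(config$network, score_scale = config$score_scale)
  say("dataset: %d genes x %d samples; network: %d edges", nrow(data$matrix),
      ncol(data$matrix), nrow(net))

  fit <- dce(data, net, tau = config$tau, confidence = config$confidence,
             B = config$B, alpha = config$alpha, mode = config$mode,
             seed = config$seed, epsilon = config$epsilon)
  say("consistent DCEs: %d; significant: %d; signature genes: %d",
      sum(fit$table$consistent), nrow(fit$significant), length(fit$signature))

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(profiles = file.path(config$output_dir, "profiles.tsv"),
             dces = file.path(config$output_dir, "dces.tsv"),
             signature = file.path(config$output_dir, "signature_genes.txt"),
             metadata = file.path(config$output_dir, "run_metadata.json"))
  write_edge_profiles(fit$profiles, paths[["profiles"]])
  write_dce_table(fit$table, fit$profiles, paths[["dces"]])
  writeLines(fit$signature, paths[["signature"]])
  meta <- list(config = config[setdiff(names(config), "group_aliases")],
               package = "dcedge",
               version = as.character(utils::packageVersion("dcedge")),
               r_version = R.version.string,
               input_md5 = as.list(tools::md5sum(c(config$expression,
                                                   config$annotations,
                                                   config$network))),
               n_edges_tested = nrow(fit$table),
               n_consistent = sum(fit$table$consistent),
               n_significant = nrow(fit$significant),
               signature_size = length(fit$signature))
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(fit = fit, paths = paths))
}
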