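# Independent oracles and tiny fixture builders used across the suite.

# Brute-force Spearman: mid-ranks computed by counting comparisons, then the
# explicit covariance formula. Deliberately avoids rank() and cor().
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Consistency statistic for one patient->group labelling, computed the slow
# way: per cell, per edge, scalar spearman on extracted vectors.
oracle_stat <- function(data, edges, labels) {
  ann <- data$annotations
  tps <- data$timepoints
  stat <- rep(Inf, nrow(edges))
  for (t in tps) {
    sel <- ann$timepoint == t
    sid <- ann$sample_id[sel]; pat <- ann$patient_id[sel]
    for (e in seq_len(nrow(edges))) {
      sR <- sid[labels[pat] == "R"]; sN <- sid[labels[pat] == "NR"]
      d <- abs(spearman(data$matrix[edges$gene_a[e], sR], data$matrix[edges$gene_b[e], sR]) -
               spearman(data$matrix[edges$gene_a[e], sN], data$matrix[edges$gene_b[e], sN]))
      stat[e] <- min(stat[e], d)
    }
  }
  stat
}

# Exhaustive permutation p-values over all C(n, nR) labellings.
oracle_exact_perm <- function(data, edges) {
  pg <- unique(data$annotations[, c("patient_id", "group")])
  patients <- pg$patient_id
  nR <- sum(pg$group == "R")
  obs <- oracle_stat(data, edges, setNames(pg$group, patients))
  sets <- combn(length(patients), nR)
  exceed <- integer(nrow(edges))
  for (j in seq_len(ncol(sets))) {
    lab <- setNames(rep("NR", length(patients)), patients)
    lab[sets[, j]] <- "R"
    s <- oracle_stat(data, edges, lab)
    exceed <- exceed + (s >= obs - 1e-9)  # same rounding-noise tolerance as the engine
  }
  list(exceed = exceed, total = ncol(sets), p = exceed / ncol(sets))
}

# Small hand-built longitudinal dataset: G genes, independent noise.
make_dataset <- function(n_R = 4, n_NR = 4, n_t = 2, genes = paste0("g", 1:4),
                         seed = 1) {
  set.seed(seed)
  pats <- c(sprintf("R%02d", seq_len(n_R)), sprintf("N%02d", seq_len(n_NR)))
  grp <- rep(c("R", "NR"), c(n_R, n_NR))
  ann <- do.call(rbind, lapply(seq_len(n_t), function(t)
    data.frame(sample_id = paste0(pats, "_t", t), patient_id = pats,
               timepoint = t, group = grp, stringsAsFactors = FALSE)))
  mat <- matrix(rnorm(length(genes) * nrow(ann)), length(genes),
                dimnames = list(genes, ann$sample_id))
  assemble_dataset(mat, ann)
}

make_net <- function(pairs, score = 0.9) {
  reference_network(data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                               score = score))
}

# Hand-built edge_profiles from a matrix of per-cell correlations.
make_profiles <- function(gene_a, gene_b, scc_R, scc_NR) {
  df <- data.frame(gene_a = gene_a, gene_b = gene_b, stringsAsFactors = FALSE)
  for (t in seq_len(ncol(scc_R))) {
    df[[paste0("scc_R_t", t)]] <- scc_R[, t]
    df[[paste0("scc_NR_t", t)]] <- scc_NR[, t]
  }
  as_edge_profiles(df, timepoints = seq_len(ncol(scc_R)))
}
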