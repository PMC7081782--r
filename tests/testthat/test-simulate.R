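test_that("the Spearman-to-Pearson bridge matches its closed form", {
  expect_equal(spearman_to_pearson(0), 0)
  expect_equal(spearman_to_pearson(1), 1)
  expect_equal(spearman_to_pearson(-1), -1)
  expect_equal(spearman_to_pearson(0.5), 2 * sin(pi / 12))
  expect_error(spearman_to_pearson(1.2), "\\[-1, 1\\]")
})

test_that("simulation is bit-identical under a fixed seed", {
  spec <- synthetic_spec(n_patients = c(R = 4, NR = 4), n_timepoints = 3,
                         n_genes = 10, n_edges = 15, seed = 12)
  a <- simulate_dce_study(spec)
  b <- simulate_dce_study(spec)
  expect_identical(a$dataset$matrix, b$dataset$matrix)
  expect_identical(as.data.frame(a$network), as.data.frame(b$network))
  expect_error(synthetic_spec(seed = NULL), "seed")
})

test_that("planted Spearman targets are met and null edges stay near zero", {
  planted <- data.frame(gene_a = c("G001", "G003"), gene_b = c("G002", "G004"),
                        rho_R = c(0.7, -0.5), rho_NR = c(-0.2, 0.4))
  spec <- synthetic_spec(n_patients = c(R = 2000, NR = 2000), n_timepoints = 1,
                         n_genes = 20, n_edges = 102, planted = planted,
                         seed = 77)
  sim <- simulate_dce_study(spec)
  prof <- profile_edges(sim$dataset, sim$network)
  key <- paste(prof$gene_a, prof$gene_b)
  for (k in seq_len(nrow(planted))) {
    row <- which(key == paste(planted$gene_a[k], planted$gene_b[k]))
    expect_lt(abs(prof$scc_R_t1[row] - planted$rho_R[k]), 0.03)
    expect_lt(abs(prof$scc_NR_t1[row] - planted$rho_NR[k]), 0.03)
  }
  null_rows <- !key %in% paste(planted$gene_a, planted$gene_b)
  expect_gte(sum(null_rows), 100L)
  expect_lt(mean(abs(prof$scc_R_t1[null_rows])), 0.1)
  expect_lt(mean(abs(prof$scc_NR_t1[null_rows])), 0.1)
})

test_that("values sit on a log2-expression-like scale and planted edges join the network", {
  spec <- synthetic_spec(n_patients = c(R = 30, NR = 30), n_timepoints = 2,
                         n_genes = 12, n_edges = 12,
                         planted = data.frame(gene_a = "G011", gene_b = "G012",
                                              rho_R = 0.9, rho_NR = -0.9),
                         mean_shift = c(G001 = 1.5), noise_sd = 1.2, seed = 9)
  sim <- simulate_dce_study(spec)
  expect_true("G011 G012" %in% paste(sim$network$gene_a, sim$network$gene_b))
  m <- sim$dataset$matrix
  expect_lt(abs(mean(m[-1, ]) - 8), 0.3)
  expect_lt(abs(sd(m["G002", ]) - 1.2), 0.4)
  ann <- sim$dataset$annotations
  shift_hat <- mean(m["G001", ann$sample_id[ann$group == "R"]]) -
               mean(m["G001", ann$sample_id[ann$group == "NR"]])
  expect_lt(abs(shift_hat - 1.5), 0.8)
})

test_that("an infeasible planted pattern is rejected, not silently distorted", {
  planted <- data.frame(gene_a = c("G001", "G002", "G001"),
                        gene_b = c("G002", "G003", "G003"),
                        rho_R = c(0.95, 0.95, -0.95), rho_NR = 0)
  spec <- synthetic_spec(n_patients = c(R = 5, NR = 5), n_timepoints = 1,
                         n_genes = 5, n_edges = 5, planted = planted, seed = 3)
  expect_error(simulate_dce_study(spec), "infeasible")
})

test_that("the patient latent factor induces across-timepoint dependence only when asked", {
  base <- list(n_patients = c(R = 200, NR = 200), n_timepoints = 2,
               n_genes = 4, n_edges = 4, seed = 55)
  indep <- simulate_dce_study(do.call(synthetic_spec, base))
  ac <- simulate_dce_study(do.call(synthetic_spec, c(base, autocorrelation = 0.8)))
  cor_t <- function(sim) {
    ann <- sim$dataset$annotations
    m <- sim$dataset$matrix
    s1 <- ann$sample_id[ann$timepoint == 1]
    s2 <- ann$sample_id[ann$timepoint == 2]
    cor(m["G001", s1], m["G001", s2])
  }
  expect_lt(abs(cor_t(indep)), 0.15)
  expect_gt(cor_t(ac), 0.6)
})

test_that("written studies re-enter the pipeline unchanged", {
  spec <- synthetic_spec(n_patients = c(R = 4, NR = 4), n_timepoints = 2,
                         n_genes = 8, n_edges = 10, seed = 14)
  sim <- simulate_dce_study(spec)
  dir <- tempfile()
  paths <- write_study(sim, dir)
  mat <- read_expression(paths[["expression"]])
  ann <- read_annotations(paths[["annotations"]])
  net <- read_string_edges(paths[["network"]], "unit")
  d2 <- assemble_dataset(mat, ann)
  expect_equal(d2$matrix[rownames(sim$dataset$matrix), colnames(sim$dataset$matrix)],
               sim$dataset$matrix, tolerance = 1e-12)
  expect_equal(as.data.frame(net), as.data.frame(sim$network))
})
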