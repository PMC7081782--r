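test_that("patient-level relabeling preserves group sizes and cell counts", {
  d <- make_dataset(n_R = 5, n_NR = 4, n_t = 3, seed = 17)
  counts0 <- table(d$annotations$group, d$annotations$timepoint)
  set.seed(1)
  for (i in 1:100) {
    p <- permute_labels(d)
    expect_identical(table(p$annotations$group, p$annotations$timepoint), counts0)
    # a patient's label is constant across timepoints
    pg <- unique(p$annotations[, c("patient_id", "group")])
    expect_false(any(duplicated(pg$patient_id)))
  }
})

test_that("exact enumeration on 4+4 patients equals the exhaustive oracle edge by edge", {
  d <- make_dataset(n_R = 4, n_NR = 4, n_t = 2, genes = paste0("g", 1:5), seed = 23)
  net <- make_net(t(combn(paste0("g", 1:5), 2)))
  prof <- profile_edges(d, net)
  rec <- detect_consistent(prof, tau = 0)   # keep all 10 edges as candidates
  res <- suppressMessages(permutation_test(d, net, rec, exact = TRUE, seed = 1))
  expect_equal(unique(res$B), choose(8, 4))
  oracle <- oracle_exact_perm(d, rec)
  expect_identical(res$exceed_count, as.integer(oracle$exceed))
  expect_equal(res$p_value, oracle$p)
  expect_true(all(res$exceed_count >= 1))   # the observed labelling is included
})

test_that("Monte Carlo mode is seed-deterministic and respects the p-value convention", {
  d <- make_dataset(n_R = 4, n_NR = 4, n_t = 2, genes = paste0("g", 1:4), seed = 5)
  net <- make_net(cbind(c("g1", "g2"), c("g3", "g4")))
  rec <- detect_consistent(profile_edges(d, net), tau = 0)
  r1 <- permutation_test(d, net, rec, B = 50, seed = 99)
  r2 <- permutation_test(d, net, rec, B = 50, seed = 99)
  expect_identical(r1$exceed_count, r2$exceed_count)
  expect_equal(r1$p_value, (r1$exceed_count + 1) / 51)
  r3 <- permutation_test(d, net, rec, B = 50, seed = 99, mode = "plugin")
  expect_identical(r3$exceed_count, r1$exceed_count)
  expect_equal(r3$p_value, r3$exceed_count / 50)
  expect_error(permutation_test(d, net, rec, B = 0, seed = 1), "positive integer")
})

test_that("a zero observed statistic has permutation p-value 1", {
  # clone each responder as a non-responder: group correlations are equal at
  # every timepoint, so the observed min |delta| is exactly 0
  d <- make_dataset(n_R = 3, n_NR = 3, n_t = 2, genes = c("g1", "g2"), seed = 2)
  ann <- d$annotations
  mat <- d$matrix
  for (k in 1:3) {
    mat[, ann$sample_id[ann$patient_id == sprintf("N%02d", k)]] <-
      mat[, ann$sample_id[ann$patient_id == sprintf("R%02d", k)]]
  }
  d2 <- assemble_dataset(mat, ann)
  net <- make_net(cbind("g1", "g2"))
  rec <- detect_consistent(profile_edges(d2, net), tau = 0)
  expect_equal(rec$stat, 0)
  res <- permutation_test(d2, net, rec, B = 19, seed = 3)
  expect_equal(res$p_value, 1)
})

test_that("requesting more draws than distinct assignments falls back to enumeration", {
  d <- make_dataset(n_R = 3, n_NR = 3, n_t = 2, genes = c("g1", "g2"), seed = 4)
  net <- make_net(cbind("g1", "g2"))
  rec <- detect_consistent(profile_edges(d, net), tau = 0)
  expect_message(res <- permutation_test(d, net, rec, B = 1000, seed = 1),
                 "enumerating")
  expect_equal(unique(res$B), choose(6, 3))
  expect_equal(unique(res$mode), "exact")
})

test_that("significant_edges applies a strict cutoff", {
  res <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                    p_value = c(0.009, 0.01))
  expect_equal(significant_edges(res, 0.01)$gene_a, "A")
  expect_equal(nrow(significant_edges(res, 0)), 0L)
  expect_equal(nrow(significant_edges(res, 1)), 2L)
})

test_that("per-edge independent nulls agree with the shared null in distribution", {
  d <- make_dataset(n_R = 4, n_NR = 4, n_t = 2, genes = paste0("g", 1:3), seed = 6)
  net <- make_net(cbind("g1", "g2"))
  rec <- detect_consistent(profile_edges(d, net), tau = 0)
  shared <- permutation_test(d, net, rec, B = 60, seed = 8)
  indep <- permutation_test(d, net, rec, B = 60, seed = 8, share_null = FALSE)
  expect_equal(nrow(indep), 1L)
  expect_lt(abs(shared$p_value - indep$p_value), 0.3)
})
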