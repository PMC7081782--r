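test_that("per-timepoint flags match the worked-example rows", {
  tab <- table1_fixture()
  prof <- as_edge_profiles(tab)
  f1 <- flag_timepoint(prof, 1, tau = 0.6)
  # ADCY1-AKT1 at t1: |-0.567 - 0.65| = 1.217 > 0.6
  expect_true(f1[tab$gene_a == "ADCY1"])
  # IL2RA-IL2RB at t2: |Delta| = 0.600 at printed precision -> needs the
  # published-value tolerance; fails the strict full-precision comparison
  i <- which(tab$gene_a == "IL2RA")
  expect_false(flag_timepoint(prof, 2, tau = 0.6)[i])
  expect_true(flag_timepoint(prof, 2, tau = 0.6, epsilon = 0.0005)[i])

  same <- make_profiles("A", "B", matrix(0.5, 1, 2), matrix(0.5, 1, 2))
  expect_false(any(flag_timepoint(same, 1, tau = 0.01)))
})

test_that("consistency requires the threshold to hold at every timepoint", {
  delta <- c(0.9, 0.9, 0.9, 0.9, 0.5)
  prof <- make_profiles("A", "B", matrix(delta, 1), matrix(0, 1, 5))
  rec <- detect_consistent(prof, tau = 0.6)
  expect_false(rec$consistent)
  expect_equal(rec$stat, 0.5)

  full <- make_profiles("A", "B", matrix(0.9, 1, 5), matrix(0, 1, 5))
  rec <- detect_consistent(full, tau = 0.6)
  expect_true(rec$consistent)
  expect_equal(rec$stat, 0.9)
  expect_true(rec$stat > 0.6)
})

test_that("a zero threshold keeps every edge with nonzero deltas", {
  set.seed(21)
  prof <- make_profiles(paste0("a", 1:6), paste0("b", 1:6),
                        matrix(runif(18, -1, 1), 6), matrix(runif(18, -1, 1), 6))
  rec <- detect_consistent(prof, tau = 0)
  expect_true(all(rec$consistent == (rec$stat > 0)))
  expect_true(all(rec$consistent))
})

test_that("edges with undefined cells are excluded and reported", {
  sccR <- matrix(0.9, 2, 3); sccN <- matrix(0, 2, 3)
  sccR[2, 2] <- NA
  prof <- make_profiles(c("A", "C"), c("B", "D"), sccR, sccN)
  rec <- detect_consistent(prof, tau = 0.6)
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "excluded")$gene_a, "C")
  expect_error(flag_timepoint(prof, 2, 0.6), "undefined")
})

test_that("stat > tau is equivalent to consistency, and both are monotone", {
  set.seed(33)
  for (rep in 1:20) {
    n_e <- sample(3:8, 1); n_t <- sample(2:5, 1)
    prof <- make_profiles(sprintf("a%02d", 1:n_e), sprintf("b%02d", 1:n_e),
                          matrix(runif(n_e * n_t, -1, 1), n_e),
                          matrix(runif(n_e * n_t, -1, 1), n_e))
    taus <- sort(runif(3, 0, 1.5))
    sets <- lapply(taus, function(tau) {
      rec <- detect_consistent(prof, tau = tau)
      expect_identical(rec$consistent, rec$stat > tau)
      which(rec$consistent)
    })
    # monotone in tau
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
    # dropping a timepoint never shrinks the consistent set
    if (n_t > 2) {
      drop_t <- sample(n_t, 1)
      keep <- setdiff(seq_len(n_t), drop_t)
      sub <- make_profiles(sprintf("a%02d", 1:n_e), sprintf("b%02d", 1:n_e),
                           sapply(keep, function(t) prof[[paste0("scc_R_t", t)]]),
                           sapply(keep, function(t) prof[[paste0("scc_NR_t", t)]]))
      s_full <- which(detect_consistent(prof, 0.6)$consistent)
      s_sub <- which(detect_consistent(sub, 0.6)$consistent)
      expect_true(all(s_full %in% s_sub))
    }
    # permuting timepoint labels leaves the consistent set unchanged
    ptv <- sample(n_t)
    shuf <- make_profiles(sprintf("a%02d", 1:n_e), sprintf("b%02d", 1:n_e),
                          sapply(ptv, function(t) prof[[paste0("scc_R_t", t)]]),
                          sapply(ptv, function(t) prof[[paste0("scc_NR_t", t)]]))
    expect_identical(detect_consistent(shuf, 0.6)$consistent,
                     detect_consistent(prof, 0.6)$consistent)
  }
})

test_that("unique_genes de-duplicates shared endpoints", {
  rec <- data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "C", "C"),
                    consistent = TRUE)
  expect_equal(unique_genes(rec), c("A", "B", "C"))
  expect_equal(unique_genes(data.frame(gene_a = "X", gene_b = "Y")), c("X", "Y"))
  chk <- check_table1()
  expect_equal(chk$n_genes, 41L)
  expect_true(all(c("EP300", "DYNC1H1", "PCNT", "IL2RA", "CXCL9") %in% chk$genes))
})

test_that("sign categories label the group correlation directions", {
  prof <- make_profiles(c("A", "C", "E"), c("B", "D", "F"),
                        matrix(c(0.9, 0.9, 0.9, 0.9, -0.9, 0.9), 3, 2),
                        matrix(c(0.1, -0.3, -0.1, 0.2, -0.2, -0.4), 3, 2))
  rec <- detect_consistent(prof, tau = 0)
  expect_equal(rec$category, c("same-sign", "mixed", "opposite-sign"))
})
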