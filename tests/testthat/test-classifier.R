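# Two independent studies with a strong planted mean shift (2 within-group
# SDs on 10 genes) used across the classifier tests.
sig_genes <- sprintf("G%03d", 1:10)
shift <- setNames(rep(2, 10), sig_genes)
train_sim <- simulate_dce_study(
  synthetic_spec(n_patients = c(R = 9, NR = 9), n_timepoints = 5,
                 n_genes = 15, n_edges = 20, mean_shift = shift, seed = 401))
valid_sim <- simulate_dce_study(
  synthetic_spec(n_patients = c(R = 12, NR = 9), n_timepoints = 3,
                 n_genes = 15, n_edges = 20, mean_shift = shift, seed = 402))

test_that("training uses one instance per sample and separates a shifted pair", {
  model <- signature_svm(train_sim$dataset, sig_genes)
  expect_length(model$weights, 10L)
  expect_equal(nrow(train_sim$dataset$annotations), 90L)  # 18 patients x 5 tp
  rep <- predict(model, train_sim$dataset)
  expect_equal(accuracy(rep)$accuracy, 1.0)
  model2 <- signature_svm(train_sim$dataset, sig_genes)
  expect_equal(model$weights, model2$weights, tolerance = 1e-8)
  expect_equal(coef(model)[["(intercept)"]], model$intercept)
})

test_that("validation scoring covers every sample-timepoint and generalizes", {
  model <- signature_svm(train_sim$dataset, sig_genes)
  rep <- predict(model, valid_sim$dataset)
  expect_equal(attr(rep, "total"), 63L)                  # 21 patients x 3 tp
  expect_equal(nrow(rep), 63L)
  expect_true(all(rep$posterior >= 0 & rep$posterior <= 1))
  expect_gt(accuracy(rep)$accuracy, 0.9)
  expect_identical(rep$predicted_group, ifelse(rep$posterior >= 0.5, "R", "NR"))
})

test_that("scaling comes from the training data only (no leakage)", {
  model <- signature_svm(train_sim$dataset, sig_genes)
  mutated <- valid_sim$dataset
  mutated$matrix <- mutated$matrix * 3 + 1
  model_after <- signature_svm(train_sim$dataset, sig_genes)
  expect_identical(model$weights, model_after$weights)
  expect_identical(model$center, model_after$center)
})

test_that("missing signature genes error or intersect as requested", {
  genes <- c(sig_genes, "NOT_A_GENE")
  expect_error(signature_svm(train_sim$dataset, genes), "NOT_A_GENE")
  expect_warning(model <- signature_svm(train_sim$dataset, genes,
                                        on_missing = "intersect"),
                 "NOT_A_GENE")
  expect_length(model$genes, 10L)
  small <- valid_sim$dataset
  small$matrix <- small$matrix[setdiff(rownames(small$matrix), "G003"), ]
  expect_error(predict(model, small), "G003")
  expect_warning(rep <- predict(model, small, on_missing = "intersect"), "G003")
  expect_gt(accuracy(rep)$accuracy, 0.8)
})

test_that("label-swapping the model complements the posteriors", {
  model <- signature_svm(train_sim$dataset, sig_genes)
  swapped <- model
  swapped$weights <- -model$weights
  swapped$intercept <- -model$intercept
  swapped$calibration[["intercept"]] <- -model$calibration[["intercept"]]
  p <- predict(model, valid_sim$dataset)$posterior
  q <- predict(swapped, valid_sim$dataset)$posterior
  expect_equal(q, 1 - p, tolerance = 1e-12)
})

test_that("posteriors are monotone in the decision score", {
  model <- signature_svm(train_sim$dataset, sig_genes)
  d <- valid_sim$dataset
  Xs <- scale(t(d$matrix[model$genes, d$annotations$sample_id]),
              center = model$center, scale = model$scale)
  score <- drop(Xs %*% model$weights) + model$intercept
  post <- predict(model, d)$posterior
  ord <- order(score)
  expect_true(all(diff(post[ord]) >= 0))
})

test_that("JSON serialization round-trips the model and its predictions", {
  model <- signature_svm(train_sim$dataset, sig_genes)
  path <- tempfile(fileext = ".json")
  write_signature_model(model, path)
  back <- read_signature_model(path)
  expect_equal(back$weights, model$weights)
  expect_equal(predict(back, valid_sim$dataset)$posterior,
               predict(model, valid_sim$dataset)$posterior)
})
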