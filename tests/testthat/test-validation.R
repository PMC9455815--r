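# Small planted benchmark shared across validation tests.
make_bench <- function(seed = 1) {
  lib <- generate_clustered_library(3, 6, 128, 0.05, seed = seed)
  ds <- generate_planted_dti(lib$clusters, 4, 0.9, seed = seed)
  list(lib = lib, ds = ds, pred = predictor_simspread(lib$features))
}

test_that("leave-one-out produces one evaluation unit per drug", {
  b <- make_bench()
  rep <- loocv(b$ds, b$pred)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(tidy(rep)), length(b$ds$drugs))
  expect_setequal(tidy(rep)$unit, b$ds$drugs)
})

test_that("a target whose only ligand is held out is masked for that drug", {
  # d1 is the sole ligand of t_only; when d1 is held out, t_only has no
  # training edge and must not count as a positive or negative for d1
  feats <- matrix(rbinom(4 * 32, 1, 0.3), 4,
    dimnames = list(paste0("d", 1:4), NULL)
  )
  ds <- interaction_dataset(
    data.frame(
      drug = c("d1", "d1", "d2", "d3", "d4"),
      target = c("t_only", "t_shared", "t_shared", "t_shared", "t_shared")
    )
  )
  rep <- loocv(ds, predictor_simspread(feats, alpha = 0))
  row <- tidy(rep)[tidy(rep)$unit == "d1", ]
  # d1's evaluable panel is only t_shared -> one positive, zero negatives
  expect_equal(row$n_pos, 1)
  expect_equal(row$n_neg, 0)
  expect_false(row$evaluable)
})

test_that("loocv rows equal hand-run predict + evaluate composition", {
  b <- make_bench(3)
  rep <- loocv(b$ds, b$pred)
  for (d in b$ds$drugs[c(1, 7, 15)]) {
    train <- subset_drugs(b$ds, setdiff(b$ds$drugs, d))
    preds <- simspread_predict(train, b$lib$features, b$lib$features[d, , drop = FALSE])
    sc <- score_vector(preds, d, b$ds$targets)
    labels <- as.integer(b$ds$targets %in% b$ds$edges$target[b$ds$edges$drug == d])
    mask <- b$ds$targets %in% train$edges$target
    want <- evaluate_ranking(sc, labels, mask = mask, k = 20)
    got <- tidy(rep)[tidy(rep)$unit == d, names(want)]
    expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-12)
  }
})

test_that("k-fold partitions are near-equal, disjoint and seed-stable", {
  ids <- sprintf("d%02d", 1:23)
  parts <- simspread:::partition_ids(ids, 5, seed = 9)
  expect_equal(sort(unname(unlist(parts))), sort(ids))
  sizes <- lengths(parts)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(parts, simspread:::partition_ids(ids, 5, seed = 9))
  expect_error(simspread:::partition_ids(ids, 24, 1), "folds")
})

test_that("repeated k-fold is reproducible and reports both granularities", {
  b <- make_bench(5)
  r1 <- repeated_kfold(b$ds, b$pred, folds = 3, repeats = 2, seed = 11)
  r2 <- repeated_kfold(b$ds, b$pred, folds = 3, repeats = 2, seed = 11)
  expect_equal(tidy(r1), tidy(r2))
  expect_equal(r1$per_drug, r2$per_drug)
  expect_equal(nrow(tidy(r1)), 3 * 2)
  # per-fold value is the mean over the fold's evaluable drugs
  pf <- tidy(r1)[1, ]
  pd <- r1$per_drug
  sel <- pd$repeat_ == pf$repeat_ & pd$fold == pf$fold & pd$evaluable
  expect_equal(pf$auroc, mean(pd$auroc[sel], na.rm = TRUE))
  # every repeat covers every drug exactly once
  counts <- table(r1$per_drug$repeat_, r1$per_drug$unit)
  expect_true(all(counts == 1))
})

test_that("interaction-holdout CV evaluates only drugs retaining training edges", {
  ds <- random_dataset(8, 5, 22, seed = 7)
  rep <- suppressMessages(
    dti_holdout_kfold(ds, predictor_nbi(), folds = 4, repeats = 2, seed = 3)
  )
  pd <- rep$per_drug
  expect_gt(nrow(pd), 0)
  # every evaluated drug kept at least one training edge in its fold
  for (i in seq_len(min(nrow(pd), 20))) {
    parts <- simspread:::partition_ids(seq_len(nrow(ds$edges)), 4, seed = 3 + pd$repeat_[i] - 1)
    held <- ds$edges[sort(parts[[pd$fold[i]]]), ]
    train <- remove_edges(ds, held)
    expect_true(pd$unit[i] %in% train$edges$drug)
  }
  expect_equal(
    tidy(suppressMessages(dti_holdout_kfold(ds, predictor_nbi(), 4, 2, seed = 3))),
    tidy(rep)
  )
})

test_that("time-split validation skips test drugs without shared positives", {
  b <- make_bench(9)
  train_raw <- subset_drugs(b$ds, b$ds$drugs[1:12])
  test_raw <- structure(
    list(
      drugs = b$ds$drugs[13:18], targets = b$ds$targets,
      edges = dplyr::filter(b$ds$edges, drug %in% b$ds$drugs[13:18])
    ),
    class = "interaction_dataset"
  )
  sp <- time_split(train_raw, test_raw)
  rep <- suppressMessages(time_split_validate(sp$train, sp$test, b$pred))
  expect_setequal(tidy(rep)$unit, unique(sp$test$edges$drug))
  # deterministic given fixed inputs
  rep2 <- suppressMessages(time_split_validate(sp$train, sp$test, b$pred))
  expect_equal(tidy(rep), tidy(rep2))
  # manual composition for one drug
  d <- tidy(rep)$unit[1]
  preds <- simspread_predict(sp$train, b$lib$features, b$lib$features[d, , drop = FALSE])
  labels <- as.integer(sp$train$targets %in% sp$test$edges$target[sp$test$edges$drug == d])
  mask <- sp$train$targets %in% sp$train$edges$target
  want <- evaluate_ranking(score_vector(preds, d, sp$train$targets), labels, mask = mask)
  got <- tidy(rep)[tidy(rep)$unit == d, names(want)]
  expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-12)
})

test_that("glance summarises central tendency and dispersion per metric", {
  b <- make_bench(2)
  g <- glance(loocv(b$ds, b$pred))
  expect_true(all(c(
    "auroc_median", "auroc_iqr", "auroc_mean", "auroc_sd",
    "r_at_k_median", "n_units", "n_skipped", "n_outside_domain"
  ) %in% names(g)))
  expect_equal(g$n_units, length(b$ds$drugs))
})

test_that("alpha sweep returns one summary row per cutoff", {
  b <- make_bench(4)
  sw <- alpha_sweep(b$ds, b$lib$features, alphas = c(0.1, 0.5, 0.9), cv = "loo")
  expect_equal(sw$alpha, c(0.1, 0.5, 0.9))
  expect_true(all(c("auprc_median", "r_at_k_median") %in% names(sw)))
})

test_that("the NBI predictor is rejected by drug-wise harnesses", {
  b <- make_bench(6)
  expect_error(loocv(b$ds, predictor_nbi()), "dti_holdout")
  expect_error(repeated_kfold(b$ds, predictor_nbi()), "dti_holdout")
})
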