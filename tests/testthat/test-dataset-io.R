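test_that("edge-list reading deduplicates and preserves first-appearance order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\tt1", "d2\tt1", "d1\tt1"), f)
  ds <- read_interactions(f)
  expect_equal(n_interactions(ds), 2)
  expect_equal(ds$drugs, c("d1", "d2"))
  expect_equal(ds$targets, "t1")
  expect_equal(n_drugs(ds), 2)
  expect_equal(n_targets(ds), 1)
})

test_that("write -> read round trip is the identity", {
  ds <- random_dataset(12, 7, 30, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(ds, f)
  ds2 <- read_interactions(f)
  # node order in the file is first-appearance order; identity holds as sets
  expect_setequal(ds2$drugs, ds$drugs)
  expect_setequal(ds2$targets, ds$targets)
  expect_equal(
    dplyr::arrange(ds2$edges, drug, target),
    dplyr::arrange(ds$edges, drug, target)
  )
})

test_that("malformed and empty files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\tt1", "lonelyfield"), f)
  expect_error(read_interactions(f), "line 2")
  writeLines(character(), f)
  expect_error(read_interactions(f), "empty")
})

test_that("adjacency-matrix reader converts to the same edge set", {
  ds <- random_dataset(6, 4, 9, seed = 2)
  A <- adjacency_matrix(ds)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(A, f, sep = "\t", quote = FALSE, col.names = NA)
  ds2 <- read_adjacency(f)
  expect_equal(sort(paste(ds2$edges$drug, ds2$edges$target)),
               sort(paste(ds$edges$drug, ds$edges$target)))
  # and transposed
  utils::write.table(t(A), f, sep = "\t", quote = FALSE, col.names = NA)
  ds3 <- read_adjacency(f, transpose = TRUE)
  expect_equal(n_interactions(ds3), n_interactions(ds))
})

test_that("dataset statistics reproduce the benchmark descriptions", {
  # counts as published for four reference datasets
  cases <- list(
    list(n = c(54, 26, 90), density = 6.41, kd = 1.67, kt = 3.46),
    list(n = c(445, 664, 2926), density = 0.99, kd = 6.58, kt = NA),
    list(n = c(1844, 1032, 10185), density = 0.54, kd = NA, kt = NA),
    list(n = c(1513, 395, 4863), density = 0.81, kd = NA, kt = 12.31)
  )
  for (cs in cases) {
    st <- dataset_stats(random_dataset(cs$n[1], cs$n[2], cs$n[3], seed = 1))
    expect_equal(round(st$density, 2), cs$density)
    if (!is.na(cs$kd)) expect_equal(round(st$ligand_degree_mean, 2), cs$kd)
    if (!is.na(cs$kt)) expect_equal(round(st$target_degree_mean, 2), cs$kt)
  }
  # complete 1x1 graph
  st <- dataset_stats(interaction_dataset(data.frame(drug = "d", target = "t")))
  expect_equal(st$density, 100)
  expect_equal(st$ligand_degree_mean, 1)
  expect_equal(st$target_degree_mean, 1)
})

test_that("stats invariants hold on random datasets", {
  for (seed in 1:5) {
    nd <- sample(3:30, 1)
    nt <- sample(3:30, 1)
    ne <- sample(seq_len(nd * nt), 1)
    ds <- random_dataset(nd, nt, ne, seed = seed)
    st <- dataset_stats(ds)
    expect_equal(st$density, 100 * ne / (nd * nt))
    expect_equal(st$ligand_degree_mean, ne / nd)
    expect_equal(st$target_degree_mean, ne / nt)
  }
  expect_error(dataset_stats(interaction_dataset(
    data.frame(drug = character(), target = character())
  )), "empty")
})

test_that("bioactivity filtering applies each inclusion rule strictly", {
  base <- list(
    compound = "c", target = "t", activity_type = "IC50",
    activity_um = 1, n_atoms = 30, phase = 2, organism = "human"
  )
  rec <- function(...) {
    tibble::as_tibble(utils::modifyList(base, list(...)))
  }
  records <- dplyr::bind_rows(
    rec(compound = "a", activity_um = 20), # fails: 20 >= 10
    rec(compound = "b", activity_type = "Ki", activity_um = 1, n_atoms = 5), # fails: 5 not > 5
    rec(compound = "c"), # passes
    rec(compound = "d", phase = 0), # fails phase
    rec(compound = "e", organism = "rat"), # fails organism
    rec(compound = "f", activity_type = "Kd", n_atoms = 79) # passes (79 < 80)
  )
  ds <- filter_bioactivities(records)
  expect_equal(sort(ds$drugs), c("c", "f"))
  expect_equal(n_interactions(ds), 2)
  # boundary: exactly 10 uM and exactly 80 atoms are excluded (strict bounds)
  expect_equal(n_interactions(filter_bioactivities(rec(activity_um = 10))), 0)
  expect_equal(n_interactions(filter_bioactivities(rec(n_atoms = 80))), 0)
})

test_that("unknown activity types are skipped with a warning, not an error", {
  records <- tibble::tibble(
    compound = c("a", "b"), target = "t",
    activity_type = c("percent_inhibition", "Ki"),
    activity_um = 1, n_atoms = 30, phase = 1, organism = "human"
  )
  expect_warning(ds <- filter_bioactivities(records), "unknown activity type")
  expect_equal(ds$drugs, "b")
})

test_that("filtering is idempotent and collapses duplicate pairs", {
  set.seed(7)
  records <- tibble::tibble(
    compound = sample(c("a", "b", "c"), 12, TRUE),
    target = sample(c("t1", "t2"), 12, TRUE),
    activity_type = sample(c("Ki", "IC50", "other"), 12, TRUE),
    activity_um = runif(12, 0.1, 30),
    n_atoms = sample(3:90, 12),
    phase = sample(0:3, 12, TRUE),
    organism = sample(c("human", "rat"), 12, TRUE)
  )
  ds1 <- suppressWarnings(filter_bioactivities(records))
  # re-filter the survivors (reconstructed as compliant records)
  if (nrow(ds1$edges)) {
    survivors <- tibble::tibble(
      compound = ds1$edges$drug, target = ds1$edges$target,
      activity_type = "Ki", activity_um = 1, n_atoms = 30, phase = 1,
      organism = "human"
    )
    ds2 <- filter_bioactivities(survivors)
    expect_equal(ds2$edges[c("drug", "target")], ds1$edges[c("drug", "target")])
  }
  expect_lte(n_interactions(ds1), 6) # at most distinct pairs
})

test_that("time split keeps shared targets and removes known interactions", {
  train <- interaction_dataset(data.frame(drug = "d1", target = "t1"))
  test <- interaction_dataset(data.frame(
    drug = c("d1", "d2", "d2"),
    target = c("t1", "t1", "t2")
  ))
  sp <- time_split(train, test)
  expect_equal(sp$train$edges$drug, "d1")
  # t2 is not shared and (d1,t1) was already known, so only (d2,t1) remains
  expect_equal(nrow(sp$test$edges), 1)
  expect_equal(sp$test$edges$drug, "d2")
  expect_equal(sp$test$edges$target, "t1")
  expect_false(any(paste(sp$test$edges$drug, sp$test$edges$target) %in%
    paste(sp$train$edges$drug, sp$train$edges$target)))
  expect_setequal(sp$train$targets, sp$test$targets)

  # identical train and test -> empty test edge set
  sp2 <- time_split(train, train)
  expect_equal(nrow(sp2$test$edges), 0)

  # disjoint target panels -> error
  other <- interaction_dataset(data.frame(drug = "d9", target = "t9"))
  expect_error(time_split(train, other), "no targets")
})

test_that("time split of random dataset pairs satisfies its invariants", {
  for (seed in 1:3) {
    a <- random_dataset(10, 8, 25, seed = seed)
    b <- random_dataset(12, 8, 30, seed = seed + 100)
    sp <- time_split(a, b)
    expect_setequal(sp$train$targets, sp$test$targets)
    expect_true(all(sp$train$targets %in% a$targets))
    expect_true(all(sp$test$targets %in% b$targets))
    expect_equal(nrow(dplyr::inner_join(sp$train$edges, sp$test$edges,
      by = c("drug", "target")
    )), 0)
  }
})
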