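test_that("single-path toy network halves the resource at the drug node", {
  net <- tripartite_network(
    matrix(1, 1, 1, dimnames = list("f1", "d1")),
    matrix(1, 1, 1, dimnames = list("d1", "t1"))
  )
  out <- denovo_spread(net, 1)
  # d1 receives 1 and splits it over its two neighbours (f1 back, t1 forward)
  expect_equal(out$score, 0.5)
  expect_equal(out$target, "t1")
  expect_equal(out$rank, 1L)
})

test_that("an all-zero query yields all-zero scores, not an error", {
  net <- random_tripartite(4, 5, 3, seed = 1)
  net <- tripartite_network(net$fd, net$dt)
  out <- denovo_spread(net, rep(0, 4))
  expect_true(all(out$score == 0))
  expect_equal(sort(unique(out$target)), sort(net$targets))
})

test_that("dimension mismatches and negative inputs are rejected", {
  net <- random_tripartite(4, 5, 3, seed = 2)
  net <- tripartite_network(net$fd, net$dt)
  expect_error(denovo_spread(net, rep(1, 5)), "feature")
  expect_error(denovo_spread(net, c(-1, 1, 1, 1)), "non-negative")
  expect_error(tripartite_network(matrix(1, 2, 2), matrix(1, 3, 2)), "disagree")
  expect_error(tripartite_network(matrix(-1, 1, 1), matrix(1, 1, 1)), "non-negative")
  expect_error(tripartite_network(matrix(1, 1, 1), matrix(2, 1, 1)), "binary")
})

test_that("total resource is conserved through both spreading rounds", {
  for (seed in 1:20) {
    for (prop in c("weighted", "binary")) {
      blocks <- random_tripartite(6, 7, 5, seed = seed, weighted = prop == "weighted")
      net <- tripartite_network(blocks$fd, blocks$dt)
      q <- runif(6)
      st <- denovo_spread(net, q, propagation = prop, full_state = TRUE)
      total <- sum(st$feature_resources) + sum(st$drug_resources) + sum(st$target_resources)
      expect_lt(abs(total - sum(q)), 1e-12)
    }
  }
})

test_that("vectorised spreading equals the per-node traversal oracle", {
  n_cases <- 0
  for (seed in 1:60) {
    for (prop in c("weighted", "binary")) {
      set.seed(seed * 1000 + (prop == "binary"))
      nf <- sample(2:10, 1)
      nd <- sample(2:10, 1)
      nt <- sample(2:10, 1)
      blocks <- random_tripartite(nf, nd, nt, seed = seed, weighted = prop == "weighted")
      q <- round(runif(nf), 3) * (runif(nf) < 0.8)
      got <- denovo_spread(tripartite_network(blocks$fd, blocks$dt), q, propagation = prop)
      want <- spread_oracle(blocks$fd, blocks$dt, q, prop)
      expect_lt(max(abs(score_vector(got, "query", colnames(blocks$dt)) - want$target)), 1e-12)
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 100)
})

test_that("a query identical to a training drug recovers that drug's targets", {
  lib <- generate_clustered_library(3, 6, 128, 0.05, seed = 8)
  ds <- generate_planted_dti(lib$clusters, 4, 0.9, seed = 8)
  d <- ds$edges$drug[1]
  out <- simspread_predict(ds, lib$features, lib$features[d, , drop = FALSE],
    alpha = 0.2
  )
  d_targets <- ds$edges$target[ds$edges$drug == d]
  got <- score_vector(out, rownames(lib$features[d, , drop = FALSE]), ds$targets)
  expect_true(all(got[d_targets] > 0))
})

test_that("at cutoff 1 only exact duplicate structures link to the feature layer", {
  lib <- generate_clustered_library(2, 4, 64, 0.1, seed = 3)
  ds <- generate_planted_dti(lib$clusters, 3, 1, seed = 3)
  dup <- lib$features[2, , drop = FALSE]
  rownames(dup) <- "copycat"
  out <- simspread_predict(ds, lib$features, dup, alpha = 1)
  # the duplicate of drug 2 still scores positively on drug 2's targets
  t2 <- ds$edges$target[ds$edges$drug == rownames(lib$features)[2]]
  sc <- score_vector(out, "copycat", ds$targets)
  expect_true(all(sc[t2] > 0))
  # a genuinely novel structure is outside the application domain at alpha 1
  novel <- matrix(as.numeric(seq_len(64) %% 7 == 0), 1,
    dimnames = list("novel", NULL)
  )
  out2 <- simspread_predict(ds, lib$features, novel, alpha = 1)
  expect_true(all(out2$score == 0))
  expect_true("novel" %in% attr(out2, "outside_domain"))
})

test_that("simspread on a tiny instance equals composing its pieces by hand", {
  feats <- matrix(
    c(
      1, 1, 0, 0,
      1, 0, 1, 0,
      0, 0, 1, 1
    ),
    3,
    byrow = TRUE, dimnames = list(c("d1", "d2", "d3"), NULL)
  )
  ds <- interaction_dataset(data.frame(
    drug = c("d1", "d2", "d3"),
    target = c("t1", "t1", "t2")
  ))
  q <- matrix(c(1, 1, 1, 0), 1, dimnames = list("q", NULL))
  out <- simspread_predict(ds, feats, q, alpha = 0.2, scheme = "sim")
  # oracle route: build the blocks explicitly and traverse per node
  s_dd <- similarity_matrix(feats)
  diag(s_dd) <- 1
  fd <- build_feature_matrix(s_dd, 0.2, "similarity")
  qf <- build_feature_matrix(similarity_matrix(q, feats), 0.2, "similarity")
  want <- spread_oracle(fd, adjacency_matrix(ds), qf[1, ], "weighted")
  expect_equal(unname(score_vector(out, "q", ds$targets)), want$target,
    tolerance = 1e-14
  )
})

test_that("raising the cutoff never widens a query's score support", {
  lib <- generate_clustered_library(3, 5, 128, 0.1, seed = 12)
  ds <- generate_planted_dti(lib$clusters, 4, 0.9, seed = 12)
  q <- lib$features[1, , drop = FALSE]
  prev_support <- NULL
  for (a in c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
    out <- simspread_predict(ds, lib$features, q, alpha = a)
    support <- out$target[out$score > 0]
    if (!is.null(prev_support)) expect_true(all(support %in% prev_support))
    prev_support <- support
  }
})

test_that("rankings are a deterministic permutation with stable tie-breaking", {
  scores <- matrix(c(0.5, 0.5, 0.1, 0.9), 1,
    dimnames = list("q", c("tb", "ta", "tc", "td"))
  )
  tbl <- simspread:::scores_to_tibble(scores)
  expect_equal(tbl$target, c("td", "ta", "tb", "tc")) # ties broken by ID
  expect_equal(tbl$rank, 1:4)
})
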