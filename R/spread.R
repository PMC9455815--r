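#' Construct a feature-drug-target network
#'
#' The prediction network has three layers: a feature layer F (in SimSpread,
#' a copy of the training drugs; in SDTNBI, substructure fingerprint bits),
#' the drug layer D, and the target layer T. `feature_drug` holds the
#' non-negative weights of F-D edges and `drug_target` the binary D-T
#' adjacency. Query compounds connect to F at prediction time through their
#' feature vectors.
#'
#' @param feature_drug Numeric matrix (features x drugs), weights >= 0.
#' @param drug_target Binary matrix (drugs x targets).
#' @return An object of class `tripartite_network`.
#' @export
tripartite_network <- function(feature_drug, drug_target) {
  fd <- as.matrix(feature_drug)
  dt <- as.matrix(drug_target)
  if (ncol(fd) != nrow(dt)) {
    abort(sprintf(
      "drug layers disagree: feature_drug has %d columns, drug_target %d rows",
      ncol(fd), nrow(dt)
    ))
  }
  if (any(fd < 0)) abort("feature-drug weights must be non-negative")
  if (!all(dt %in% c(0, 1))) abort("drug-target adjacency must be binary")
  structure(
    list(
      fd = fd, dt = dt,
      features = rownames(fd) %||% paste0("f", seq_len(nrow(fd))),
      drugs = colnames(fd) %||% rownames(dt) %||% paste0("d", seq_len(ncol(fd))),
      targets = colnames(dt) %||% paste0("t", seq_len(ncol(dt)))
    ),
    class = "tripartite_network"
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf(
    "<tripartite_network> %d features, %d drugs, %d targets; %d F-D edges, %d D-T edges\n",
    length(x$features), length(x$drugs), length(x$targets),
    sum(x$fd > 0), sum(x$dt > 0)
  ))
  invisible(x)
}

# Row-normalize a non-negative matrix into a transfer operator. Under binary
# propagation every edge receives an equal share (1/degree); under weighted
# propagation shares are proportional to edge weight. Zero-degree rows stay
# zero: such a node retains nothing and distributes nothing.
transfer_operator <- function(w, propagation) {
  if (propagation == "binary") w <- (w > 0) * 1
  den <- rowSums(w)
  den[den == 0] <- Inf
  w / den
}

#' Two-round resource diffusion on the tripartite network
#'
#' The de novo network-based inference core. Resources start on the feature
#' layer with the query's feature values; in round one every feature node
#' splits its resource over its drug neighbours; in round two every drug
#' node splits what it received over *all* its neighbours jointly -- back to
#' the feature layer and forward to the target layer -- using the same
#' division-and-summation rule. The prediction score of a target is its
#' final resource. A query with an all-zero feature vector has no path into
#' the network and receives all-zero scores (it lies outside the
#' application domain).
#'
#' @param net A [tripartite_network()].
#' @param query_features Non-negative numeric vector over the feature layer,
#'   or a matrix with one query per row.
#' @param propagation `"weighted"` (shares proportional to edge weight) or
#'   `"binary"` (equal shares over edge count).
#' @param full_state If `TRUE`, also return the final resources on the
#'   feature and drug layers (for conservation diagnostics).
#' @return A tibble `(query, target, score, rank)` with deterministic
#'   tie-breaking (score descending, then target ID); with
#'   `full_state = TRUE`, a list with elements `scores`, `feature_resources`
#'   and `drug_resources`.
#' @examples
#' net <- tripartite_network(matrix(1, 1, 1), matrix(1, 1, 1))
#' denovo_spread(net, 1) # single target scores 0.5
#' @export
denovo_spread <- function(net, query_features,
                          propagation = c("weighted", "binary"),
                          full_state = FALSE) {
  propagation <- match.arg(propagation)
  q <- query_features
  if (is.null(dim(q))) q <- matrix(q, nrow = 1, dimnames = list("query", NULL))
  q <- as.matrix(q)
  if (ncol(q) != nrow(net$fd)) {
    abort(sprintf(
      "query feature length %d does not match %d feature nodes",
      ncol(q), nrow(net$fd)
    ))
  }
  if (any(q < 0)) abort("query features must be non-negative")
  if (is.null(rownames(q))) rownames(q) <- paste0("query", seq_len(nrow(q)))

  m1 <- transfer_operator(net$fd, propagation) # F -> D
  # round 2: each drug spreads over its joint neighbourhood in F and T
  joint <- cbind(t(net$fd), net$dt)
  m2 <- transfer_operator(joint, propagation)
  m2f <- m2[, seq_len(nrow(net$fd)), drop = FALSE]
  m2t <- m2[, nrow(net$fd) + seq_len(ncol(net$dt)), drop = FALSE]

  d1 <- q %*% m1
  scores <- d1 %*% m2t
  colnames(scores) <- net$targets
  tbl <- scores_to_tibble(scores)
  if (!full_state) {
    return(tbl)
  }
  list(
    scores = tbl,
    feature_resources = d1 %*% m2f,
    drug_resources = d1 * 0,
    target_resources = scores
  )
}

# Long-format ranked scores with deterministic tie-breaking:
# score descending, then target ID ascending.
scores_to_tibble <- function(scores) {
  tbl <- tibble(
    query = rep(rownames(scores), times = ncol(scores)),
    target = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores)
  )
  tbl <- dplyr::arrange(tbl, .data$query, dplyr::desc(.data$score), .data$target)
  dplyr::mutate(dplyr::group_by(tbl, .data$query), rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Predict targets with SimSpread
#'
#' Runs the full SimSpread pipeline: builds the thresholded/weighted
#' drug-drug feature matrix and the query-drug feature matrix from the
#' supplied descriptors (Tanimoto similarity), assembles the tripartite
#' network whose feature layer is a copy of the training drugs (self-edges
#' with similarity 1 included), and spreads resources for every query. A
#' query whose feature row is all zero -- no training drug with similarity
#' at or above `alpha` -- lies outside the application domain and receives
#' all-zero scores; such queries are listed in the `outside_domain`
#' attribute of the result.
#'
#' @param train An [interaction_dataset()] providing the drug-target layer.
#' @param drug_features Descriptor matrix covering all training drugs.
#' @param queries Descriptor matrix of query compounds (same descriptor
#'   space), or a character vector of IDs to pick rows of `drug_features`.
#' @param alpha Similarity cutoff in \[0, 1\] (default 0.2).
#' @param scheme Feature weighting: `"similarity"`/`"sim"` keeps similarity
#'   values, `"binary"`/`"bin"` sets surviving entries to 1 (default
#'   similarity).
#' @param propagation Resource-splitting rule, `"weighted"` or `"binary"`
#'   (default weighted, the natural partner of similarity weighting).
#' @param kind Similarity kind passed to [similarity_matrix()].
#' @return A tibble `(query, target, score, rank)`.
#' @export
simspread_predict <- function(train, drug_features, queries, alpha = 0.2,
                              scheme = c("similarity", "binary", "sim", "bin"),
                              propagation = c("weighted", "binary"),
                              kind = c("auto", "binary", "continuous")) {
  propagation <- match.arg(propagation)
  kind <- match.arg(kind)
  if (is.character(queries) && is.null(dim(queries))) {
    queries <- drug_features[queries, , drop = FALSE]
  }
  missing_feat <- setdiff(train$drugs, rownames(drug_features))
  if (length(missing_feat)) {
    abort(paste0("no descriptors for training drug(s): ", paste(head(missing_feat, 5), collapse = ", ")))
  }
  df <- drug_features[train$drugs, , drop = FALSE]
  s_dd <- similarity_matrix(df, df, kind = kind)
  diag(s_dd) <- 1
  s_qd <- similarity_matrix(as.matrix(queries), df, kind = kind)
  fd <- build_feature_matrix(s_dd, alpha, scheme)
  qf <- build_feature_matrix(s_qd, alpha, scheme)
  net <- tripartite_network(fd, adjacency_matrix(train))
  out <- denovo_spread(net, qf, propagation)
  outside <- rownames(qf)[rowSums(qf) == 0]
  attr(out, "outside_domain") <- outside
  out
}
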