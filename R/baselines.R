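#' Network-based inference on the bipartite drug-target network
#'
#' The classical two-round resource-spreading recommender: every annotated
#' target of the query drug starts with one unit of resource; targets
#' distribute their resource equally over their annotated drugs; drugs then
#' distribute equally over their annotated targets. The final target
#' resources are the prediction scores. NBI can only score drugs already in
#' the network; an isolated drug receives all-zero scores.
#'
#' @param train An [interaction_dataset()].
#' @param drugs Character vector of query drug IDs (must belong to
#'   `train$drugs`). Defaults to all drugs.
#' @return A tibble `(query, target, score, rank)`.
#' @examples
#' ds <- interaction_dataset(data.frame(drug = "d1", target = "t1"))
#' nbi_predict(ds) # d1/t1 scores 1
#' @export
nbi_predict <- function(train, drugs = NULL) {
  drugs <- drugs %||% train$drugs
  unknown <- setdiff(drugs, train$drugs)
  if (length(unknown)) {
    abort(paste0("drug(s) not in the network: ", paste(head(unknown, 5), collapse = ", ")))
  }
  A <- adjacency_matrix(train)
  m1 <- transfer_operator(t(A), "binary") # T -> D, equal shares
  m2 <- transfer_operator(A, "binary") # D -> T, equal shares
  scores <- A[drugs, , drop = FALSE] %*% m1 %*% m2
  scores_to_tibble(scores)
}

#' SDTNBI: substructure-drug-target network-based inference
#'
#' De novo prediction for compounds not in the network, with a feature layer
#' made of binary fingerprint substructure bits. Delegates to
#' [denovo_spread()] with binary propagation: the feature-drug block is the
#' transposed training fingerprint matrix and the query connects through its
#' own bits. A query sharing no set bit with the training substructure
#' vocabulary receives all-zero scores.
#'
#' @param train An [interaction_dataset()].
#' @param substructures Binary descriptor matrix covering all training
#'   drugs (rows = drugs, columns = substructure bits).
#' @param query_bits Binary vector over the same bit space, or a matrix with
#'   one query per row, or a character vector of IDs picking rows of
#'   `substructures`.
#' @return A tibble `(query, target, score, rank)`.
#' @export
sdtnbi_predict <- function(train, substructures, query_bits) {
  if (is.character(query_bits) && is.null(dim(query_bits))) {
    query_bits <- substructures[query_bits, , drop = FALSE]
  }
  missing_fp <- setdiff(train$drugs, rownames(substructures))
  if (length(missing_fp)) {
    abort(paste0("no fingerprint for training drug(s): ", paste(head(missing_fp, 5), collapse = ", ")))
  }
  if (!all(substructures %in% c(0, 1)) || !all(query_bits %in% c(0, 1))) {
    abort("SDTNBI requires binary fingerprints")
  }
  fd <- t(substructures[train$drugs, , drop = FALSE])
  net <- tripartite_network(fd, adjacency_matrix(train))
  denovo_spread(net, query_bits, propagation = "binary")
}

#' k-nearest-neighbour target prediction
#'
#' Scores each target by the similarity of the query to the target's
#' annotated ligands: with `k = 1` the score is the maximum similarity, for
#' `k > 1` the mean of the `k` highest similarities. Targets without
#' annotated ligands score 0. Duplicate ligand annotations do not change
#' the result.
#'
#' @param train An [interaction_dataset()].
#' @param similarities Similarity matrix, queries in rows, training drugs in
#'   columns (column names must cover `train$drugs`).
#' @param k Number of neighbours (default 1, plain maximum).
#' @return A tibble `(query, target, score, rank)`.
#' @export
knn_predict <- function(train, similarities, k = 1) {
  if (k < 1) abort("`k` must be >= 1")
  s <- as.matrix(similarities)
  missing_sim <- setdiff(train$drugs, colnames(s))
  if (length(missing_sim)) {
    abort(paste0("no similarity column for training drug(s): ", paste(head(missing_sim, 5), collapse = ", ")))
  }
  if (is.null(rownames(s))) rownames(s) <- paste0("query", seq_len(nrow(s)))
  ligands <- split(ds_edges_drug(train), ds_edges_target(train))
  scores <- matrix(0, nrow(s), length(train$targets),
    dimnames = list(rownames(s), train$targets)
  )
  for (t in names(ligands)) {
    sims <- s[, unique(ligands[[t]]), drop = FALSE]
    scores[, t] <- apply(sims, 1, function(v) {
      mean(sort(v, decreasing = TRUE)[seq_len(min(k, length(v)))])
    })
  }
  scores_to_tibble(scores)
}

ds_edges_drug <- function(ds) ds$edges$drug
ds_edges_target <- function(ds) ds$edges$target
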