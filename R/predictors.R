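#' Predictor configurations for the validation harnesses
#'
#' A predictor object bundles a method with its descriptors and
#' hyper-parameters so that the cross-validation harnesses can rebuild the
#' network from any training subset and score any held-out drug through a
#' single generic, [predict_targets()].
#'
#' * `predictor_simspread()` -- tripartite similarity-guided spreading; the
#'   feature layer is a copy of the training drugs.
#' * `predictor_sdtnbi()` -- substructure-drug-target spreading on binary
#'   fingerprint bits.
#' * `predictor_knn()` -- k-nearest-neighbour similarity lookup.
#' * `predictor_nbi()` -- bipartite spreading; queries must be part of the
#'   training network (use the interaction-holdout harness).
#'
#' @param features Descriptor matrix covering every drug that can appear in
#'   training or as a query.
#' @param alpha Similarity cutoff (default 0.2).
#' @param scheme Feature weighting, `"similarity"`/`"sim"` or
#'   `"binary"`/`"bin"`.
#' @param propagation `"weighted"` or `"binary"` resource splitting.
#' @param kind Similarity kind for continuous descriptors.
#' @param k Neighbour count for the k-NN predictor.
#' @return An object of class `dti_predictor`.
#' @name predictors
NULL

#' @rdname predictors
#' @export
predictor_simspread <- function(features, alpha = 0.2,
                                scheme = c("similarity", "binary", "sim", "bin"),
                                propagation = c("weighted", "binary"),
                                kind = c("auto", "binary", "continuous")) {
  scheme <- match.arg(scheme)
  scheme <- switch(scheme, sim = "similarity", bin = "binary", scheme)
  structure(
    list(
      method = "simspread", features = features, alpha = alpha,
      scheme = scheme, propagation = match.arg(propagation),
      kind = match.arg(kind)
    ),
    class = c("simspread_predictor", "dti_predictor")
  )
}

#' @rdname predictors
#' @export
predictor_sdtnbi <- function(features) {
  structure(
    list(method = "sdtnbi", features = features),
    class = c("sdtnbi_predictor", "dti_predictor")
  )
}

#' @rdname predictors
#' @export
predictor_knn <- function(features, k = 1, kind = c("auto", "binary", "continuous")) {
  structure(
    list(method = "knn", features = features, k = k, kind = match.arg(kind)),
    class = c("knn_predictor", "dti_predictor")
  )
}

#' @rdname predictors
#' @export
predictor_nbi <- function() {
  structure(list(method = "nbi"), class = c("nbi_predictor", "dti_predictor"))
}

#' @export
print.dti_predictor <- function(x, ...) {
  extra <- switch(x$method,
    simspread = sprintf(" (alpha=%g, %s weighting, %s propagation)", x$alpha, x$scheme, x$propagation),
    knn = sprintf(" (k=%d)", x$k),
    ""
  )
  cat(sprintf("<dti_predictor> %s%s\n", x$method, extra))
  invisible(x)
}

#' Score query drugs against a training network
#'
#' Generic dispatched on the predictor configuration; used by every
#' validation harness. Queries absent from the training network are scored
#' de novo through their descriptors (SimSpread, SDTNBI, k-NN); the NBI
#' predictor requires queries to be training drugs.
#'
#' @param predictor A configuration from [predictors].
#' @param train Training [interaction_dataset()].
#' @param queries Character vector of query compound IDs.
#' @return A tibble `(query, target, score, rank)`.
#' @export
predict_targets <- function(predictor, train, queries) {
  UseMethod("predict_targets")
}

#' @export
predict_targets.simspread_predictor <- function(predictor, train, queries) {
  simspread_predict(
    train, predictor$features, queries,
    alpha = predictor$alpha, scheme = predictor$scheme,
    propagation = predictor$propagation, kind = predictor$kind
  )
}

#' @export
predict_targets.sdtnbi_predictor <- function(predictor, train, queries) {
  sdtnbi_predict(train, predictor$features, queries)
}

#' @export
predict_targets.knn_predictor <- function(predictor, train, queries) {
  s <- similarity_matrix(
    predictor$features[queries, , drop = FALSE],
    predictor$features[train$drugs, , drop = FALSE],
    kind = predictor$kind
  )
  knn_predict(train, s, k = predictor$k)
}

#' @export
predict_targets.nbi_predictor <- function(predictor, train, queries) {
  nbi_predict(train, queries)
}

predictor_label <- function(p) {
  switch(p$method,
    simspread = sprintf(
      "simspread(alpha=%g, scheme=%s, propagation=%s)",
      p$alpha, p$scheme, p$propagation
    ),
    knn = sprintf("knn(k=%d)", p$k),
    p$method
  )
}
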