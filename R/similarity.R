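#' Tanimoto similarity between two descriptor vectors
#'
#' For binary vectors the Tanimoto (Jaccard) coefficient
#' \eqn{|A \cap B| / |A \cup B|}; for continuous vectors the generalised form
#' \eqn{\sum a_i b_i / (\sum a_i^2 + \sum b_i^2 - \sum a_i b_i)}. Continuous
#' inputs are expected on \[0, 1\] (see [normalize_columns()]). The empty case
#' 0/0 is defined as 0: two compounds without any descriptor signal are not
#' considered similar.
#'
#' @param a,b Numeric vectors of equal length.
#' @param kind `"auto"` (default; binary iff both vectors are 0/1),
#'   `"binary"` or `"continuous"`.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 1/3
#' tanimoto(c(1, 1), c(1, 0), kind = "continuous") # 0.5
#' @export
tanimoto <- function(a, b, kind = c("auto", "binary", "continuous")) {
  kind <- match.arg(kind)
  if (length(a) != length(b)) abort("descriptor vectors differ in length")
  if (kind == "auto") {
    kind <- if (all(a %in% c(0, 1)) && all(b %in% c(0, 1))) "binary" else "continuous"
  }
  ab <- sum(a * b)
  den <- if (kind == "binary") sum(a) + sum(b) - ab else sum(a^2) + sum(b^2) - ab
  if (den == 0) 0 else ab / den
}

#' Tversky index between two bit vectors
#'
#' \eqn{|A \cap B| / (|A \cap B| + \alpha |A \setminus B| + \beta |B \setminus A|)}.
#' With `alpha = beta = 1` it reduces to the binary Tanimoto coefficient;
#' with `alpha = 0, beta = 1` it measures the fraction of `b` covered by `a`
#' (a substructure-style asymmetric similarity). 0/0 is defined as 0.
#'
#' @param a,b Binary vectors of equal length.
#' @param alpha,beta Non-negative weights of the asymmetric differences.
#' @return Similarity in \[0, 1\].
#' @export
tversky <- function(a, b, alpha = 0, beta = 1) {
  if (length(a) != length(b)) abort("descriptor vectors differ in length")
  if (alpha < 0 || beta < 0) abort("tversky weights must be non-negative")
  ab <- sum(a * b)
  den <- ab + alpha * (sum(a) - ab) + beta * (sum(b) - ab)
  if (den == 0) 0 else ab / den
}

#' Pairwise similarity matrix between two compound sets
#'
#' Vectorised all-vs-all similarity. Rows follow `a`, columns follow `b`.
#'
#' @param a,b Descriptor matrices (compounds in rows, shared column space).
#'   `b` defaults to `a` (symmetric all-vs-all, unit diagonal).
#' @param method `"tanimoto"` (default) or `"tversky"`.
#' @param kind For Tanimoto: `"auto"`, `"binary"` or `"continuous"`.
#' @param alpha,beta Tversky weights (row set is `a`: `alpha` weights
#'   features unique to the row compound).
#' @return Numeric matrix of similarities in \[0, 1\].
#' @export
similarity_matrix <- function(a, b = a, method = c("tanimoto", "tversky"),
                              kind = c("auto", "binary", "continuous"),
                              alpha = 0, beta = 1) {
  method <- match.arg(method)
  kind <- match.arg(kind)
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b)) abort("descriptor matrices differ in column count")
  cross <- a %*% t(b)
  if (method == "tversky") {
    if (alpha < 0 || beta < 0) abort("tversky weights must be non-negative")
    if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) abort("tversky requires binary input")
    den <- cross + alpha * (rowSums(a) - cross) + beta * outer(rep(1, nrow(a)), rowSums(b)) - beta * cross
  } else {
    if (kind == "auto") {
      kind <- if (all(a %in% c(0, 1)) && all(b %in% c(0, 1))) "binary" else "continuous"
    }
    na <- if (kind == "binary") rowSums(a) else rowSums(a^2)
    nb <- if (kind == "binary") rowSums(b) else rowSums(b^2)
    den <- outer(na, nb, `+`) - cross
  }
  s <- ifelse(den == 0, 0, cross / den)
  dimnames(s) <- list(rownames(a), rownames(b))
  s
}

#' Threshold and weight a similarity matrix into a feature matrix
#'
#' Applies the similarity cutoff `alpha` (inclusive: entries with
#' `S >= alpha` survive) and the weighting scheme: under `"binary"`
#' weighting surviving entries become 1; under `"similarity"` weighting they
#' keep their similarity value. All other entries are 0. The result is the
#' feature matrix that links compounds to the drug (feature) layer of the
#' prediction network.
#'
#' @param S Similarity matrix with values in \[0, 1\].
#' @param alpha Similarity cutoff in \[0, 1\].
#' @param scheme `"similarity"` (alias `"sim"`) or `"binary"` (alias
#'   `"bin"`).
#' @return Matrix of the same shape with attributes `alpha` and `scheme`.
#' @examples
#' S <- matrix(c(0.1, 0.3, 0.9), 1)
#' build_feature_matrix(S, 0.2, "binary") # 0 1 1
#' build_feature_matrix(S, 0.2, "similarity") # 0 0.3 0.9
#' @export
build_feature_matrix <- function(S, alpha, scheme = c("similarity", "binary", "sim", "bin")) {
  scheme <- match.arg(scheme)
  scheme <- switch(scheme, sim = "similarity", bin = "binary", scheme)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single value in [0, 1]")
  }
  S <- as.matrix(S)
  keep <- S >= alpha
  out <- if (scheme == "binary") keep * 1 else S * keep
  structure(out, alpha = alpha, scheme = scheme)
}
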