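#' Generate a clustered synthetic fingerprint library
#'
#' Builds a compound library with planted chemical-series structure: each
#' cluster has a random prototype bit vector (bit density
#' `prototype_density`, the typical on-bit fraction of folded circular
#' fingerprints of drug-like molecules), and every member is the prototype
#' with each bit flipped independently with probability `flip_prob`. By
#' construction the within-cluster Tanimoto similarity (about 0.47 at the
#' defaults) clearly exceeds the between-cluster similarity (about 0.07,
#' staying below the default 0.2 linking cutoff so clusters do not connect
#' through the feature layer), emulating the similarity-property principle
#' that similar compounds share bioactivities.
#'
#' @param n_clusters Number of clusters (default 4).
#' @param compounds_per_cluster Members per cluster (default 15).
#' @param n_bits Fingerprint length (default 256).
#' @param flip_prob Per-bit flip probability in \[0, 0.5) (default 0.05).
#' @param prototype_density Prototype on-bit probability (default 0.2).
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A list with `features` (binary descriptor matrix) and `clusters`
#'   (tibble `compound`, `cluster`).
#' @export
generate_clustered_library <- function(n_clusters = 4, compounds_per_cluster = 15,
                                       n_bits = 256, flip_prob = 0.05,
                                       prototype_density = 0.1, seed = 1) {
  if (n_clusters < 1 || compounds_per_cluster < 1 || n_bits < 1) {
    abort("degenerate library size")
  }
  if (flip_prob < 0 || flip_prob >= 0.5) abort("`flip_prob` must lie in [0, 0.5)")
  set.seed(seed)
  rows <- list()
  labels <- list()
  for (cl in seq_len(n_clusters)) {
    proto <- rbinom(n_bits, 1, prototype_density)
    for (m in seq_len(compounds_per_cluster)) {
      flips <- rbinom(n_bits, 1, flip_prob)
      id <- sprintf("c%02d_m%02d", cl, m)
      rows[[id]] <- abs(proto - flips)
      labels[[id]] <- cl
    }
  }
  features <- do.call(rbind, rows)
  list(
    features = new_descriptor_matrix(features, "binary"),
    clusters = tibble(
      compound = names(labels),
      cluster = unlist(labels, use.names = FALSE)
    )
  )
}

#' Generate a drug-target dataset with planted cluster-target structure
#'
#' Assigns every cluster its own disjoint block of targets and annotates
#' each cluster member to each of its cluster's targets independently with
#' probability `annotation_prob`. No cross-cluster edge is ever created, so
#' a predictor that exploits chemical similarity should recover the block
#' structure.
#'
#' @param clusters Tibble `(compound, cluster)` as returned by
#'   [generate_clustered_library()].
#' @param targets_per_cluster Targets in each cluster's block (default 5).
#' @param annotation_prob Per-pair annotation probability in (0, 1\]
#'   (default 0.8).
#' @param seed Integer seed.
#' @return An [interaction_dataset()] (drug list = all compounds, target
#'   list = all block targets, including any that drew no edge).
#' @export
generate_planted_dti <- function(clusters, targets_per_cluster = 5,
                                 annotation_prob = 0.8, seed = 1) {
  clusters <- as_tibble(clusters)
  if (!nrow(clusters)) abort("empty cluster table")
  if (annotation_prob <= 0 || annotation_prob > 1) {
    abort("`annotation_prob` must lie in (0, 1]")
  }
  set.seed(seed)
  cls <- sort(unique(clusters$cluster))
  targets <- unlist(lapply(cls, function(cl) {
    sprintf("t_c%02d_%02d", cl, seq_len(targets_per_cluster))
  }))
  edges <- purrr::map_dfr(seq_len(nrow(clusters)), function(i) {
    cl <- clusters$cluster[i]
    block <- sprintf("t_c%02d_%02d", cl, seq_len(targets_per_cluster))
    hit <- runif(targets_per_cluster) < annotation_prob
    if (!any(hit)) {
      return(tibble(drug = character(), target = character()))
    }
    tibble(drug = clusters$compound[i], target = block[hit])
  })
  interaction_dataset(edges, drugs = clusters$compound, targets = targets)
}

#' Generate a synthetic bioactivity table with planted rule compliance
#'
#' Creates records for [filter_bioactivities()] where each of the five
#' inclusion rules (known activity type, activity below 10 uM, heavy atoms
#' strictly between 5 and 80, clinical phase >= 1, human target) is
#' satisfied independently with a controlled probability, so the expected
#' survivor count is computable in closed form. Compound/target pairs are
#' unique, making the survivor count exact for a given draw.
#'
#' @param n_records Number of records (default 20).
#' @param pass_fractions Named numeric vector of per-rule pass
#'   probabilities with names `type`, `activity`, `atoms`, `phase`,
#'   `organism` (default all 1).
#' @param seed Integer seed.
#' @return A tibble of bioactivity records with a logical `compliant`
#'   column marking records passing every rule (drop it before filtering if
#'   you want a blind test).
#' @export
generate_bioactivity_table <- function(n_records = 20,
                                       pass_fractions = c(
                                         type = 1, activity = 1, atoms = 1,
                                         phase = 1, organism = 1
                                       ),
                                       seed = 1) {
  defaults <- c(type = 1, activity = 1, atoms = 1, phase = 1, organism = 1)
  defaults[names(pass_fractions)] <- pass_fractions
  pf <- defaults
  if (any(pf < 0 | pf > 1)) abort("pass fractions must lie in [0, 1]")
  set.seed(seed)
  ok <- function(p) runif(n_records) < p
  t_ok <- ok(pf["type"])
  a_ok <- ok(pf["activity"])
  n_ok <- ok(pf["atoms"])
  p_ok <- ok(pf["phase"])
  o_ok <- ok(pf["organism"])
  tibble(
    compound = sprintf("cmp%03d", seq_len(n_records)),
    target = sprintf("tgt%03d", seq_len(n_records)),
    activity_type = ifelse(t_ok, sample(c("Ki", "Kd", "IC50", "EC50"), n_records, TRUE), "percent_inhibition"),
    activity_um = ifelse(a_ok, runif(n_records, 0.001, 9.99), runif(n_records, 10, 500)),
    n_atoms = ifelse(n_ok, sample(6:79, n_records, TRUE), sample(c(1:5, 80:120), n_records, TRUE)),
    phase = ifelse(p_ok, sample(1:4, n_records, TRUE), 0L),
    organism = ifelse(o_ok, "human", sample(c("rat", "mouse"), n_records, TRUE)),
    compliant = t_ok & a_ok & n_ok & p_ok & o_ok
  )
}

#' Shuffle the target labels of a dataset's edges
#'
#' Permutation-null utility: randomly permutes the target column of the edge
#' list (drug degrees are preserved; duplicate edges created by the
#' permutation are collapsed). Used as the label-shuffled control that
#' breaks the association between chemical similarity and target
#' annotations.
#'
#' @param ds An [interaction_dataset()].
#' @param seed Integer seed.
#' @return An [interaction_dataset()] with the same node lists.
#' @export
shuffle_edges <- function(ds, seed = 1) {
  set.seed(seed)
  edges <- ds$edges
  edges$target <- sample(edges$target)
  edges <- dplyr::distinct(edges, .data$drug, .data$target)
  interaction_dataset(edges, drugs = ds$drugs, targets = ds$targets)
}

#' Random bipartite interaction dataset
#'
#' Samples `n_edges` distinct drug-target pairs. When the edge budget allows
#' (`n_edges` at least the number of nodes needing coverage), every drug and
#' every target receives at least one edge first -- matching real benchmark
#' datasets, which carry no isolated nodes -- and the remaining edges are
#' drawn uniformly; otherwise all pairs are uniform and some nodes may stay
#' isolated.
#'
#' @param n_drugs,n_targets,n_edges Counts; `n_edges` must not exceed
#'   `n_drugs * n_targets`.
#' @param seed Integer seed.
#' @return An [interaction_dataset()].
#' @export
random_dataset <- function(n_drugs, n_targets, n_edges, seed = 1) {
  if (n_edges > n_drugs * n_targets) abort("more edges than possible pairs")
  set.seed(seed)
  drugs <- sprintf("d%04d", seq_len(n_drugs))
  targets <- sprintf("t%04d", seq_len(n_targets))
  cell_id <- function(d, t) (t - 1) * n_drugs + d
  cells <- integer(0)
  if (n_edges >= n_drugs) {
    cells <- cell_id(seq_len(n_drugs), sample.int(n_targets, n_drugs, replace = TRUE))
    covered <- unique((cells - 1) %/% n_drugs + 1)
    uncov <- setdiff(seq_len(n_targets), covered)
    if (length(uncov) && n_drugs + length(uncov) <= n_edges) {
      cells <- c(cells, cell_id(
        sample.int(n_drugs, length(uncov), replace = TRUE), uncov
      ))
    }
    cells <- unique(cells)
    if (length(cells) > n_edges) cells <- integer(0) # coverage infeasible
  }
  pool <- setdiff(sample.int(n_drugs * n_targets), cells)
  cells <- c(cells, pool[seq_len(n_edges - length(cells))])
  interaction_dataset(
    tibble(
      drug = drugs[(cells - 1) %% n_drugs + 1],
      target = targets[(cells - 1) %/% n_drugs + 1]
    ),
    drugs = drugs, targets = targets
  )
}
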