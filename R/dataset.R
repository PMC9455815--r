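#' Create a drug-target interaction dataset
#'
#' An `interaction_dataset` is the bipartite drug-target layer of the
#' prediction network: an ordered set of drug IDs, an ordered set of target
#' IDs, and a deduplicated set of interaction edges between them. Edges may
#' optionally carry a bioactivity value (in micromolar) and a date/version
#' tag, which are preserved but ignored by the predictors (the drug-target
#' layer is unweighted).
#'
#' @param edges A data frame with character columns `drug` and `target`
#'   (first two columns are used positionally if unnamed), and optionally
#'   `activity_um` and `date`.
#' @param drugs,targets Optional ID vectors fixing the node sets and their
#'   order. Defaults to first-appearance order in `edges`. May include IDs
#'   with no edges (isolated nodes).
#' @return An object of class `interaction_dataset` with elements `drugs`,
#'   `targets` and `edges` (a tibble).
#' @examples
#' ds <- interaction_dataset(data.frame(drug = c("d1", "d2"), target = "t1"))
#' ds
#' @export
interaction_dataset <- function(edges, drugs = NULL, targets = NULL) {
  edges <- as_tibble(edges)
  if (ncol(edges) < 2) {
    abort("`edges` needs at least two columns (drug, target).")
  }
  if (!all(c("drug", "target") %in% names(edges))) {
    names(edges)[1:2] <- c("drug", "target")
  }
  edges$drug <- as.character(edges$drug)
  edges$target <- as.character(edges$target)
  if (anyNA(edges$drug) || anyNA(edges$target)) {
    abort("edge list contains missing drug or target IDs")
  }
  edges <- dplyr::distinct(edges, .data$drug, .data$target, .keep_all = TRUE)
  drugs <- as.character(drugs %||% unique(edges$drug))
  targets <- as.character(targets %||% unique(edges$target))
  if (anyDuplicated(drugs)) abort("duplicate drug IDs")
  if (anyDuplicated(targets)) abort("duplicate target IDs")
  bad_d <- setdiff(edges$drug, drugs)
  bad_t <- setdiff(edges$target, targets)
  if (length(bad_d) || length(bad_t)) {
    abort(paste0(
      "edges reference unlisted nodes: ",
      paste(head(c(bad_d, bad_t), 5), collapse = ", ")
    ))
  }
  structure(
    list(drugs = drugs, targets = targets, edges = edges),
    class = "interaction_dataset"
  )
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf(
    "<interaction_dataset> %d drugs, %d targets, %d interactions\n",
    length(x$drugs), length(x$targets), nrow(x$edges)
  ))
  print(head(x$edges, 5))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.interaction_dataset <- function(x, ...) x$edges

#' Number of drugs/targets/edges helpers
#' @param ds An [interaction_dataset()].
#' @return Integer count.
#' @export
n_drugs <- function(ds) length(ds$drugs)

#' @rdname n_drugs
#' @export
n_targets <- function(ds) length(ds$targets)

#' @rdname n_drugs
#' @export
n_interactions <- function(ds) nrow(ds$edges)

#' Binary drug-target adjacency matrix of a dataset
#'
#' @param ds An [interaction_dataset()].
#' @return A binary matrix (drugs in rows, targets in columns) in the
#'   dataset's node order.
#' @export
adjacency_matrix <- function(ds) {
  A <- matrix(0, length(ds$drugs), length(ds$targets),
    dimnames = list(ds$drugs, ds$targets)
  )
  A[cbind(ds$edges$drug, ds$edges$target)] <- 1
  A
}

#' Read a drug-target edge list from a TSV file
#'
#' The canonical interchange format is a headerless tab-separated edge list
#' with columns drug, target and, optionally, bioactivity (micromolar) and a
#' date/version tag. Duplicate edges are collapsed; node order is
#' first-appearance order.
#'
#' @param path Path to the TSV file.
#' @param header Does the file carry a header row? Default `FALSE`.
#' @return An [interaction_dataset()].
#' @export
read_interactions <- function(path, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines)) lines <- lines[-1]
  if (!length(lines)) abort(paste0("empty interaction file: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2)) {
    bad <- which(nfield < 2)[1] + as.integer(header)
    abort(sprintf("malformed row at line %d of %s (need >= 2 fields)", bad, path))
  }
  edges <- tibble(
    drug = vapply(parts, `[`, "", 1),
    target = vapply(parts, `[`, "", 2)
  )
  if (max(nfield) >= 3) {
    act <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, "")
    edges$activity_um <- suppressWarnings(as.numeric(act))
  }
  if (max(nfield) >= 4) {
    edges$date <- vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, "")
  }
  interaction_dataset(edges)
}

#' Write a dataset as a TSV edge list
#'
#' @param ds An [interaction_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(ds, path) {
  readr::write_tsv(ds$edges, path, col_names = FALSE, na = "")
  invisible(path)
}

#' Read a drug-target adjacency matrix as a dataset
#'
#' Reads a labelled 0/1 matrix (drugs in rows, targets in columns, first
#' column = drug IDs, header = target IDs) and converts it to an edge list.
#' Set `transpose = TRUE` for files with targets in rows.
#'
#' @param path Path to the TSV matrix.
#' @param transpose Are targets in rows? Default `FALSE`.
#' @return An [interaction_dataset()].
#' @export
read_adjacency <- function(path, transpose = FALSE) {
  m <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(m)
  if (transpose) m <- t(m)
  idx <- which(m != 0, arr.ind = TRUE)
  if (!nrow(idx)) abort(paste0("adjacency matrix has no interactions: ", path))
  interaction_dataset(
    tibble(drug = rownames(m)[idx[, 1]], target = colnames(m)[idx[, 2]]),
    drugs = rownames(m), targets = colnames(m)
  )
}

#' Summary statistics of an interaction dataset
#'
#' Computes the usual dataset description: node and edge counts, mean and SD
#' of per-drug and per-target degree, heavy-atom range (when atom counts are
#' supplied), and density -- the percentage of all possible drug-target pairs
#' that is annotated, `100 * n_interactions / (n_ligands * n_targets)`.
#' Degrees of isolated nodes count as zero. Values are returned at full
#' precision; round for display.
#'
#' @param ds An [interaction_dataset()].
#' @param atom_counts Optional named vector mapping drug ID to heavy-atom
#'   count.
#' @return A one-row tibble.
#' @examples
#' ds <- random_dataset(54, 26, 90, seed = 1)
#' dataset_stats(ds) # density 6.41 %
#' @export
dataset_stats <- function(ds, atom_counts = NULL) {
  if (!inherits(ds, "interaction_dataset")) abort("`ds` must be an interaction_dataset")
  if (!nrow(ds$edges)) abort("empty dataset")
  deg_d <- table(factor(ds$edges$drug, levels = ds$drugs))
  deg_t <- table(factor(ds$edges$target, levels = ds$targets))
  atoms <- if (!is.null(atom_counts)) {
    range(atom_counts[ds$drugs], na.rm = TRUE)
  } else {
    c(NA_real_, NA_real_)
  }
  tibble(
    n_ligands = length(ds$drugs),
    n_targets = length(ds$targets),
    n_interactions = nrow(ds$edges),
    ligand_degree_mean = nrow(ds$edges) / length(ds$drugs),
    ligand_degree_sd = sd(as.numeric(deg_d)),
    target_degree_mean = nrow(ds$edges) / length(ds$targets),
    target_degree_sd = sd(as.numeric(deg_t)),
    atoms_min = atoms[1],
    atoms_max = atoms[2],
    density = 100 * nrow(ds$edges) / (length(ds$drugs) * length(ds$targets))
  )
}

#' Filter a bioactivity table into an interaction dataset
#'
#' Applies the standard medicinal-chemistry inclusion rules for building a
#' drug-target network from a flat bioactivity table: a record is kept iff
#' its activity type is one of Ki, Kd, IC50, EC50, its activity value is
#' strictly below `activity_cutoff_um`, its heavy-atom count lies strictly
#' between `min_atoms` and `max_atoms`, its clinical phase is at least
#' `min_phase` and its target organism matches `organism`
#' (case-insensitively). Records with an unrecognised activity type are
#' skipped with a warning. Surviving duplicate (compound, target) pairs
#' collapse to one unweighted edge, so the filter is idempotent.
#'
#' @param records Data frame with columns `compound`, `target`,
#'   `activity_type`, `activity_um`, `n_atoms`, `phase`, `organism`.
#' @param activity_cutoff_um Strict upper bound on activity (default 10).
#' @param min_atoms,max_atoms Strict heavy-atom bounds (defaults 5 and 80).
#' @param min_phase Minimum clinical phase, inclusive (default 1).
#' @param organism Required organism label (default `"human"`).
#' @return An [interaction_dataset()].
#' @export
filter_bioactivities <- function(records, activity_cutoff_um = 10,
                                 min_atoms = 5, max_atoms = 80,
                                 min_phase = 1, organism = "human") {
  records <- as_tibble(records)
  need <- c("compound", "target", "activity_type", "activity_um", "n_atoms", "phase", "organism")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("records lack columns: ", paste(miss, collapse = ", ")))
  if (!nrow(records)) abort("`records` is empty")
  known_types <- c("ki", "kd", "ic50", "ec50")
  type <- tolower(records$activity_type)
  unknown <- !(type %in% known_types)
  if (any(unknown)) {
    warn(sprintf(
      "skipping %d record(s) with unknown activity type: %s",
      sum(unknown), paste(unique(records$activity_type[unknown]), collapse = ", ")
    ))
  }
  keep <- !unknown &
    records$activity_um < activity_cutoff_um &
    records$n_atoms > min_atoms & records$n_atoms < max_atoms &
    records$phase >= min_phase &
    tolower(records$organism) == tolower(organism)
  kept <- records[keep, c("compound", "target")]
  names(kept) <- c("drug", "target")
  if (!nrow(kept)) {
    return(structure(
      list(drugs = character(), targets = character(), edges = tibble(drug = character(), target = character())),
      class = "interaction_dataset"
    ))
  }
  interaction_dataset(kept)
}

#' Time-split a pair of datasets into train and test sets
#'
#' Restricts both datasets to their shared targets, then removes from the
#' test set every interaction already present in the training set. The
#' result is a prospective-validation split: train and test share the same
#' target panel, and every test edge is new relative to training.
#'
#' @param train_raw,test_raw [interaction_dataset()] objects (e.g. an older
#'   and a newer database release).
#' @return A list with elements `train` and `test`.
#' @export
time_split <- function(train_raw, test_raw) {
  if (!nrow(train_raw$edges) || !nrow(test_raw$edges)) abort("both datasets must be non-empty")
  shared <- intersect(train_raw$targets, test_raw$targets)
  shared <- shared[shared %in% train_raw$edges$target | shared %in% test_raw$edges$target]
  if (!length(shared)) abort("train and test share no targets")
  tr_edges <- dplyr::filter(train_raw$edges, .data$target %in% shared)
  te_edges <- dplyr::filter(test_raw$edges, .data$target %in% shared)
  te_edges <- dplyr::anti_join(te_edges, tr_edges, by = c("drug", "target"))
  train <- interaction_dataset(tr_edges,
    drugs = unique(tr_edges$drug), targets = shared
  )
  test <- structure(
    list(drugs = unique(te_edges$drug), targets = shared, edges = te_edges),
    class = "interaction_dataset"
  )
  list(train = train, test = test)
}

#' Restrict a dataset to a subset of drugs
#'
#' Removes all edges of drugs outside `keep` (and the drugs themselves from
#' the node list). Targets are retained even if they become disconnected;
#' validation harnesses mask disconnected targets at evaluation time.
#'
#' @param ds An [interaction_dataset()].
#' @param keep Character vector of drug IDs to keep.
#' @return An [interaction_dataset()].
#' @export
subset_drugs <- function(ds, keep) {
  structure(
    list(
      drugs = ds$drugs[ds$drugs %in% keep],
      targets = ds$targets,
      edges = dplyr::filter(ds$edges, .data$drug %in% keep)
    ),
    class = "interaction_dataset"
  )
}

#' Remove a specific set of edges from a dataset
#'
#' @param ds An [interaction_dataset()].
#' @param edges Data frame with columns `drug`, `target` of edges to drop.
#'   Node lists are unchanged.
#' @return An [interaction_dataset()].
#' @export
remove_edges <- function(ds, edges) {
  kept <- dplyr::anti_join(ds$edges, as_tibble(edges)[c("drug", "target")],
    by = c("drug", "target")
  )
  structure(
    list(drugs = ds$drugs, targets = ds$targets, edges = kept),
    class = "interaction_dataset"
  )
}
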