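#' Bemis-Murcko scaffold of a molecule
#'
#' Extracts the molecular framework -- ring systems plus the linkers
#' connecting them, with all side chains removed -- and returns it as a
#' canonical SMILES string. The framework is the 2-core of the heavy-atom
#' graph (iteratively pruning terminal atoms removes every acyclic side
#' chain but never a ring or an inter-ring linker), augmented with atoms
#' attached to the framework by a double or triple bond (e.g. carbonyl
#' oxygens on a ring). Acyclic molecules have an empty scaffold and return
#' `""`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules, `NA` for unparseable input).
#' @examples
#' \donttest{
#' murcko_scaffold(c("Cc1ccccc1", "CCO")) # benzene, ""
#' }
#' @export
murcko_scaffold <- function(smiles) {
  vapply(smiles, murcko_scaffold_one, "", USE.NAMES = !is.null(names(smiles)))
}

murcko_scaffold_one <- function(smi) {
  if (is.na(smi) || !nzchar(smi)) {
    return(NA_character_)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(smi, "m")))[[1]],
    error = function(e) NULL
  )
  if (is.null(sdf)) {
    return(NA_character_)
  }
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (is.null(bb) || nrow(bb) == 0 || n < 3) {
    return("")
  }
  from <- bb[, 1]
  to <- bb[, 2]
  order_ <- bb[, 3]
  # 2-core: iteratively delete degree-1 atoms (side chains)
  keep <- rep(TRUE, n)
  repeat {
    deg <- tabulate(c(from[keep[from] & keep[to]], to[keep[from] & keep[to]]), n)
    drop <- keep & deg <= 1
    if (!any(drop)) break
    keep[drop] <- FALSE
    if (!any(keep)) {
      return("")
    }
  }
  # re-attach atoms multiple-bonded to the framework (exocyclic =O etc.)
  multi <- order_ > 1
  add_from <- multi & keep[to] & !keep[from]
  add_to <- multi & keep[from] & !keep[to]
  keep[from[add_from]] <- TRUE
  keep[to[add_to]] <- TRUE
  atoms <- which(keep)
  bonds <- which(keep[from] & keep[to])
  if (!length(atoms)) {
    return("")
  }
  idx <- match(seq_len(n), atoms)
  elem <- gsub("_.*$", "", rownames(ab)[atoms])
  mol <- c(
    "scaffold", "  simspread", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", length(atoms), length(bonds)),
    sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      ab[atoms, 1], ab[atoms, 2], 0, elem
    ),
    sprintf("%3d%3d%3d  0  0  0  0", idx[from[bonds]], idx[to[bonds]], order_[bonds]),
    "M  END", "$$$$"
  )
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", paste(mol, collapse = "\n")),
    error = function(e) NA_character_
  )
  if (is.na(out)) {
    return(NA_character_)
  }
  strsplit(trimws(out), "[[:space:]]+")[[1]][1]
}

#' Classify scaffolds as known or novel relative to a training set
#'
#' A scaffold is "known" if it also occurs among the training scaffolds and
#' "novel" otherwise; empty scaffolds (acyclic molecules) are flagged.
#'
#' @param scaffolds Character vector of scaffold SMILES.
#' @param train_scaffolds Character vector of training-set scaffold SMILES.
#' @return Character vector with values `"known"`/`"novel"` (`NA` for empty
#'   scaffolds).
#' @export
scaffold_novelty <- function(scaffolds, train_scaffolds) {
  out <- ifelse(scaffolds %in% setdiff(train_scaffolds, ""), "known", "novel")
  out[!nzchar(scaffolds) | is.na(scaffolds)] <- NA_character_
  out
}

#' Read a target GO-annotation table
#'
#' Two-column TSV (target ID, GO term), one row per annotation. The term
#' vocabulary is the union of all terms in the file.
#'
#' @param path Path to the TSV.
#' @return Binary matrix, targets in rows, GO terms in columns.
#' @export
read_go_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("target", "term"))
  targets <- unique(df$target)
  terms <- unique(df$term)
  m <- matrix(0L, length(targets), length(terms), dimnames = list(targets, terms))
  m[cbind(df$target, df$term)] <- 1L
  m
}

#' Scaffold and target diversity of the top-L predictions
#'
#' Pools the predictions of all queries, sorts them globally by score
#' (deterministic tie-breaking: score descending, then query ID, then target
#' ID), and for each list length L counts the unique scaffolds among the
#' query compounds -- split into scaffolds known from the training set and
#' novel ones -- and the unique targets. Growing, diverse counts indicate
#' scaffold- and target-hopping behaviour.
#'
#' @param predictions Tibble `(query, target, score)` pooled over queries.
#' @param train_scaffolds Character vector of training-set scaffold SMILES.
#' @param query_scaffolds Named character vector mapping query ID to
#'   scaffold SMILES.
#' @param L_grid Integer vector of list lengths (default `seq(10, 1000, 10)`).
#' @return A tibble `(L, n_known_scaffolds, n_novel_scaffolds,
#'   n_unique_scaffolds, n_unique_targets)`.
#' @export
diversity_curves <- function(predictions, train_scaffolds, query_scaffolds,
                             L_grid = seq(10, 1000, by = 10)) {
  preds <- as_tibble(predictions)
  preds <- dplyr::arrange(preds, dplyr::desc(.data$score), .data$query, .data$target)
  if (any(L_grid > nrow(preds))) {
    warn(sprintf(
      "L values above the %d available predictions are truncated", nrow(preds)
    ))
    L_grid <- unique(pmin(L_grid, nrow(preds)))
  }
  missing_scaf <- setdiff(unique(preds$query), names(query_scaffolds))
  if (length(missing_scaf)) {
    abort(paste0("no scaffold for query(s): ", paste(head(missing_scaf, 5), collapse = ", ")))
  }
  scaf <- query_scaffolds[preds$query]
  nov <- scaffold_novelty(scaf, train_scaffolds)
  purrr::map_dfr(sort(L_grid), function(L) {
    s <- scaf[seq_len(L)]
    v <- nov[seq_len(L)]
    first <- !duplicated(s) & nzchar(s) & !is.na(s)
    tibble(
      L = L,
      n_known_scaffolds = sum(first & v == "known", na.rm = TRUE),
      n_novel_scaffolds = sum(first & v == "novel", na.rm = TRUE),
      n_unique_scaffolds = sum(first),
      n_unique_targets = dplyr::n_distinct(preds$target[seq_len(L)])
    )
  })
}

#' Two-dimensional embedding of binary descriptor vectors
#'
#' Deterministic visualization utility: classical multidimensional scaling
#' (principal coordinates) of the Jaccard distances between rows. Meant for
#' plotting chemical or target space coverage only -- no quantitative
#' analysis in this package depends on it.
#'
#' @param vectors Binary matrix (items in rows).
#' @param seed Unused (the embedding is deterministic); accepted so callers
#'   can treat all embedders uniformly.
#' @return Numeric matrix with two columns (`dim1`, `dim2`).
#' @export
embed_2d <- function(vectors, seed = 1) {
  m <- as.matrix(vectors)
  if (nrow(m) < 3) abort("need at least 3 rows to embed")
  inter <- m %*% t(m)
  sz <- rowSums(m)
  un <- outer(sz, sz, `+`) - inter
  d <- 1 - ifelse(un == 0, 1, inter / un)
  coords <- cmdscale(stats::as.dist(d), k = 2)
  colnames(coords) <- c("dim1", "dim2")
  coords
}
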