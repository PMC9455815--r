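supported_fingerprints <- c("ECFP4", "MACCS", "FP2", "FP4")

new_descriptor_matrix <- function(m, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  if (is.null(rownames(m))) abort("descriptor matrix needs compound IDs as rownames")
  if (kind == "binary" && !all(m %in% c(0, 1))) {
    abort("binary descriptor matrix may contain only 0/1")
  }
  structure(m, kind = kind, class = c("descriptor_matrix", class(m)))
}

descriptor_kind <- function(m) attr(m, "kind") %||% if (all(m %in% c(0, 1))) "binary" else "continuous"

#' Compute binary molecular fingerprints from SMILES
#'
#' Calculates folded binary fingerprints with the OpenBabel backend
#' (via ChemmineR/ChemmineOB). Supported descriptors: `ECFP4`
#' (extended-connectivity, radius 2, folded to 4096 bits), `MACCS`, `FP2`
#' and `FP4`. Other descriptor families (e.g. FCFP4, Klekota-Roth) are not
#' provided by this backend; import them as a precomputed matrix with
#' [read_descriptor_matrix()] instead.
#'
#' @param smiles Named character vector of SMILES (names = compound IDs), or
#'   a data frame with columns `id` and `smiles`.
#' @param descriptor Fingerprint name; one of `"ECFP4"`, `"MACCS"`, `"FP2"`,
#'   `"FP4"`.
#' @return A binary descriptor matrix (compounds in rows, named by ID).
#' @examples
#' \donttest{
#' fp <- compute_fingerprints(c(benzene = "c1ccccc1", toluene = "Cc1ccccc1"))
#' tanimoto(fp["benzene", ], fp["benzene", ]) # 1
#' }
#' @export
compute_fingerprints <- function(smiles, descriptor = "ECFP4") {
  if (is.data.frame(smiles)) {
    smiles <- setNames(as.character(smiles$smiles), as.character(smiles$id))
  }
  if (is.null(names(smiles)) || any(!nzchar(names(smiles)))) {
    names(smiles) <- paste0("cmp", seq_along(smiles))
  }
  if (anyDuplicated(names(smiles))) abort("duplicate compound IDs in `smiles`")
  if (!descriptor %in% supported_fingerprints) {
    abort(sprintf(
      "unsupported descriptor '%s'; supported: %s",
      descriptor, paste(supported_fingerprints, collapse = ", ")
    ))
  }
  bad <- names(smiles)[is.na(smiles) | !nzchar(smiles) | !smiles_valid(smiles)]
  if (length(bad)) {
    abort(paste0("unparseable SMILES for compound(s): ", paste(bad, collapse = ", ")))
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  suppressWarnings(ChemmineR::cid(sdf) <- names(smiles))
  fp <- suppressWarnings(ChemmineR::fingerprintOB(sdf, descriptor))
  m <- methods::slot(fp, "fpma") # as.matrix() fails on single-compound sets
  rownames(m) <- names(smiles)
  new_descriptor_matrix(m, "binary")
}

smiles_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\tx\n")),
      error = function(e) ""
    )
    nzchar(trimws(out))
  }, logical(1), USE.NAMES = FALSE)
}

#' Read a SMILES (.smi) file
#'
#' Each line holds a SMILES string, whitespace, and a compound ID.
#'
#' @param path Path to the file.
#' @return Named character vector of SMILES.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("empty SMILES file: ", path))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  smi <- vapply(parts, `[`, "", 1)
  ids <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
  ids[is.na(ids)] <- paste0("cmp", which(is.na(ids)))
  setNames(smi, ids)
}

#' Write SMILES to a .smi file
#' @param smiles Named character vector of SMILES.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(smiles, path) {
  writeLines(paste(smiles, names(smiles), sep = "\t"), path)
  invisible(path)
}

#' Read/write a descriptor matrix as TSV
#'
#' The format is one row per compound: compound ID followed by the numeric
#' descriptor columns, with a header line. Use this to import descriptors
#' computed with external tools (e.g. FCFP4, Klekota-Roth bits or
#' real-valued topological descriptor sets).
#'
#' @param path File path.
#' @param kind `"binary"` or `"continuous"`. Continuous matrices should be
#'   passed through [normalize_columns()] before similarity calculation.
#' @return A descriptor matrix with compound IDs as rownames.
#' @export
read_descriptor_matrix <- function(path, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  m <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  new_descriptor_matrix(as.matrix(m), kind)
}

#' @rdname read_descriptor_matrix
#' @param m Descriptor matrix.
#' @export
write_descriptor_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m)), check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Normalize descriptor columns to the unit interval
#'
#' Maps each column linearly so its minimum becomes 0 and its maximum 1,
#' the required preprocessing before the continuous Tanimoto coefficient.
#' Constant columns map to 0 (rather than NaN) so that the similarity stays
#' finite.
#'
#' @param m Numeric matrix (compounds in rows).
#' @return A continuous descriptor matrix with values in \[0, 1\].
#' @export
normalize_columns <- function(m) {
  m <- as.matrix(m)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  rng <- hi - lo
  out <- sweep(m, 2, lo)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], `/`)
  out[, !nz] <- 0
  new_descriptor_matrix(out, "continuous")
}
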