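#' Structure ensembles
#'
#' A structure ensemble is a set of models (conformers) sharing one atom
#' roster, as deposited for NMR structures. Coordinates are stored as an
#' `n_atoms x 3 x n_models` array in Angstrom.
#'
#' @param atoms data frame with columns `residue_index`, `residue_name`,
#'   `atom`, `element`.
#' @param xyz numeric array `n_atoms x 3 x n_models`.
#' @param source free-text provenance label.
#' @return Object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, xyz, source = "") {
  need <- c("residue_index", "residue_name", "atom", "element")
  if (!all(need %in% names(atoms)))
    stop("structure_ensemble atoms missing columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  if (length(dim(xyz)) == 2L) xyz <- array(xyz, c(dim(xyz), 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[1] == nrow(atoms),
            dim(xyz)[2] == 3L, dim(xyz)[3] >= 1L)
  structure(list(atoms = as.data.frame(atoms)[need], xyz = xyz,
                 source = source),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d models, %d atoms, residues %d-%d",
              n_models(x), nrow(x$atoms), min(x$atoms$residue_index),
              max(x$atoms$residue_index)))
  if (nzchar(x$source)) cat(sprintf(" [%s]", x$source))
  cat("\n")
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble a [structure_ensemble].
#' @return Integer model count.
#' @export
n_models <- function(ensemble) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  dim(ensemble$xyz)[3]
}

#' Extract one model's coordinates
#' @param ensemble a [structure_ensemble].
#' @param i model number.
#' @return `n_atoms x 3` coordinate matrix.
#' @export
model_coords <- function(ensemble, i = 1L) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  ensemble$xyz[, , i, drop = TRUE]
}

## Row indices of atoms matching a residue range / atom set / element
## filter; `atoms = "backbone"` means N, CA, C and `"heavy"` all
## non-hydrogen atoms.
select_atoms <- function(ensemble, residues = NULL, atoms = "heavy") {
  a <- ensemble$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(residues)) keep <- keep & a$residue_index %in% residues
  if (identical(atoms, "backbone")) {
    keep <- keep & a$atom %in% c("N", "CA", "C")
  } else if (identical(atoms, "heavy")) {
    keep <- keep & toupper(a$element) != "H"
  } else if (!identical(atoms, "all")) {
    keep <- keep & a$atom %in% atoms
  }
  which(keep)
}

#' Read a (multi-model) PDB file into a structure ensemble
#'
#' Models are delimited by MODEL/ENDMDL records; a file without MODEL
#' records is read as a single-model ensemble. Each model is parsed with
#' \pkg{bio3d}. Atoms present in only a subset of the models are dropped
#' with a warning so that every model shares one atom roster.
#'
#' @param path PDB file.
#' @return A [structure_ensemble].
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  chunks <- if (length(starts)) {
    if (length(starts) != length(ends))
      stop(path, ": unbalanced MODEL/ENDMDL records", call. = FALSE)
    Map(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends)
  } else list(lines)
  models <- lapply(chunks, function(ch) {
    if (!any(grepl("^(ATOM|HETATM)", ch))) return(NULL)
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(ch, tf)
    p <- bio3d::read.pdb(tf, verbose = FALSE)
    at <- p$atom
    el <- trimws(at$elesy)
    blank <- is.na(el) | !nzchar(el)
    el[blank] <- element_from_atom_name(at$elety[blank])
    data.frame(residue_index = at$resno, residue_name = trimws(at$resid),
               atom = trimws(at$elety), element = toupper(el),
               chain = ifelse(is.na(at$chain), "", at$chain),
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  })
  models <- models[!vapply(models, is.null, logical(1))]
  if (!length(models))
    stop(path, ": no ATOM records found", call. = FALSE)

  key <- function(m) paste(m$chain, m$residue_index, m$atom)
  common <- Reduce(intersect, lapply(models, key))
  n_drop <- sum(vapply(models, nrow, integer(1))) -
    length(common) * length(models)
  if (n_drop > 0L)
    warning(sprintf(
      "%s: dropped %d atom record(s) absent from some models",
      basename(path), n_drop))
  if (!length(common)) stop(path, ": models share no atoms", call. = FALSE)

  ref <- models[[1]]
  ref <- ref[match(common, key(ref)), , drop = FALSE]
  xyz <- array(NA_real_, c(nrow(ref), 3L, length(models)))
  for (k in seq_along(models)) {
    m <- models[[k]]
    idx <- match(common, key(m))
    xyz[, , k] <- as.matrix(m[idx, c("x", "y", "z")])
  }
  structure_ensemble(
    ref[c("residue_index", "residue_name", "atom", "element")],
    xyz, source = basename(path))
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' @param ensemble a [structure_ensemble].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  a <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_models(ensemble))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- ensemble$xyz[, , k]
    rec <- ifelse(a$element == "ZN", "HETATM", "ATOM  ")
    writeLines(sprintf(
      "%s%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      rec, seq_len(nrow(a)),
      ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
      a$residue_name, a$residue_index,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
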