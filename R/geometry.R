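## Rigid-body superposition and ensemble coordinate statistics.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' ||R b + t - a||^2 over matched atom rows, via the SVD construction with
#' the determinant (reflection) guard, and reports the post-fit RMSD.
#'
#' @param model_a,model_b `n x 3` coordinate matrices (b is moved onto a).
#' @param atom_selection optional row indices of the atoms to fit.
#' @return Object of class `superposition` with `rotation` (3x3,
#'   det +1), `translation` (length 3), `rmsd` (Angstrom).
#' @export
superpose <- function(model_a, model_b, atom_selection = NULL) {
  a <- as.matrix(model_a); b <- as.matrix(model_b)
  if (!is.null(atom_selection)) {
    a <- a[atom_selection, , drop = FALSE]
    b <- b[atom_selection, , drop = FALSE]
  }
  stopifnot(ncol(a) == 3L, all(dim(a) == dim(b)))
  if (nrow(a) < 3L) stop("superpose: need >= 3 matched atoms")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  sv_a <- svd(a0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1))
    stop("superpose: selection is collinear")
  H <- crossprod(b0, a0)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(ca - R %*% cb)
  moved <- b %*% t(R) + matrix(t_vec, nrow(b), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - a)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

## Apply a superposition transform to an n x 3 coordinate matrix.
apply_transform <- function(xyz, sp) {
  as.matrix(xyz) %*% t(sp$rotation) +
    matrix(sp$translation, nrow(xyz), 3L, byrow = TRUE)
}

#' Average pairwise RMSD over an ensemble
#'
#' Superposes every unordered model pair on the selected atoms and
#' reports mean and standard deviation of the pairwise RMSDs — the usual
#' precision statistic quoted for NMR ensembles. `atom_set = "backbone"`
#' uses N, CA, C; `"heavy"` all non-hydrogen atoms of the selection.
#'
#' @param ensemble a [structure_ensemble].
#' @param residues residue indices of the selection (default all).
#' @param atom_set `"backbone"` or `"heavy"`.
#' @return List with `mean`, `sd` (Angstrom), `n_pairs`, `n_atoms`.
#' @export
average_pairwise_rmsd <- function(ensemble, residues = NULL,
                                  atom_set = c("backbone", "heavy")) {
  atom_set <- match.arg(atom_set)
  stopifnot(inherits(ensemble, "structure_ensemble"))
  sel <- select_atoms(ensemble, residues, atom_set)
  if (!length(sel)) stop("average_pairwise_rmsd: empty atom selection")
  nm <- n_models(ensemble)
  if (nm < 2L) stop("average_pairwise_rmsd: need >= 2 models")
  pairs <- utils::combn(nm, 2L)
  rmsds <- vapply(seq_len(ncol(pairs)), function(k) {
    superpose(ensemble$xyz[sel, , pairs[1, k]],
              ensemble$xyz[sel, , pairs[2, k]])$rmsd
  }, numeric(1))
  list(mean = mean(rmsds), sd = stats::sd(rmsds),
       n_pairs = length(rmsds), n_atoms = length(sel))
}

#' Ordered residues by CA fluctuation
#'
#' Superposes all models onto model 1 on all CA atoms, computes the
#' per-residue CA root-mean-square fluctuation about the ensemble mean
#' position, and calls residues with RMSF below the threshold "ordered".
#'
#' @param ensemble a [structure_ensemble].
#' @param rmsf_threshold ordered/disordered cutoff in Angstrom
#'   (default 1.0).
#' @return Object of class `ordered_region` with `residues` (ordered set),
#'   `rmsf` (named per-residue vector), `threshold`.
#' @export
ordered_residues <- function(ensemble, rmsf_threshold = 1.0) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  nm <- n_models(ensemble)
  if (nm < 2L) stop("ordered_residues: need >= 2 models")
  sel <- select_atoms(ensemble, atoms = "CA")
  if (!length(sel)) stop("ordered_residues: no CA atoms")
  res <- ensemble$atoms$residue_index[sel]
  coords <- array(NA_real_, c(length(sel), 3L, nm))
  coords[, , 1] <- ensemble$xyz[sel, , 1]
  for (k in seq_len(nm)[-1]) {
    sp <- superpose(ensemble$xyz[sel, , 1], ensemble$xyz[sel, , k])
    coords[, , k] <- apply_transform(ensemble$xyz[sel, , k], sp)
  }
  mean_xyz <- apply(coords, c(1L, 2L), mean)
  dev2 <- vapply(seq_len(nm), function(k)
    rowSums((coords[, , k] - mean_xyz)^2), numeric(length(sel)))
  rmsf <- sqrt(rowMeans(matrix(dev2, nrow = length(sel))))
  names(rmsf) <- res
  structure(list(residues = res[rmsf < rmsf_threshold], rmsf = rmsf,
                 threshold = rmsf_threshold),
            class = "ordered_region")
}

#' @export
print.ordered_region <- function(x, ...) {
  cat(sprintf("<ordered_region> %d/%d residues ordered (CA RMSF < %.2f A)\n",
              length(x$residues), length(x$rmsf), x$threshold))
  invisible(x)
}
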