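## Shared fixtures: everything is generated in code at test time.

with_seed <- bboxnmr:::with_seed

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## Minimal peak list built directly (bypassing file parsing).
make_peaks <- function(residues, H, N, site = "backbone",
                       intensity = 1e6) {
  peak_list(data.frame(
    residue_index = residues, residue_name = "ALA",
    site = rep_len(site, length(residues)),
    atom1 = "N", atom2 = "H",
    w1 = N, w2 = H, intensity = intensity))
}

## Shift table from a wide data frame of residue/atom values.
make_shifts <- function(residue_index, residue_name, ...) {
  vals <- list(...)
  rows <- do.call(rbind, lapply(seq_along(residue_index), function(i) {
    atoms <- names(vals)
    data.frame(residue_index = residue_index[i],
               residue_name = residue_name[i], atom = atoms,
               shift = vapply(atoms, function(a) vals[[a]][i], numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[is.finite(rows$shift), , drop = FALSE]
  shift_table(rows)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_xyz <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax); cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

## Brute-force minimal RMSD over rotations: multi-start quasi-Newton on
## Euler angles after centroid alignment; independent oracle for the SVD
## superposition route.
brute_rmsd <- function(a, b, n_starts = 30L) {
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  obj <- function(p) {
    R <- rot_xyz(p[1], p[2], p[3])
    sqrt(mean(rowSums((b0 %*% t(R) - a0)^2)))
  }
  starts <- with_seed(11L, matrix(stats::runif(3 * n_starts, 0, 2 * pi),
                                  ncol = 3))
  min(apply(starts, 1, function(s)
    stats::optim(s, obj, method = "BFGS",
                 control = list(reltol = 1e-14))$value))
}

## Paths where the deposited reference data would live if present. The
## repository ships no third-party coordinate or restraint deposits; the
## deposit-dependent checks operate on these paths.
deposited_ensemble_path <- function() {
  system.file("extdata", "5jpx.pdb", package = "bboxnmr")
}
deposited_restraints_path <- function() {
  system.file("extdata", "5jpx_noe.upl", package = "bboxnmr")
}
require_deposit <- function(path, what) {
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf(
      "deposited %s not available offline; place the file under inst/extdata to run this check",
      what), call. = FALSE)
  path
}
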