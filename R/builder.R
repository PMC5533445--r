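## Idealized polypeptide backbone construction from internal coordinates
## (NeRF chain extension). Used by the synthetic ensemble generator:
## helices from canonical (phi, psi), hairpins from template dihedrals.

## Place atom D given three prior atoms A-B-C, the C-D bond length, the
## B-C-D angle (degrees) and the A-B-C-D dihedral (degrees).
nerf_place <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(C - B)
  n <- unit(pracma_cross(B - A, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Ideal backbone internal coordinates (Engh-Huber-like).
.bb_geo <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                ang_c_n_ca = 121.7)

## CB direction solving d.t = cos(110.5 deg), d.u = cos(110.1 deg) in the
## local (t, u, w) frame; the out-of-plane root is taken consistently.
place_cb <- function(N, CA, C, bond = 1.53) {
  t <- unit(N - CA); u <- unit(C - CA)
  w <- unit(pracma_cross(u, t))
  ct <- cos(110.5 * pi / 180); cu <- cos(110.1 * pi / 180)
  tu <- sum(t * u)
  ## d = a t + b u + c w with d.t = ct, d.u = cu
  a <- (ct - cu * tu) / (1 - tu^2)
  b <- (cu - ct * tu) / (1 - tu^2)
  c2 <- 1 - (a^2 + b^2 + 2 * a * b * tu)
  d <- a * t + b * u + sqrt(max(c2, 0)) * w
  CA + bond * unit(d)
}

#' Build an idealized backbone from dihedral angles
#'
#' Constructs N, CA, C, O (and CB except for glycine) coordinates for a
#' poly-residue chain from per-residue (phi, psi) with ideal bond lengths
#' and angles and trans peptide bonds. Residue names default to alanine.
#'
#' @param phi,psi numeric vectors of backbone dihedrals in degrees (length
#'   = number of residues; `phi[1]` and `psi[n]` shape the termini).
#' @param residue_names 3-letter residue names (recycled).
#' @param first_residue numbering of the first residue.
#' @return List `atoms` (data frame) + `xyz` (matrix), consumable by
#'   [structure_ensemble()].
#' @export
build_backbone <- function(phi, psi, residue_names = "ALA",
                           first_residue = 1L) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  residue_names <- rep_len(residue_names, n)
  g <- .bb_geo
  ## seed the first residue in a standard frame
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C1 <- CA1 + g$ca_c * c(-cos(ang), sin(ang), 0)
  Ns <- list(N1); CAs <- list(CA1); Cs <- list(C1)
  for (i in seq_len(n - 1L)) {
    Ni1 <- nerf_place(Ns[[i]], CAs[[i]], Cs[[i]], g$c_n, g$ang_ca_c_n,
                      psi[i])
    CAi1 <- nerf_place(CAs[[i]], Cs[[i]], Ni1, g$n_ca, g$ang_c_n_ca,
                       180)                      # omega, trans
    Ci1 <- nerf_place(Cs[[i]], Ni1, CAi1, g$ca_c, g$ang_n_ca_c,
                      phi[i + 1L])
    Ns[[i + 1L]] <- Ni1; CAs[[i + 1L]] <- CAi1; Cs[[i + 1L]] <- Ci1
  }
  ## carbonyl O: anti to the bisector of (next N, CA) as seen from C; the
  ## last residue uses a virtual next N extended with its psi
  Os <- vector("list", n)
  for (i in seq_len(n)) {
    Nn <- if (i < n) Ns[[i + 1L]] else
      nerf_place(Ns[[i]], CAs[[i]], Cs[[i]], g$c_n, g$ang_ca_c_n, psi[i])
    dir <- -(unit(Nn - Cs[[i]]) + unit(CAs[[i]] - Cs[[i]]))
    Os[[i]] <- Cs[[i]] + g$c_o * unit(dir)
  }
  rows <- list(); xyz <- list()
  for (i in seq_len(n)) {
    res <- first_residue + i - 1L
    add <- function(at, el, co) {
      rows[[length(rows) + 1L]] <<- data.frame(
        residue_index = res, residue_name = residue_names[i], atom = at,
        element = el, stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <<- co
    }
    add("N", "N", Ns[[i]]); add("CA", "C", CAs[[i]])
    add("C", "C", Cs[[i]]); add("O", "O", Os[[i]])
    if (residue_names[i] != "GLY")
      add("CB", "C", place_cb(Ns[[i]], CAs[[i]], Cs[[i]]))
  }
  list(atoms = do.call(rbind, rows), xyz = do.call(rbind, xyz))
}

## Dihedral templates for the generator topologies.
topology_dihedrals <- function(topology, length) {
  switch(topology,
    helix = list(phi = rep(-57, length), psi = rep(-47, length),
                 core = seq_len(length)),
    hairpin = {
      ## two antiparallel strands joined by a type II-prime turn
      ns <- (length - 2L) %/% 2L
      n2 <- length - 2L - ns
      phi <- c(rep(-139, ns), 60, -80, rep(-139, n2))
      psi <- c(rep(135, ns), -120, 0, rep(135, n2))
      list(phi = phi, psi = psi, core = seq_len(length))
    },
    `helix+tail` = {
      ncore <- max(ceiling(2 * length / 3), 5L)
      ntail <- length - ncore
      list(phi = c(rep(-57, ncore), rep(-120, ntail)),
           psi = c(rep(-47, ncore), rep(130, ntail)),
           core = seq_len(ncore))
    },
    stop("unknown topology: ", topology))
}
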