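## DSSP-style secondary structure from backbone geometry: Kabsch-Sander
## hydrogen-bond energies, 4-turn helices and bridge/ladder strands,
## collapsed to the three states H (helix), E (strand), C (coil).

## Per-residue backbone atom coordinates from an atom table + xyz matrix.
## Returns list of matrices N, CA, C, O (rows = residues, NA when absent)
## and the residue index / name vectors.
backbone_frames <- function(atoms, xyz) {
  res <- unique(atoms$residue_index)
  pick <- function(at) {
    idx <- match(paste(res, at), paste(atoms$residue_index, atoms$atom))
    out <- matrix(NA_real_, length(res), 3L)
    ok <- !is.na(idx)
    out[ok, ] <- xyz[idx[ok], , drop = FALSE]
    out
  }
  list(residue_index = res,
       residue_name = atoms$residue_name[match(res, atoms$residue_index)],
       N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"),
       H = pick("H"))
}

unit <- function(v) v / sqrt(sum(v^2))

## Amide H positions: use the file's H where present, otherwise rebuild at
## 1.01 A from N along the bisector of the C(i-1)->N and CA->N directions.
## No donor for the first residue or prolines.
amide_h <- function(bb) {
  n <- length(bb$residue_index)
  H <- bb$H
  for (i in seq_len(n)) {
    if (all(is.finite(H[i, ]))) next
    if (i == 1L || bb$residue_name[i] == "PRO") next
    if (bb$residue_index[i] - bb$residue_index[i - 1L] != 1L) next
    if (any(!is.finite(bb$N[i, ])) || any(!is.finite(bb$CA[i, ])) ||
        any(!is.finite(bb$C[i - 1L, ]))) next
    d <- unit(unit(bb$N[i, ] - bb$C[i - 1L, ]) +
                unit(bb$N[i, ] - bb$CA[i, ]))
    H[i, ] <- bb$N[i, ] + 1.01 * d
  }
  ## never donate through a proline or the chain start
  H[1L, ] <- NA_real_
  H[bb$residue_name == "PRO", ] <- NA_real_
  H
}

## Kabsch-Sander H-bond energy matrix: E[i, j] is the energy (kcal/mol) of
## the bond donated by NH(i) to CO(j); bonded if E < -0.5. Pairs closer
## than |i - j| < 2 in sequence are excluded, as are CA pairs beyond 9 A.
ks_hbond_matrix <- function(bb, H) {
  n <- length(bb$residue_index)
  E <- matrix(Inf, n, n)
  q <- 0.084 * 332
  dst <- function(p, q2) sqrt(sum((p - q2)^2))
  for (i in seq_len(n)) {
    if (any(!is.finite(H[i, ])) || any(!is.finite(bb$N[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L) next
      if (any(!is.finite(bb$O[j, ])) || any(!is.finite(bb$C[j, ]))) next
      if (dst(bb$CA[i, ], bb$CA[j, ]) > 9) next
      rON <- dst(bb$O[j, ], bb$N[i, ])
      rCH <- dst(bb$C[j, ], H[i, ])
      rOH <- dst(bb$O[j, ], H[i, ])
      rCN <- dst(bb$C[j, ], bb$N[i, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) { E[i, j] <- -9.9; next }
      E[i, j] <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  E
}

#' Secondary structure of one model (DSSP-style, 3 states)
#'
#' Assigns H/E/C from backbone hydrogen bonding: the Kabsch-Sander
#' electrostatic H-bond energy (bond if E < -0.5 kcal/mol), alpha-helices
#' from runs of at least two consecutive i+4 -> i turns, and strands from
#' parallel/antiparallel bridge pairings; 3-10/pi helices and bends are
#' collapsed into the three states. Missing amide protons are rebuilt
#' geometrically; residues lacking backbone N, CA, C or O are marked "?".
#'
#' @param ensemble a [structure_ensemble] (or pass `atoms` + `xyz`).
#' @param model model number within the ensemble.
#' @return Character vector of per-residue states, named by residue index.
#' @export
secondary_structure <- function(ensemble, model = 1L) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  bb <- backbone_frames(ensemble$atoms, model_coords(ensemble, model))
  n <- length(bb$residue_index)
  state <- rep("C", n)
  complete <- rowSums(!is.finite(cbind(bb$N, bb$CA, bb$C, bb$O))) == 0
  state[!complete] <- "?"
  if (n >= 3L) {
    H <- amide_h(bb)
    E <- ks_hbond_matrix(bb, H)
    hb <- E < -0.5
    ## consecutive residue numbering guard (chain breaks)
    consec <- function(i, j) all(diff(bb$residue_index[i:j]) == 1L)

    ## 4-turns: hb[i+4, i]; helix = residues i+1..i+4 for two consecutive
    ## turns at i, i+1
    turn4 <- rep(FALSE, n)
    for (i in seq_len(max(n - 4L, 0L)))
      if (hb[i + 4L, i] && consec(i, i + 4L)) turn4[i] <- TRUE
    helix <- rep(FALSE, n)
    for (i in seq_len(max(n - 5L, 0L)))
      if (turn4[i] && turn4[i + 1L]) helix[(i + 1L):(i + 4L)] <- TRUE

    ## bridges
    bridge <- rep(FALSE, n)
    for (i in 2:(n - 1L)) {
      for (j in 2:(n - 1L)) {
        if (abs(i - j) < 3L) next
        par <- (hb[i, j - 1L] && hb[j + 1L, i]) ||
          (hb[j, i - 1L] && hb[i + 1L, j])
        anti <- (hb[i, j] && hb[j, i]) ||
          (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
        if (par || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
      }
    }
    state[bridge & complete] <- "E"
    state[helix & complete] <- "H"   # helix takes precedence
  }
  names(state) <- bb$residue_index
  state
}

#' Per-residue secondary-structure frequencies over an ensemble
#'
#' Runs [secondary_structure()] on every model and tabulates, per residue,
#' the fraction of models in each state.
#'
#' @param ensemble a [structure_ensemble].
#' @return Object of class `secondary_structure_profile`: list with
#'   `states` (model x residue character matrix), `frequency` (residue x
#'   state matrix), `consensus` (modal state per residue).
#' @export
element_frequency <- function(ensemble) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  nm <- n_models(ensemble)
  states <- t(vapply(seq_len(nm),
                     function(k) secondary_structure(ensemble, k),
                     character(length(unique(ensemble$atoms$residue_index)))))
  lv <- c("H", "E", "C")
  freq <- t(apply(states, 2L, function(col)
    c(H = mean(col == "H"), E = mean(col == "E"), C = mean(col == "C"))))
  consensus <- lv[max.col(freq, ties.method = "last")]
  names(consensus) <- colnames(states)
  structure(list(states = states, frequency = freq, consensus = consensus),
            class = "secondary_structure_profile")
}

#' @export
print.secondary_structure_profile <- function(x, ...) {
  cat(sprintf("<secondary_structure_profile> %d models\n  consensus: %s\n",
              nrow(x$states), paste(x$consensus, collapse = "")))
  invisible(x)
}
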