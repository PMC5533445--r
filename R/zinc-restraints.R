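## Zinc-site restraint generation and restraint accounting: tetrahedral
## zinc coordination geometry expressed as heavy-atom distance bounds,
## NOE classification by sequence separation, and violation counting
## against a structure ensemble.

#' Define a zinc coordination site
#'
#' @param label site label (e.g. "site I").
#' @param ligands data frame with columns `residue_index`,
#'   `residue_name` (CYS, HIS or ASP) and `donor_atom` (SG for Cys, NE2 or
#'   ND1 for His, OD1 or OD2 for Asp). 2-4 ligands.
#' @return Object of class `zinc_site`.
#' @export
zinc_site <- function(label, ligands) {
  need <- c("residue_index", "residue_name", "donor_atom")
  stopifnot(all(need %in% names(ligands)))
  ligands <- as.data.frame(ligands)[need]
  ## an empty ligand table is allowed as a degenerate site (generates no
  ## restraints); a populated site must have 2-4 ligands
  if (nrow(ligands) == 1L || nrow(ligands) > 4L)
    stop("zinc_site: need 2-4 ligands")
  allowed <- list(CYS = "SG", HIS = c("NE2", "ND1"),
                  ASP = c("OD1", "OD2"))
  for (i in seq_len(nrow(ligands))) {
    rn <- ligands$residue_name[i]
    if (!rn %in% names(allowed))
      stop("zinc_site: unsupported ligand residue ", rn)
    if (!ligands$donor_atom[i] %in% allowed[[rn]])
      stop(sprintf("zinc_site: donor %s not valid for %s",
                   ligands$donor_atom[i], rn))
  }
  ligands <- ligands[order(ligands$residue_index), , drop = FALSE]
  structure(list(label = label, ligands = ligands), class = "zinc_site")
}

#' Default zinc restraint distance scheme
#'
#' Upper/lower distance bounds (Angstrom) for the pair classes emitted by
#' [generate_zinc_restraints()]. Values follow common tetrahedral
#' zinc-site calibrations: Zn-S(thiolate) ~2.3 A, Zn-N(imidazole) ~2.0 A,
#' S...S across the tetrahedron ~3.8 A, and an anchor tether keeping each
#' ligand arm oriented (Zn to the Cys CB / Asp CG at ~3.2 A).
#'
#' @return Named list of `c(lower, upper)` bounds per pair class.
#' @export
zinc_restraint_scheme <- function() {
  list(zn_sg = c(2.25, 2.40), zn_ne2 = c(1.95, 2.10),
       zn_od = c(1.90, 2.05), sg_sg = c(3.55, 3.95),
       ne2_sg = c(3.40, 3.80), sg_cb = c(3.00, 3.40),
       od_cg = c(3.00, 3.40))
}

#' Generate tetrahedral zinc-site distance restraints
#'
#' Emits, per site: a Zn-donor restraint for every ligand (the zinc is
#' addressed as a pseudo-residue "ZN" atom placed at `zn_residue`); an
#' anchor tether per Cys (Zn to CB) and per Asp (Zn to CG) keeping the
#' ligand arm oriented; all Cys SG-SG pairs; and every His-donor to Cys SG
#' pair. Together these bounds enforce a tetrahedral geometry around the
#' zinc without explicit angle terms. All bounds come from `scheme` and
#' are overridable.
#'
#' @param site a [zinc_site].
#' @param scheme bounds per pair class; see [zinc_restraint_scheme()].
#' @param zn_residue residue index assigned to the zinc pseudo-atom
#'   (default 999).
#' @return A [restraint_list] with kind "zinc", canonically ordered.
#' @export
generate_zinc_restraints <- function(site, scheme = zinc_restraint_scheme(),
                                     zn_residue = 999L) {
  stopifnot(inherits(site, "zinc_site"))
  lg <- site$ligands
  rows <- list()
  add <- function(ri, ni, ai, rj, nj, aj, bounds) {
    rows[[length(rows) + 1L]] <<- data.frame(
      res_i = ri, name_i = ni, atom_i = ai,
      res_j = rj, name_j = nj, atom_j = aj,
      lower = bounds[1], upper = bounds[2], kind = "zinc",
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(lg))) {
    rn <- lg$residue_name[i]; ri <- lg$residue_index[i]
    da <- lg$donor_atom[i]
    b <- switch(rn, CYS = scheme$zn_sg, HIS = scheme$zn_ne2,
                ASP = scheme$zn_od)
    add(zn_residue, "ZN", "ZN", ri, rn, da, b)         # Zn-donor
    if (rn == "CYS") add(zn_residue, "ZN", "ZN", ri, rn, "CB",
                         scheme$sg_cb)                 # arm tether
    if (rn == "ASP") add(zn_residue, "ZN", "ZN", ri, rn, "CG",
                         scheme$od_cg)
  }
  cys <- lg[lg$residue_name == "CYS", , drop = FALSE]
  his <- lg[lg$residue_name == "HIS", , drop = FALSE]
  if (nrow(cys) >= 2L) {
    pairs <- utils::combn(seq_len(nrow(cys)), 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      add(cys$residue_index[i], "CYS", "SG",
          cys$residue_index[j], "CYS", "SG", scheme$sg_sg)
    }
  }
  if (nrow(his) && nrow(cys)) {
    for (i in seq_len(nrow(his))) for (j in seq_len(nrow(cys)))
      add(his$residue_index[i], "HIS", his$donor_atom[i],
          cys$residue_index[j], "CYS", "SG", scheme$ne2_sg)
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  sorted <- sort_restraints(restraint_list(out))
  rownames(sorted) <- NULL
  restraint_list(sorted)
}

#' Classify NOE restraints by sequence separation
#'
#' Bins restraints of kind "NOE" by s = |res_i - res_j|: intra-residue
#' (s = 0), sequential (s = 1), medium-range (2 <= s <= 4) and long-range
#' (s >= 5). Non-NOE restraints are ignored and counted.
#'
#' @param restraints a [restraint_list].
#' @return Object of class `range_counts` with `intra`, `sequential`,
#'   `medium`, `long`, `total`, `ignored`.
#' @export
classify_noe <- function(restraints) {
  stopifnot(inherits(restraints, "restraint_list"))
  noe <- restraints[restraints$kind == "NOE", , drop = FALSE]
  s <- abs(noe$res_i - noe$res_j)
  out <- list(intra = sum(s == 0L), sequential = sum(s == 1L),
              medium = sum(s >= 2L & s <= 4L), long = sum(s >= 5L),
              total = nrow(noe),
              ignored = nrow(restraints) - nrow(noe))
  structure(out, class = "range_counts")
}

#' @export
print.range_counts <- function(x, ...) {
  cat("NOE restraint classification\n")
  cat(sprintf("  Total NOE            %5d\n", x$total))
  cat(sprintf("  Intra-residue (s=0)  %5d\n", x$intra))
  cat(sprintf("  Sequential (s=1)     %5d\n", x$sequential))
  cat(sprintf("  Medium-range (1<s<5) %5d\n", x$medium))
  cat(sprintf("  Long-range (s>=5)    %5d\n", x$long))
  if (x$ignored) cat(sprintf("  (ignored non-NOE     %5d)\n", x$ignored))
  invisible(x)
}

#' Count restraint violations against an ensemble
#'
#' A restraint is violated if in any model the inter-atomic distance
#' exceeds `upper + threshold` or falls below `lower - threshold`; the
#' count is over restraints, not model-restraint pairs, and the maximal
#' excess over models is reported per violated restraint. Restraints whose
#' atoms cannot be resolved in the ensemble roster are skipped with a
#' warning.
#'
#' @param restraints a [restraint_list].
#' @param ensemble a [structure_ensemble].
#' @param threshold violation threshold in Angstrom (default 0.5).
#' @return Object of class `violation_report` with `threshold`,
#'   `violations` (data frame with `max_excess`), `count`, `n_skipped`.
#' @export
check_violations <- function(restraints, ensemble, threshold = 0.5) {
  stopifnot(inherits(restraints, "restraint_list"),
            inherits(ensemble, "structure_ensemble"))
  a <- ensemble$atoms
  key <- paste(a$residue_index, a$atom)
  ii <- match(paste(restraints$res_i, restraints$atom_i), key)
  jj <- match(paste(restraints$res_j, restraints$atom_j), key)
  ok <- !is.na(ii) & !is.na(jj)
  n_skipped <- sum(!ok)
  if (n_skipped)
    warning(sprintf("check_violations: %d restraint(s) reference atoms absent from the ensemble, skipped",
                    n_skipped))
  r <- restraints[ok, , drop = FALSE]
  ii <- ii[ok]; jj <- jj[ok]
  nm <- n_models(ensemble)
  if (nrow(r)) {
    excess <- rep(-Inf, nrow(r))
    for (k in seq_len(nm)) {
      xyz <- ensemble$xyz[, , k]
      d <- sqrt(rowSums((xyz[ii, , drop = FALSE] -
                           xyz[jj, , drop = FALSE])^2))
      e <- pmax(d - r$upper, r$lower - d)
      excess <- pmax(excess, e)
    }
    viol <- excess > threshold
    violations <- cbind(as.data.frame(r)[viol, , drop = FALSE],
                        max_excess = excess[viol])
    rownames(violations) <- NULL
  } else {
    violations <- cbind(as.data.frame(r), max_excess = numeric())
  }
  structure(list(threshold = threshold, violations = violations,
                 count = nrow(violations), n_skipped = n_skipped),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf("<violation_report> %d violation(s) at threshold %.2f A",
              x$count, x$threshold))
  if (x$n_skipped) cat(sprintf(" (%d restraint(s) skipped)", x$n_skipped))
  cat("\n")
  if (x$count) print.data.frame(utils::head(x$violations, 10L))
  invisible(x)
}
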