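## Chemical-shift-derived inference: composite chemical shift
## perturbations (CSP), titration trajectories, chemical shift index
## (CSI) secondary structure, and cysteine zinc-coordination scoring.

#' Composite 1H/15N chemical shift perturbation
#'
#' For each (residue, site) present in both peak lists, the composite CSP
#' is sqrt(ddH^2 + (ddN/scale_N)^2), with ddH and ddN the amide 1H and 15N
#' shift changes in ppm and `scale_N` (default 6.5) compressing the wider
#' nitrogen scale onto the proton scale. Which peak dimension is 1H and
#' which is 15N is resolved from the assignment atom names. Peaks present
#' in only one list are reported in the `unmatched` attribute with a
#' warning, never silently dropped.
#'
#' @param apo,bound [peak_list] objects (reference and perturbed spectra).
#' @param scale_N nitrogen scale factor (default 6.5).
#' @return Data frame of class `csp_records` with columns `residue_index`,
#'   `site`, `delta_H`, `delta_N`, `csp` (all ppm).
#' @export
compute_csp <- function(apo, bound, scale_N = 6.5) {
  stopifnot(inherits(apo, "peak_list"), inherits(bound, "peak_list"))
  split_hn <- function(p) {
    ## map (w1, w2) onto (H, N) using the assignment atom names
    n_first <- startsWith(p$atom1, "N")
    data.frame(residue_index = p$residue_index, site = p$site,
               H = ifelse(n_first, p$w2, p$w1),
               N = ifelse(n_first, p$w1, p$w2),
               stringsAsFactors = FALSE)
  }
  a <- split_hn(apo); b <- split_hn(bound)
  ka <- paste(a$residue_index, a$site)
  kb <- paste(b$residue_index, b$site)
  common <- intersect(ka, kb)
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmatched))
    warning(sprintf("compute_csp: %d unmatched peak(s): %s",
                    length(unmatched),
                    paste(utils::head(unmatched, 10L), collapse = "; ")))
  if (!length(common)) {
    warning("compute_csp: no matched sites")
    out <- data.frame(residue_index = integer(), site = character(),
                      delta_H = numeric(), delta_N = numeric(),
                      csp = numeric(), stringsAsFactors = FALSE)
  } else {
    ia <- match(common, ka); ib <- match(common, kb)
    dH <- b$H[ib] - a$H[ia]
    dN <- b$N[ib] - a$N[ia]
    out <- data.frame(residue_index = a$residue_index[ia],
                      site = a$site[ia], delta_H = dH, delta_N = dN,
                      csp = sqrt(dH^2 + (dN / scale_N)^2),
                      stringsAsFactors = FALSE)
    out <- out[order(out$residue_index, out$site), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("csp_records", "data.frame"),
            unmatched = unmatched, scale_N = scale_N)
}

#' Select significantly perturbed sites
#'
#' @param records a `csp_records` data frame from [compute_csp()].
#' @param cutoff CSP significance cutoff in ppm, inclusive (default 0.10).
#' @return The subset of `records` with `csp >= cutoff`, with a
#'   `site_label` column ("96" for backbone, "112sc" for side chains).
#' @export
select_significant <- function(records, cutoff = 0.10) {
  stopifnot(cutoff >= 0)
  out <- as.data.frame(records)[records$csp >= cutoff, , drop = FALSE]
  out$site_label <- paste0(out$residue_index,
                           ifelse(out$site == "sidechain", "sc", ""))
  rownames(out) <- NULL
  out
}

#' Titration series
#'
#' Amide 1H/15N positions of tracked sites across titrant equivalents.
#' The first point must be the apo (0 equivalents) reference.
#'
#' @param equivalents non-negative, strictly increasing; first element 0.
#' @param sites data frame with `residue_index`, `site`.
#' @param H,N matrices `n_sites x n_points` of 1H and 15N shifts (ppm).
#' @param protein_concentration protein concentration, uM.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(equivalents, sites, H, N,
                             protein_concentration) {
  stopifnot(all(equivalents >= 0), all(diff(equivalents) > 0),
            equivalents[1] == 0,
            nrow(H) == nrow(sites), ncol(H) == length(equivalents),
            all(dim(H) == dim(N)))
  structure(list(equivalents = equivalents, sites = as.data.frame(sites),
                 H = H, N = N,
                 protein_concentration = protein_concentration),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d sites x %d points (eq: %s), P = %g uM\n",
              nrow(x$sites), length(x$equivalents),
              paste(x$equivalents, collapse = ", "),
              x$protein_concentration))
  invisible(x)
}

#' Per-site CSP trajectories across a titration
#'
#' Computes the composite CSP of every site at each titration point
#' against the apo reference, and flags sites whose CSP decreases by more
#' than `noise_floor` between consecutive points: under fast exchange on a
#' 1:1 binding isotherm trajectories are non-decreasing, so a flagged site
#' indicates noise or a more complex process.
#'
#' @param series a [titration_series].
#' @param scale_N nitrogen scale factor for the composite CSP.
#' @param noise_floor allowed CSP decrease between consecutive points, ppm.
#' @return List with `csp` (matrix `n_sites x n_points`), `sites` (with
#'   `site_label`), `equivalents`, and logical `non_monotone` per site.
#' @export
titration_trajectory <- function(series, scale_N = 6.5, noise_floor = 0) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$equivalents) < 2L)
    stop("titration_trajectory: need >= 2 titration points")
  dH <- series$H - series$H[, 1]
  dN <- series$N - series$N[, 1]
  csp <- sqrt(dH^2 + (dN / scale_N)^2)
  colnames(csp) <- paste0("eq", series$equivalents)
  non_mono <- apply(csp, 1L, function(v) any(diff(v) < -noise_floor))
  sites <- series$sites
  sites$site_label <- paste0(sites$residue_index,
                             ifelse(sites$site == "sidechain", "sc", ""))
  list(csp = csp, sites = sites, equivalents = series$equivalents,
       non_monotone = non_mono)
}

#' Bundled random-coil chemical shift reference
#'
#' Neighbor-uncorrected random-coil shifts (ppm) for the 20 standard
#' residues and the atoms N, H, CA, CB, HA, C. The table is a plain TSV
#' under `extdata` and can be swapped for any reference with the same
#' columns.
#'
#' @param path optional path to an alternative table.
#' @return A [shift_table].
#' @export
random_coil_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "random_coil_shifts.tsv",
                                package = "bboxnmr", mustWork = TRUE)
  wide <- utils::read.delim(path, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(setdiff(names(wide), "residue_name"),
    function(at) data.frame(residue_name = wide$residue_name, atom = at,
                            shift = wide[[at]], stringsAsFactors = FALSE)))
  long <- long[is.finite(long$shift), , drop = FALSE]
  ## keyed by residue type: residue_index slot repurposed as a type key
  long$residue_index <- match(long$residue_name,
                              sort(unique(long$residue_name)))
  shift_table(long[c("residue_index", "residue_name", "atom", "shift")])
}

#' Chemical shift index secondary-structure classification
#'
#' Classical CSI logic on secondary shifts (observed minus random coil):
#' CA deviations above +`ca_thr` vote helix and below -`ca_thr` vote
#' strand; CB deviations above +`cb_thr` vote strand (CB is not a helix
#' reporter); HA deviations below -`ha_thr` vote helix and above +`ha_thr`
#' vote strand. A residue's raw index is the majority vote of its
#' available atoms (+1 helix, -1 strand, 0 coil); a secondary-structure
#' element is called only for runs of at least `min_run` consecutive
#' residues with the same non-coil index, everything else is coil.
#'
#' @param shifts observed [shift_table]; CA required per classified
#'   residue, CB/HA optional refinements.
#' @param random_coil random-coil reference, matched by residue type
#'   (default the bundled table, see [random_coil_table()]).
#' @param ca_thr,cb_thr,ha_thr thresholds in ppm.
#' @param min_run minimum consecutive run for a non-coil call.
#' @return Data frame of class `secondary_assignment` with per-residue
#'   atom indices, raw consensus and final `state` in {H, E, C}.
#' @export
csi_classify <- function(shifts, random_coil = random_coil_table(),
                         ca_thr = 0.7, cb_thr = 0.7, ha_thr = 0.1,
                         min_run = 4L) {
  stopifnot(inherits(shifts, "shift_table"))
  rc <- as.data.frame(random_coil)
  rc_key <- paste(rc$residue_name, rc$atom)
  rc_of <- function(resname, atom) rc$shift[match(paste(resname, atom),
                                                  rc_key)]
  df <- as.data.frame(shifts)
  residues <- sort(unique(df$residue_index))
  name_of <- df$residue_name[match(residues, df$residue_index)]
  no_rc <- !(name_of %in% rc$residue_name)
  if (any(no_rc)) {
    warning(sprintf("csi_classify: %d residue(s) missing from the random-coil table, skipped",
                    sum(no_rc)))
    residues <- residues[!no_rc]; name_of <- name_of[!no_rc]
  }
  obs <- function(res, atom) df$shift[match(paste(res, atom),
                                            paste(df$residue_index, df$atom))]
  d_ca <- obs(residues, "CA") - rc_of(name_of, "CA")
  d_cb <- obs(residues, "CB") - rc_of(name_of, "CB")
  d_ha <- obs(residues, "HA") - rc_of(name_of, "HA")

  has_ca <- is.finite(d_ca)
  if (any(!has_ca)) {
    warning(sprintf("csi_classify: %d residue(s) lack a CA shift, skipped",
                    sum(!has_ca)))
    keep <- has_ca
    residues <- residues[keep]; name_of <- name_of[keep]
    d_ca <- d_ca[keep]; d_cb <- d_cb[keep]; d_ha <- d_ha[keep]
  }
  idx3 <- function(d, thr, helix_sign) {
    out <- integer(length(d))
    out[is.finite(d) & d > thr] <- helix_sign
    out[is.finite(d) & d < -thr] <- -helix_sign
    out
  }
  i_ca <- idx3(d_ca, ca_thr, +1L)                 # CA up = helix
  i_cb <- ifelse(is.finite(d_cb) & d_cb > cb_thr, -1L, 0L)  # CB up = strand
  i_ha <- idx3(d_ha, ha_thr, -1L)                 # HA up = strand
  votes <- cbind(i_ca, i_cb, i_ha)
  raw <- apply(votes, 1L, function(v) {
    s <- sum(v)
    if (s > 0) +1L else if (s < 0) -1L else 0L
  })

  ## run-length consensus: >= min_run consecutive identical non-coil raw
  ## indices on consecutive residue numbers
  state <- rep("C", length(residues))
  if (length(residues)) {
    grp <- cumsum(c(TRUE, diff(residues) != 1L | diff(raw) != 0L))
    for (g in unique(grp)) {
      sel <- grp == g
      if (sum(sel) >= min_run && raw[sel][1] != 0L)
        state[sel] <- if (raw[sel][1] > 0L) "H" else "E"
    }
  }
  structure(data.frame(residue_index = residues, residue_name = name_of,
                       idx_CA = i_ca, idx_CB = i_cb, idx_HA = i_ha,
                       raw = raw, state = state, stringsAsFactors = FALSE),
            class = c("secondary_assignment", "data.frame"))
}

#' @export
print.secondary_assignment <- function(x, ...) {
  cat(sprintf("<secondary_assignment> %d residues: %s\n", nrow(x),
              paste(x$state, collapse = "")))
  invisible(x)
}

#' Zinc-coordination score for cysteines from CA/CB shifts
#'
#' Metal-ligated cysteines show characteristic CA/CB chemical shifts
#' (notably an upfield-of-free CB around 28-33 ppm vs ~28 ppm reduced and
#' much larger values oxidized). This scorer places each queried cysteine
#' in (CA, CB) shift space and returns a logistic score of the signed
#' distance to the perpendicular bisector between a "free reduced" and a
#' "metal bound" reference centroid: 0.5 on the bisector, above 0.5 on the
#' metal-bound side, monotone along the centroid axis. The centroids and
#' steepness are configuration with documented defaults; the score is a
#' screening surrogate, not a calibrated posterior probability.
#'
#' @param shifts a [shift_table] with CA and CB shifts.
#' @param residues cysteine residue indices to score.
#' @param free_centroid,bound_centroid named vectors `c(CA=, CB=)` in ppm.
#' @param steepness logistic steepness, 1/ppm.
#' @return Data frame of class `zinc_scores` with `residue_index`, `CA`,
#'   `CB`, `score`. Residues missing a CA or CB shift are omitted with a
#'   warning.
#' @export
zinc_probability <- function(shifts, residues,
                             free_centroid = c(CA = 59.0, CB = 28.0),
                             bound_centroid = c(CA = 58.5, CB = 31.5),
                             steepness = 1.5) {
  stopifnot(inherits(shifts, "shift_table"))
  ca <- get_shift(shifts, residues, "CA")
  cb <- get_shift(shifts, residues, "CB")
  ok <- is.finite(ca) & is.finite(cb)
  if (any(!ok))
    warning(sprintf("zinc_probability: residue(s) %s lack CA or CB shifts, omitted",
                    paste(residues[!ok], collapse = ", ")))
  axis <- bound_centroid[c("CA", "CB")] - free_centroid[c("CA", "CB")]
  u <- axis / sqrt(sum(axis^2))
  mid <- (bound_centroid[c("CA", "CB")] + free_centroid[c("CA", "CB")]) / 2
  t <- (ca[ok] - mid["CA"]) * u["CA"] + (cb[ok] - mid["CB"]) * u["CB"]
  structure(data.frame(residue_index = residues[ok], CA = ca[ok],
                       CB = cb[ok],
                       score = stats::plogis(steepness * t)),
            class = c("zinc_scores", "data.frame"))
}
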