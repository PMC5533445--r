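## Synthetic-data generators: every input class the analysis consumes,
## with known ground truth, so the full chain runs and is testable with
## no external downloads. All generators are pure functions of
## (parameters, seed) and never touch global RNG state.

#' Default relaxation delay grids
#'
#' The delay schedules emulated by the generator: 19 delays spanning
#' 10-646 ms for R1 and 18 delays spanning 6-100 ms for R1rho.
#'
#' @param experiment `"r1"` or `"r1rho"`.
#' @return Numeric vector of delays in seconds.
#' @export
default_delay_grid <- function(experiment = c("r1", "r1rho")) {
  experiment <- match.arg(experiment)
  switch(experiment,
         r1 = seq(0.010, 0.646, length.out = 19L),
         r1rho = seq(0.006, 0.100, length.out = 18L))
}

#' Generate a monoexponential relaxation decay
#'
#' I(t) = I0 exp(-R t) + N(0, noise_sigma^2), reproducible under `seed`.
#'
#' @param R decay rate, s^-1.
#' @param I0 initial intensity.
#' @param delays delay grid in seconds (default the R1 grid).
#' @param noise_sigma Gaussian noise sd (0 = noiseless).
#' @param seed RNG seed.
#' @param residue_index residue label for the series.
#' @return A [relaxation_series] (with `noise_sigma` recorded when > 0).
#' @export
gen_relaxation_series <- function(R, I0, delays = default_delay_grid("r1"),
                                  noise_sigma = 0, seed = 1L,
                                  residue_index = 1L) {
  stopifnot(length(delays) >= 1L)
  y <- I0 * exp(-R * delays)
  if (noise_sigma > 0)
    y <- y + with_seed(seed, stats::rnorm(length(delays), 0, noise_sigma))
  relaxation_series(residue_index, delays, y,
                    noise_sigma = if (noise_sigma > 0) noise_sigma else NULL)
}

#' 1:1 binding model for fast-exchange titrations
#'
#' @param kd dissociation constant, uM.
#' @param protein_concentration protein concentration, uM.
#' @param equivalents titrant schedule in equivalents of protein; must
#'   start at 0 (apo).
#' @return Object of class `binding_model`.
#' @export
binding_model <- function(kd, protein_concentration,
                          equivalents = c(0, 0.25, 0.5, 1.0, 2.0)) {
  stopifnot(kd > 0, protein_concentration > 0, equivalents[1] == 0)
  structure(list(kd = kd, protein_concentration = protein_concentration,
                 equivalents = equivalents), class = "binding_model")
}

#' Bound fraction of a 1:1 complex
#'
#' Exact solution of the binding quadratic:
#' f = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P).
#'
#' @param P,L,kd protein and total ligand concentrations and Kd, same
#'   units.
#' @return Bound protein fraction in [0, 1].
#' @export
bound_fraction <- function(P, L, kd) {
  s <- P + L + kd
  pmax(pmin((s - sqrt(s^2 - 4 * P * L)) / (2 * P), 1), 0)
}

#' Generate a fast-exchange titration series
#'
#' Observed shifts are population-weighted: delta_obs = delta_free +
#' f * delta_max per site, with the bound fraction from the exact 1:1
#' quadratic at each titration point. Optional Gaussian shift noise.
#'
#' @param model a [binding_model].
#' @param shifting_sites data frame with columns `residue_index`, `site`,
#'   `H0`, `N0` (apo shifts, ppm), `dH_max`, `dN_max` (saturated shift
#'   changes, ppm).
#' @param shift_noise Gaussian sd added to every shift (ppm, default 0).
#' @param seed RNG seed.
#' @return A [titration_series].
#' @export
gen_titration <- function(model, shifting_sites, shift_noise = 0,
                          seed = 1L) {
  stopifnot(inherits(model, "binding_model"))
  need <- c("residue_index", "site", "H0", "N0", "dH_max", "dN_max")
  stopifnot(all(need %in% names(shifting_sites)))
  s <- as.data.frame(shifting_sites)
  P <- model$protein_concentration
  L <- model$equivalents * P
  f <- bound_fraction(P, L, model$kd)
  H <- outer(s$H0, rep(1, length(f))) + outer(s$dH_max, f)
  N <- outer(s$N0, rep(1, length(f))) + outer(s$dN_max, f)
  if (shift_noise > 0) {
    noise <- with_seed(seed, list(
      H = matrix(stats::rnorm(length(H), 0, shift_noise), nrow(H)),
      N = matrix(stats::rnorm(length(N), 0, shift_noise), nrow(N))))
    H <- H + noise$H; N <- N + noise$N
  }
  titration_series(model$equivalents, s[c("residue_index", "site")],
                   H, N, protein_concentration = P)
}

#' Ensemble recipe for the synthetic structure generator
#'
#' @param topology `"helix"`, `"hairpin"` or `"helix+tail"`.
#' @param length number of residues.
#' @param core_sigma per-coordinate Gaussian jitter of core residues, A.
#' @param tail_sigma jitter of tail residues (helix+tail topology), A.
#' @param n_models number of models.
#' @param seed RNG seed.
#' @param first_residue numbering of the first residue.
#' @return Object of class `ensemble_recipe`.
#' @export
ensemble_recipe <- function(topology = "helix", length = 16L,
                            core_sigma = 0, tail_sigma = core_sigma,
                            n_models = 10L, seed = 1L,
                            first_residue = 1L) {
  stopifnot(core_sigma >= 0, tail_sigma >= 0, n_models >= 1L,
            length >= 4L)
  structure(list(topology = topology, length = as.integer(length),
                 core_sigma = core_sigma, tail_sigma = tail_sigma,
                 n_models = as.integer(n_models), seed = as.integer(seed),
                 first_residue = as.integer(first_residue)),
            class = "ensemble_recipe")
}

#' Generate a synthetic multi-model ensemble
#'
#' Builds an idealized backbone (+CB) for the recipe's topology and emits
#' `n_models` copies with independent per-atom Gaussian coordinate jitter:
#' `core_sigma` on core residues and `tail_sigma` on the planted flexible
#' tail (helix+tail topology). Deterministic under the recipe seed.
#'
#' @param recipe an [ensemble_recipe].
#' @return A [structure_ensemble] with attributes `core_residues` and
#'   `tail_residues`.
#' @export
gen_ensemble <- function(recipe) {
  stopifnot(inherits(recipe, "ensemble_recipe"))
  td <- topology_dihedrals(recipe$topology, recipe$length)
  bb <- build_backbone(td$phi, td$psi, first_residue = recipe$first_residue)
  core_res <- recipe$first_residue + td$core - 1L
  all_res <- recipe$first_residue + seq_len(recipe$length) - 1L
  tail_res <- setdiff(all_res, core_res)
  sigma_of_atom <- ifelse(bb$atoms$residue_index %in% core_res,
                          recipe$core_sigma, recipe$tail_sigma)
  n_at <- nrow(bb$xyz)
  xyz <- array(NA_real_, c(n_at, 3L, recipe$n_models))
  jitter <- with_seed(recipe$seed,
    array(stats::rnorm(n_at * 3L * recipe$n_models),
          c(n_at, 3L, recipe$n_models)))
  for (k in seq_len(recipe$n_models))
    xyz[, , k] <- bb$xyz + jitter[, , k] * sigma_of_atom
  out <- structure_ensemble(bb$atoms, xyz,
                            source = sprintf("synthetic %s", recipe$topology))
  attr(out, "core_residues") <- core_res
  attr(out, "tail_residues") <- tail_res
  out
}

#' Derive NOE-style restraints from a structure
#'
#' For every inter-residue heavy-atom pair within `contact_cutoff` in
#' model 1, emits an NOE-kind restraint with upper bound = observed
#' distance + `slack` (lower bound 0). By construction the generating
#' model satisfies every restraint.
#'
#' @param ensemble a [structure_ensemble].
#' @param contact_cutoff contact distance in Angstrom (default 5.0).
#' @param slack added to each observed distance (default 0.2 A).
#' @return A [restraint_list] of kind "NOE".
#' @export
gen_restraints_from_structure <- function(ensemble, contact_cutoff = 5.0,
                                          slack = 0.2) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  a <- ensemble$atoms
  heavy <- which(toupper(a$element) != "H")
  xyz <- matrix(ensemble$xyz[heavy, , 1], ncol = 3L)
  d <- as.matrix(stats::dist(xyz))
  rows <- list()
  for (i in seq_along(heavy)) {
    for (j in seq_along(heavy)) {
      if (j <= i) next
      ri <- a$residue_index[heavy[i]]; rj <- a$residue_index[heavy[j]]
      if (ri == rj) next
      if (d[i, j] > contact_cutoff) next
      rows[[length(rows) + 1L]] <- data.frame(
        res_i = ri, name_i = a$residue_name[heavy[i]],
        atom_i = a$atom[heavy[i]],
        res_j = rj, name_j = a$residue_name[heavy[j]],
        atom_j = a$atom[heavy[j]],
        lower = 0, upper = d[i, j] + slack, kind = "NOE",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  r <- sort_restraints(restraint_list(out))
  rownames(r) <- NULL
  restraint_list(r)
}
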