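## Configuration-driven orchestration of the analysis stages into one
## reproducible run with a machine-readable report.

default_cutoffs <- function() {
  list(csp = 0.10, violation = 0.5, sasa = 0.15, patch = 8.0, rmsf = 1.0)
}

#' Build a pipeline configuration
#'
#' A configuration is a named list (or a YAML file with the same shape)
#' with a `stages` block naming the stages to run and their inputs, plus
#' global `cutoffs`, `seed` and `out_dir`. Defaults are materialized into
#' the effective configuration so that its hash pins the whole analysis.
#'
#' Stages and their inputs:
#' \describe{
#'   \item{relaxation}{`series_tsv` (columns residue_index, delay,
#'     intensity, experiment in r1/r1rho), `field_mhz`, `b1_hz`,
#'     `carrier_ppm`, optional `shifts_tsv` for per-residue 15N offsets
#'     and `selection` residues for the correlation-time estimate.}
#'   \item{csp}{`apo` and `bound` Sparky peak lists.}
#'   \item{csi}{`shifts` TSV shift table.}
#'   \item{zinc_scores}{`shifts` TSV shift table, `residues` (Cys).}
#'   \item{restraints}{`file` (.upl), optional `pdb` for violations.}
#'   \item{ensemble}{`pdb`, optional `residues` range, `atoms`
#'     (backbone/heavy), optional `csp_sites` residues for patch
#'     clustering.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return Object of class `pipeline_config` (the effective config).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  eff <- list(
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir %||% NULL,
    strict = isTRUE(config$strict),
    cutoffs = utils::modifyList(default_cutoffs(),
                                config$cutoffs %||% list()),
    stages = config$stages %||% list()
  )
  if (!length(eff$stages))
    stop("pipeline_config: at least one stage must be configured")
  cl <- eff$cutoffs
  if (cl$csp < 0 || cl$violation < 0 || cl$sasa < 0 || cl$sasa > 1 ||
      cl$patch <= 0 || cl$rmsf <= 0)
    stop("pipeline_config: cutoff outside its documented range")
  structure(eff, class = "pipeline_config")
}

## Every file referenced by a stage, for fail-fast validation.
config_input_files <- function(cfg) {
  s <- cfg$stages
  unlist(c(s$relaxation$series_tsv, s$relaxation$shifts_tsv,
           s$csp$apo, s$csp$bound, s$csi$shifts, s$zinc_scores$shifts,
           s$restraints$file, s$restraints$pdb, s$ensemble$pdb),
         use.names = FALSE)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  eff <- unclass(cfg)
  eff$out_dir <- NULL  # where results land does not change what they are
  yaml::write_yaml(eff, tf)
  unname(tools::md5sum(tf))
}

pipe_log <- function(verbose, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

#' Run the configured analysis pipeline
#'
#' Validates the configuration (all referenced input files must exist
#' before any stage runs), executes the enabled stages in dependency
#' order, and assembles a report with one section per executed stage plus
#' a provenance block (hash of the effective configuration, seed, package
#' version). A failing stage is recorded and does not abort the others
#' unless `strict` is set in the configuration.
#'
#' @param config a [pipeline_config], a named list, or a YAML path.
#' @param verbose log stage progress to stderr.
#' @return Object of class `analysis_report`. Attribute `failed_stages`
#'   names stages that errored.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  missing <- Filter(function(f) !file.exists(f), config_input_files(cfg))
  if (length(missing))
    stop("run_pipeline: missing input file(s): ",
         paste(missing, collapse = ", "))

  sections <- list()
  failed <- character()
  run_stage <- function(name, fun) {
    pipe_log(verbose, "stage %s: start", name)
    res <- tryCatch(fun(), error = function(e) {
      if (cfg$strict)
        stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      failed <<- c(failed, name)
      message(sprintf("stage %s failed: %s", name, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) sections[[name]] <<- res
    pipe_log(verbose, "stage %s: done", name)
  }
  st <- cfg$stages

  if (!is.null(st$relaxation))
    run_stage("relaxation", function()
      stage_relaxation(st$relaxation, cfg))
  if (!is.null(st$csp))
    run_stage("csp", function() stage_csp(st$csp, cfg))
  if (!is.null(st$csi))
    run_stage("csi", function() stage_csi(st$csi))
  if (!is.null(st$zinc_scores))
    run_stage("zinc_scores", function() stage_zinc(st$zinc_scores))
  if (!is.null(st$restraints))
    run_stage("restraints", function() stage_restraints(st$restraints, cfg))
  if (!is.null(st$ensemble))
    run_stage("ensemble", function()
      stage_ensemble(st$ensemble, cfg, sections))

  report <- structure(list(
    sections = sections,
    provenance = list(config_hash = config_hash(cfg), seed = cfg$seed,
                      package = "bboxnmr",
                      version = as.character(utils::packageVersion("bboxnmr")))),
    class = "analysis_report", failed_stages = failed)
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

stage_relaxation <- function(s, cfg) {
  tab <- utils::read.delim(s$series_tsv, stringsAsFactors = FALSE)
  need <- c("residue_index", "delay", "intensity", "experiment")
  stopifnot(all(need %in% names(tab)))
  settings <- spinlock_settings(
    b1 = s$b1_hz %||% 1761,
    carrier = s$carrier_ppm %||% 118.98,
    nitrogen_frequency = (s$field_mhz %||% 600) * abs(.gamma_N) / .gamma_H)
  shifts <- if (!is.null(s$shifts_tsv))
    read_shift_table(s$shifts_tsv, "tsv") else NULL
  fit_exp <- function(exp_name) {
    sub <- tab[tab$experiment == exp_name, , drop = FALSE]
    lapply(split(sub, sub$residue_index), function(d)
      fit_monoexponential(relaxation_series(d$residue_index[1], d$delay,
                                            d$intensity),
                          seed = cfg$seed))
  }
  r1 <- fit_exp("r1")
  r1rho <- fit_exp("r1rho")
  r2 <- lapply(names(r1rho), function(res) {
    if (!res %in% names(r1)) return(NULL)
    shift_N <- if (!is.null(shifts))
      get_shift(shifts, as.integer(res), "N") else settings$carrier
    if (!is.finite(shift_N)) shift_N <- settings$carrier
    r2_from_r1rho(r1[[res]], r1rho[[res]], shift_N, settings)
  })
  r2 <- Filter(Negate(is.null), r2)
  tauc <- estimate_tauc(r1, r2, field_1H = s$field_mhz %||% 600,
                        selection = s$selection)
  rate_row <- function(x) data.frame(residue_index = x$residue_index,
                                     R = x$R, rate_error = x$rate_error)
  list(r1 = do.call(rbind, lapply(r1, rate_row)),
       r2 = do.call(rbind, lapply(r2, rate_row)),
       tau_c_ns = tauc$tau_c, n_residues_used = tauc$n_residues_used)
}

stage_csp <- function(s, cfg) {
  apo <- read_peak_list(s$apo)
  bound <- read_peak_list(s$bound)
  rec <- compute_csp(apo, bound)
  sig <- select_significant(rec, cfg$cutoffs$csp)
  list(csp = as.data.frame(rec), significant = sig,
       cutoff = cfg$cutoffs$csp)
}

stage_csi <- function(s) {
  shifts <- read_shift_table(s$shifts, "tsv")
  as.data.frame(csi_classify(shifts))
}

stage_zinc <- function(s) {
  shifts <- read_shift_table(s$shifts, "tsv")
  as.data.frame(zinc_probability(shifts, as.integer(s$residues)))
}

stage_restraints <- function(s, cfg) {
  r <- read_restraints(s$file, "cyana_upl")
  counts <- classify_noe(r)
  out <- list(counts = unclass(counts))
  if (!is.null(s$pdb)) {
    ens <- read_ensemble(s$pdb)
    v <- check_violations(r, ens, threshold = cfg$cutoffs$violation)
    out$violations <- list(count = v$count, threshold = v$threshold,
                           n_skipped = v$n_skipped)
  }
  out
}

stage_ensemble <- function(s, cfg, sections) {
  ens <- read_ensemble(s$pdb)
  residues <- if (!is.null(s$residues)) as.integer(s$residues) else NULL
  out <- list(n_models = n_models(ens))
  bb <- average_pairwise_rmsd(ens, residues, "backbone")
  hv <- average_pairwise_rmsd(ens, residues, "heavy")
  out$rmsd <- list(backbone_mean = bb$mean, backbone_sd = bb$sd,
                   heavy_mean = hv$mean, heavy_sd = hv$sd)
  if (n_models(ens) >= 2L) {
    ord <- ordered_residues(ens, cfg$cutoffs$rmsf)
    out$ordered_residues <- ord$residues
  }
  prof <- element_frequency(ens)
  out$secondary_structure <- unname(paste(prof$consensus, collapse = ""))
  acc <- accessibility(ens, threshold = cfg$cutoffs$sasa)
  out$buried_residues <- acc$residue_index[acc$buried]
  sig_sites <- s$csp_sites %||%
    (if (!is.null(sections$csp)) sections$csp$significant$residue_index
     else NULL)
  if (!is.null(sig_sites) && length(sig_sites)) {
    patches <- cluster_patches(ens, as.integer(sig_sites),
                               cfg$cutoffs$patch)
    out$patches <- lapply(unclass(patches), function(p)
      list(members = p$members))
  }
  out
}

#' Write an analysis report
#'
#' Serializes the report as `report.json` (machine-readable, reloadable
#' via [read_report()]) plus one TSV per tabular section, side by side in
#' `out_dir`. Serialization contains no timestamps, so identical runs
#' produce byte-identical reports.
#'
#' @param report an `analysis_report`.
#' @param out_dir output directory (created if needed).
#' @return Path of the JSON report, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  for (nm in names(report$sections)) {
    sec <- report$sections[[nm]]
    if (is.data.frame(sec))
      utils::write.table(sec, file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Reload a serialized analysis report
#'
#' @param path path to a `report.json` written by [write_report()].
#' @return The report as an `analysis_report`.
#' @export
read_report <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> sections: %s\n",
              paste(names(x$sections), collapse = ", ")))
  cat(sprintf("  config %s, seed %d, %s %s\n",
              substr(x$provenance$config_hash, 1, 8), x$provenance$seed,
              x$provenance$package, x$provenance$version))
  invisible(x)
}

#' Simulate a complete demo input set
#'
#' Writes synthetic inputs for every stage into `dir` (relaxation series
#' TSV, apo/bound peak lists, shift table, restraint file, multi-model
#' PDB) and returns a ready-to-run configuration using them. All content
#' is deterministic under `seed`.
#'
#' @param dir directory for the generated files.
#' @param seed RNG seed.
#' @return A [pipeline_config].
#' @export
demo_config <- function(dir = tempfile("bboxnmr_demo"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  ## relaxation: 12 rigid residues at tau_c = 3.4 ns, 600 MHz
  rates <- predict_rates(motion_model(3.4, 600))
  rows <- list()
  for (res in 1:12) {
    for (exp_name in c("r1", "r1rho")) {
      R <- if (exp_name == "r1") rates["R1"] else rates["R2"]
      ser <- gen_relaxation_series(R, I0 = 100,
                                   delays = default_delay_grid(exp_name),
                                   noise_sigma = 1, seed = seed + res,
                                   residue_index = res)
      rows[[length(rows) + 1L]] <- data.frame(
        residue_index = res, delay = ser$delays,
        intensity = ser$intensities, experiment = exp_name)
    }
  }
  relax_tsv <- file.path(dir, "relaxation_series.tsv")
  utils::write.table(do.call(rbind, rows), relax_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## titration endpoints as apo/bound peak lists
  sites <- data.frame(residue_index = 1:12, site = "backbone",
                      H0 = 8 + (1:12) / 20, N0 = 110 + (1:12),
                      dH_max = c(rep(0, 8), 0.12, 0.15, 0.18, 0.11),
                      dN_max = c(rep(0, 8), 0.9, 1.1, 1.3, 0.8))
  tit <- gen_titration(binding_model(1, 200), sites, seed = seed)
  pk <- function(col) peak_list(data.frame(
    residue_index = sites$residue_index, residue_name = "ALA",
    site = sites$site, atom1 = "N", atom2 = "H",
    w1 = tit$N[, col], w2 = tit$H[, col], intensity = 1e6))
  apo_path <- file.path(dir, "apo.list")
  bound_path <- file.path(dir, "bound.list")
  write_peak_list(pk(1L), apo_path)
  write_peak_list(pk(ncol(tit$H)), bound_path)

  ## shift table with a helix signature on residues 4-9
  rc <- random_coil_table()
  ala <- function(atom) rc$shift[rc$residue_name == "ALA" &
                                   rc$atom == atom]
  sh <- do.call(rbind, lapply(1:12, function(r) data.frame(
    residue_index = r, residue_name = "ALA",
    atom = c("CA", "CB", "HA", "N"),
    shift = c(ala("CA") + if (r %in% 4:9) 3 else 0, ala("CB"),
              ala("HA") + if (r %in% 4:9) -0.3 else 0, ala("N")))))
  shifts_tsv <- file.path(dir, "shifts.tsv")
  utils::write.table(sh, shifts_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## ensemble + restraints derived from it
  ens <- gen_ensemble(ensemble_recipe("helix", 14L, core_sigma = 0.15,
                                      n_models = 5L, seed = seed))
  pdb_path <- file.path(dir, "ensemble.pdb")
  write_ensemble(ens, pdb_path)
  ## generous slack: the demo checks these bounds against every jittered
  ## model, not just the generating one
  restr <- gen_restraints_from_structure(ens, slack = 1.2)
  upl_path <- file.path(dir, "restraints.upl")
  write_restraints(restr, upl_path)

  pipeline_config(list(
    seed = seed,
    stages = list(
      relaxation = list(series_tsv = relax_tsv, field_mhz = 600,
                        b1_hz = 1761, carrier_ppm = 118.98),
      csp = list(apo = apo_path, bound = bound_path),
      csi = list(shifts = shifts_tsv),
      restraints = list(file = upl_path, pdb = pdb_path),
      ensemble = list(pdb = pdb_path))))
}
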