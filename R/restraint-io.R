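#' Distance restraint lists
#'
#' A restraint list holds atom-pair distance bounds: NOE upper limits,
#' zinc-site geometry restraints, or other bounds. Each row addresses two
#' atoms by residue index and atom name and carries a lower bound (0 for
#' plain upper-limit restraints) and an upper bound in Angstrom.
#'
#' @param restraints data frame with columns `res_i`, `name_i`, `atom_i`,
#'   `res_j`, `name_j`, `atom_j`, `lower`, `upper`, `kind` (one of "NOE",
#'   "zinc", "other").
#' @return Object of class `restraint_list` (a data frame).
#' @export
restraint_list <- function(restraints = NULL) {
  if (is.null(restraints)) {
    restraints <- data.frame(
      res_i = integer(), name_i = character(), atom_i = character(),
      res_j = integer(), name_j = character(), atom_j = character(),
      lower = numeric(), upper = numeric(), kind = character(),
      stringsAsFactors = FALSE)
  }
  need <- c("res_i", "name_i", "atom_i", "res_j", "name_j", "atom_j",
            "lower", "upper", "kind")
  if (!all(need %in% names(restraints)))
    stop("restraint_list missing columns: ",
         paste(setdiff(need, names(restraints)), collapse = ", "))
  restraints <- as.data.frame(restraints)[need]
  if (nrow(restraints)) {
    if (any(restraints$upper <= 0))
      stop("restraint_list: upper bounds must be > 0")
    if (any(restraints$lower > restraints$upper))
      stop("restraint_list: lower bound exceeds upper bound")
    same <- restraints$res_i == restraints$res_j &
      restraints$atom_i == restraints$atom_j
    if (any(same))
      stop("restraint_list: restraint between an atom and itself")
    if (!all(restraints$kind %in% c("NOE", "zinc", "other")))
      stop("restraint_list: kind must be NOE, zinc or other")
  }
  structure(restraints, class = c("restraint_list", "data.frame"))
}

#' @export
print.restraint_list <- function(x, ...) {
  kinds <- table(x$kind)
  cat(sprintf("<restraint_list> %d restraints (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(kinds), kinds),
                    collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

sort_restraints <- function(r) {
  r[order(r$res_i, r$atom_i, r$res_j, r$atom_j), , drop = FALSE]
}

#' Read a distance restraint file
#'
#' `"cyana_upl"` parses CYANA upper-limit files: one restraint per line,
#' `res_i name_i atom_i res_j name_j atom_j upper`, comments starting with
#' `#`. Lower bounds are 0. `"nmrstar_min"` parses the minimal NMR-STAR
#' general-distance-constraint loop (tags `Seq_ID_1`, `Comp_ID_1`,
#' `Atom_ID_1`, same for 2, and `Distance_upper_bound_val`, optional
#' `Distance_lower_bound_val`).
#'
#' @param path input file.
#' @param dialect `"cyana_upl"` or `"nmrstar_min"`.
#' @param kind restraint kind to assign ("NOE", "zinc" or "other"); the
#'   file formats do not encode it.
#' @return A [restraint_list].
#' @export
read_restraints <- function(path, dialect = c("cyana_upl", "nmrstar_min"),
                            kind = "NOE") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "cyana_upl") {
    lines <- readLines(path, warn = FALSE)
    rows <- list()
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || startsWith(ln, "#")) next
      f <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(f) < 7L)
        stop_parse(path, i, sprintf("expected 7 fields, got %d", length(f)))
      ri <- suppressWarnings(as.integer(f[1]))
      rj <- suppressWarnings(as.integer(f[4]))
      ub <- suppressWarnings(as.numeric(f[7]))
      if (is.na(ri) || is.na(rj))
        stop_parse(path, i, "non-numeric residue index")
      if (is.na(ub)) stop_parse(path, i, "non-numeric distance bound")
      rows[[length(rows) + 1L]] <- data.frame(
        res_i = ri, name_i = toupper(f[2]), atom_i = toupper(f[3]),
        res_j = rj, name_j = toupper(f[5]), atom_j = toupper(f[6]),
        lower = 0, upper = ub, kind = kind, stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else NULL
    return(restraint_list(df))
  }
  ## nmrstar_min
  lines <- readLines(path, warn = FALSE)
  loop <- star_loop(lines, c("Seq_ID_1", "Comp_ID_1", "Atom_ID_1",
                             "Seq_ID_2", "Comp_ID_2", "Atom_ID_2",
                             "Distance_upper_bound_val"))
  if (is.null(loop)) return(restraint_list())
  lower <- if ("Distance_lower_bound_val" %in% names(loop)) {
    lo <- suppressWarnings(as.numeric(loop$Distance_lower_bound_val))
    ifelse(is.na(lo), 0, lo)
  } else 0
  restraint_list(data.frame(
    res_i = as.integer(loop$Seq_ID_1), name_i = toupper(loop$Comp_ID_1),
    atom_i = toupper(loop$Atom_ID_1),
    res_j = as.integer(loop$Seq_ID_2), name_j = toupper(loop$Comp_ID_2),
    atom_j = toupper(loop$Atom_ID_2),
    lower = lower,
    upper = as.numeric(loop$Distance_upper_bound_val),
    kind = kind, stringsAsFactors = FALSE))
}

#' Write restraints in CYANA upper-limit format
#'
#' Restraints are emitted in a canonical order (by `res_i`, `atom_i`,
#' `res_j`, `atom_j`) with two-decimal bounds, so output is deterministic
#' and round-trips through [read_restraints()] bit-exactly (upper-limit
#' files carry no lower bounds or kinds).
#'
#' @param restraints a [restraint_list].
#' @param path output path; `NULL` returns the text instead of writing.
#' @param dialect only `"cyana_upl"`.
#' @return The formatted text (invisibly when `path` is given).
#' @export
write_restraints <- function(restraints, path = NULL,
                             dialect = "cyana_upl") {
  dialect <- match.arg(dialect, "cyana_upl")
  stopifnot(inherits(restraints, "restraint_list"))
  r <- sort_restraints(restraints)
  txt <- if (nrow(r)) {
    sprintf("%4d %-4s %-4s %4d %-4s %-4s %8.2f",
            r$res_i, r$name_i, r$atom_i, r$res_j, r$name_j, r$atom_j,
            r$upper)
  } else character()
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
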