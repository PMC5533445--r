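#' Peak lists
#'
#' A peak list holds one row per cross peak of a 2D correlation spectrum:
#' the assignment (residue index, residue type, the two correlated atoms),
#' the two peak positions in ppm, and the peak intensity in arbitrary
#' units. Side-chain amide peaks (e.g. the Trp indole NE1-HE1) are tracked
#' as separate sites so that titration analysis can report them alongside
#' backbone amides.
#'
#' @param entries data frame with columns `residue_index`, `residue_name`,
#'   `site` ("backbone" or "sidechain"), `atom1`, `atom2`, `w1`, `w2`,
#'   `intensity`.
#' @param source_label free-text provenance label.
#' @return An object of class `peak_list` (a data frame).
#' @export
peak_list <- function(entries = NULL, source_label = "") {
  if (is.null(entries)) {
    entries <- data.frame(
      residue_index = integer(), residue_name = character(),
      site = character(), atom1 = character(), atom2 = character(),
      w1 = numeric(), w2 = numeric(), intensity = numeric(),
      stringsAsFactors = FALSE)
  }
  need <- c("residue_index", "residue_name", "site", "atom1", "atom2",
            "w1", "w2", "intensity")
  if (!all(need %in% names(entries)))
    stop("peak_list entries missing columns: ",
         paste(setdiff(need, names(entries)), collapse = ", "))
  entries <- as.data.frame(entries)[need]
  if (nrow(entries)) {
    if (any(entries$residue_index < 1L))
      stop("peak_list: residue_index must be >= 1")
    if (!all(is.finite(entries$w1)) || !all(is.finite(entries$w2)))
      stop("peak_list: peak positions must be finite")
    if (!all(is.finite(entries$intensity)))
      stop("peak_list: intensities must be finite")
  }
  structure(entries, class = c("peak_list", "data.frame"),
            source_label = source_label)
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks", nrow(x)))
  lab <- attr(x, "source_label")
  if (nzchar(lab)) cat(sprintf(" [%s]", lab))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

## Sparky assignment grammar: one-letter residue code, residue number,
## optional side-chain marker "sc", then two atom tokens joined by "-",
## e.g. "G96N-H" or "W112scNE1-HE1". Returns a one-row data frame or NULL.
parse_sparky_assignment <- function(tok) {
  m <- regmatches(tok,
    regexec("^([A-Za-z?])([0-9]+)(sc)?([A-Z][A-Z0-9']*)-([A-Z][A-Z0-9']*)$",
            tok))[[1]]
  if (!length(m)) return(NULL)
  one <- toupper(m[2])
  data.frame(
    residue_index = as.integer(m[3]),
    residue_name = if (one %in% names(aa_three_from_one))
      unname(aa_three_from_one[one]) else "?",
    site = if (identical(m[4], "sc")) "sidechain" else "backbone",
    atom1 = m[5], atom2 = m[6], stringsAsFactors = FALSE)
}

#' Read a Sparky-style peak list
#'
#' Parses text peak lists of the form exported by Sparky: an optional
#' header line starting with "Assignment", then one line per peak with the
#' assignment string, two positions (ppm) and an intensity. Comment lines
#' start with `#`.
#'
#' @param path path to the peak-list file.
#' @param dialect only `"sparky"` is supported.
#' @return A [peak_list].
#' @examples
#' f <- tempfile()
#' writeLines(c("Assignment w1 w2 Height", "G96N-H 104.21 8.35 1.2e6"), f)
#' read_peak_list(f)
#' @export
read_peak_list <- function(path, dialect = "sparky") {
  dialect <- match.arg(dialect, "sparky")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (identical(tolower(f[1]), "assignment")) next  # Sparky header
    asg <- parse_sparky_assignment(f[1])
    if (is.null(asg))
      stop_parse(path, i, sprintf("malformed assignment '%s'", f[1]))
    if (length(f) < 4L)
      stop_parse(path, i, sprintf("expected 4 columns, got %d", length(f)))
    vals <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(vals)))
      stop_parse(path, i, "non-numeric position or intensity column")
    asg$w1 <- vals[1]; asg$w2 <- vals[2]; asg$intensity <- vals[3]
    rows[[i]] <- asg
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  entries <- if (length(rows)) do.call(rbind, rows) else NULL
  peak_list(entries, source_label = basename(path))
}

#' Write a peak list in Sparky text form
#'
#' @param peaks a [peak_list].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_list"))
  one_from_three <- stats::setNames(names(aa_three_from_one),
                                    aa_three_from_one)
  hdr <- sprintf("%-18s %9s %9s %12s", "Assignment", "w1", "w2", "Height")
  lines <- hdr
  if (nrow(peaks)) {
    one <- one_from_three[peaks$residue_name]
    one[is.na(one)] <- "?"
    asg <- sprintf("%s%d%s%s-%s", one, peaks$residue_index,
                   ifelse(peaks$site == "sidechain", "sc", ""),
                   peaks$atom1, peaks$atom2)
    lines <- c(lines, sprintf("%-18s %9.3f %9.3f %12.5g",
                              asg, peaks$w1, peaks$w2, peaks$intensity))
  }
  writeLines(lines, path)
  invisible(path)
}
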