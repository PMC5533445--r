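#' Chemical shift tables
#'
#' A shift table stores assigned chemical shifts, one row per
#' (residue, atom) pair, for the backbone atoms used by shift-based
#' inference: amide N and H, CA, CB, HA and the carbonyl C.
#'
#' @param records data frame with columns `residue_index`, `residue_name`,
#'   `atom`, `shift`.
#' @return An object of class `shift_table` (a data frame).
#' @export
shift_table <- function(records = NULL) {
  if (is.null(records)) {
    records <- data.frame(residue_index = integer(),
                          residue_name = character(),
                          atom = character(), shift = numeric(),
                          stringsAsFactors = FALSE)
  }
  need <- c("residue_index", "residue_name", "atom", "shift")
  if (!all(need %in% names(records)))
    stop("shift_table records missing columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  records <- as.data.frame(records)[need]
  if (nrow(records)) {
    key <- paste(records$residue_index, records$atom)
    if (anyDuplicated(key))
      stop("shift_table: duplicate (residue, atom) record(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    if (!all(is.finite(records$shift)))
      stop("shift_table: shifts must be finite")
  }
  structure(records, class = c("shift_table", "data.frame"))
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("<shift_table> %d records, %d residues\n",
              nrow(x), length(unique(x$residue_index))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

shift_atoms <- c("N", "H", "CA", "CB", "HA", "C")

## Canonicalize common synonyms for the atoms this package analyses.
canonical_shift_atom <- function(atom) {
  a <- toupper(atom)
  a[a %in% c("C'", "CO")] <- "C"
  a[a == "HN"] <- "H"
  a
}

#' Look up a shift by residue and atom
#'
#' @param table a [shift_table].
#' @param residue_index residue number(s).
#' @param atom atom name (canonical: N, H, CA, CB, HA, C).
#' @return Numeric vector of shifts (ppm), `NA` where absent.
#' @export
get_shift <- function(table, residue_index, atom) {
  stopifnot(inherits(table, "shift_table"))
  key <- paste(table$residue_index, table$atom)
  want <- paste(residue_index, canonical_shift_atom(atom))
  table$shift[match(want, key)]
}

#' Read a chemical shift table
#'
#' Two dialects are supported. `"tsv"` expects a header naming (at least)
#' the columns `residue_index`, `residue_name`, `atom`, `shift`.
#' `"nmrstar_min"` parses the minimal NMR-STAR subset used for deposited
#' assigned shifts: a `loop_` whose tags include `Comp_index_ID` (or
#' `Seq_ID`), `Comp_ID`, `Atom_ID` and `Val`.
#'
#' Rows whose atom is outside the supported set (N, H/HN, CA, CB, HA,
#' C/C'/CO) are skipped; the number skipped is attached as attribute
#' `n_skipped` and reported via a warning. Duplicate (residue, atom) rows
#' are an integrity error.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"nmrstar_min"`.
#' @return A [shift_table] with attribute `n_skipped`.
#' @export
read_shift_table <- function(path, dialect = c("tsv", "nmrstar_min")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(dialect,
                tsv = read_shift_tsv(path),
                nmrstar_min = read_shift_star(path))
  raw$atom <- canonical_shift_atom(raw$atom)
  keep <- raw$atom %in% shift_atoms
  n_skipped <- sum(!keep)
  if (n_skipped)
    warning(sprintf("%s: skipped %d record(s) with unsupported atom names",
                    basename(path), n_skipped))
  out <- shift_table(raw[keep, , drop = FALSE])
  attr(out, "n_skipped") <- n_skipped
  out
}

read_shift_tsv <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first)) & !startsWith(trimws(first), "#")]
  if (!length(first))
    return(data.frame(residue_index = integer(), residue_name = character(),
                      atom = character(), shift = numeric(),
                      stringsAsFactors = FALSE))
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("residue_index", "residue_name", "atom", "shift")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: TSV shift table must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$shift))))
  if (length(bad))
    stop_parse(path, bad[1] + 1L, "non-numeric shift value")
  df$residue_index <- as.integer(df$residue_index)
  df$shift <- as.numeric(df$shift)
  df[c("residue_index", "residue_name", "atom", "shift")]
}

## Minimal NMR-STAR loop reader: returns rows of the first loop whose tag
## set contains all of `want` (matched on the part after the final dot).
star_loop <- function(lines, want) {
  lines <- trimws(lines)
  i <- 1L
  while (i <= length(lines)) {
    if (identical(lines[i], "loop_")) {
      tags <- character()
      j <- i + 1L
      while (j <= length(lines) && startsWith(lines[j], "_")) {
        tags <- c(tags, sub(".*\\.", "", lines[j]))
        j <- j + 1L
      }
      rows <- list()
      while (j <= length(lines) && !identical(lines[j], "stop_")) {
        if (nzchar(lines[j]) && !startsWith(lines[j], "#"))
          rows[[length(rows) + 1L]] <- strsplit(lines[j], "[[:space:]]+")[[1]]
        j <- j + 1L
      }
      if (all(want %in% tags)) {
        ok <- vapply(rows, length, integer(1)) == length(tags)
        if (!all(ok)) stop("NMR-STAR loop row/tag count mismatch",
                           call. = FALSE)
        mat <- do.call(rbind, rows)
        colnames(mat) <- tags
        return(as.data.frame(mat, stringsAsFactors = FALSE))
      }
      i <- j
    }
    i <- i + 1L
  }
  NULL
}

read_shift_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop <- star_loop(lines, c("Comp_ID", "Atom_ID", "Val"))
  if (is.null(loop))
    return(data.frame(residue_index = integer(), residue_name = character(),
                      atom = character(), shift = numeric(),
                      stringsAsFactors = FALSE))
  seq_col <- intersect(c("Comp_index_ID", "Seq_ID"), names(loop))[1]
  if (is.na(seq_col))
    stop(path, ": shift loop lacks a residue index tag", call. = FALSE)
  data.frame(residue_index = as.integer(loop[[seq_col]]),
             residue_name = toupper(loop$Comp_ID),
             atom = loop$Atom_ID,
             shift = as.numeric(loop$Val),
             stringsAsFactors = FALSE)
}

#' Write a shift table as TSV
#'
#' @param table a [shift_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
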