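#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards. All stochastic routines in the
## package funnel through this so that no call mutates global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

aa_three_from_one <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

## van der Waals radii (Angstrom) by element, Bondi-style; fallback 1.70.
vdw_radius <- function(element) {
  radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
             P = 1.80, SE = 1.90, ZN = 1.39, F = 1.47, CL = 1.75)
  el <- toupper(element)
  r <- radii[el]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using default radius 1.70 A",
                    paste(unique(el[unknown]), collapse = ", ")))
    r[unknown] <- 1.70
  }
  unname(r)
}

## Element symbol guessed from a PDB atom name when the element column is
## blank (first non-digit character; two-letter zinc handled explicitly).
element_from_atom_name <- function(atom) {
  a <- toupper(trimws(atom))
  out <- ifelse(a %in% c("ZN", "ZN2"), "ZN",
                substr(gsub("^[0-9']*", "", a), 1L, 1L))
  out[out == ""] <- "C"
  out
}

## Deterministic quasi-uniform point set on the unit sphere
## (Fibonacci/golden-section spiral); used by the SASA quadrature.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

is_finite_number <- function(x) is.numeric(x) && all(is.finite(x))

stop_parse <- function(path, line_no, msg) {
  stop(sprintf("%s: parse error at line %d: %s", path, line_no, msg),
       call. = FALSE)
}
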