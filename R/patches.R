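## Clustering of perturbed sites into contiguous surface patches.

#' Cluster significant sites into spatial patches
#'
#' Single-linkage clustering of residues on the structure: the distance
#' between two sites is the minimum heavy-atom distance between their
#' residues, averaged over models; two sites are linked when that distance
#' is at most `linkage_cutoff`, and patches are the connected components.
#' The patches partition the input site set and are returned largest
#' first.
#'
#' @param ensemble a [structure_ensemble].
#' @param significant_sites data frame with `residue_index` and optionally
#'   `site` ("backbone"/"sidechain"), e.g. from [select_significant()];
#'   or a plain vector of residue indices.
#' @param linkage_cutoff linkage distance in Angstrom (default 8.0).
#' @return List of class `patch_set`; each patch has `members`
#'   (site labels), `residues`, and `anchor` (mean CA position of member
#'   residues in model 1).
#' @export
cluster_patches <- function(ensemble, significant_sites,
                            linkage_cutoff = 8.0) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (is.data.frame(significant_sites)) {
    sites <- significant_sites
    if (is.null(sites$site)) sites$site <- "backbone"
  } else {
    sites <- data.frame(residue_index = as.integer(significant_sites),
                        site = rep("backbone", length(significant_sites)),
                        stringsAsFactors = FALSE)
  }
  if (!nrow(sites)) return(structure(list(), class = "patch_set"))
  a <- ensemble$atoms
  resolvable <- sites$residue_index %in% a$residue_index
  if (any(!resolvable)) {
    warning(sprintf("cluster_patches: site(s) %s not in the ensemble, dropped",
                    paste(sites$residue_index[!resolvable], collapse = ", ")))
    sites <- sites[resolvable, , drop = FALSE]
  }
  if (!nrow(sites)) return(structure(list(), class = "patch_set"))
  labels <- paste0(sites$residue_index,
                   ifelse(sites$site == "sidechain", "sc", ""))

  nm <- n_models(ensemble)
  heavy_idx <- lapply(sites$residue_index, function(r)
    select_atoms(ensemble, residues = r, atoms = "heavy"))
  ns <- nrow(sites)
  D <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    dk <- vapply(seq_len(nm), function(k) {
      xi <- matrix(ensemble$xyz[heavy_idx[[i]], , k], ncol = 3L)
      xj <- matrix(ensemble$xyz[heavy_idx[[j]], , k], ncol = 3L)
      d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
      sqrt(max(min(d2), 0))
    }, numeric(1))
    D[i, j] <- D[j, i] <- mean(dk)
  }
  ## connected components of the <= cutoff graph (single linkage)
  comp <- seq_len(ns)
  repeat {
    changed <- FALSE
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (D[i, j] <= linkage_cutoff && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ca_rows <- select_atoms(ensemble, atoms = "CA")
  ca_res <- a$residue_index[ca_rows]
  patches <- lapply(unique(comp), function(cc) {
    m <- comp == cc
    rows <- ca_rows[ca_res %in% sites$residue_index[m]]
    anchor <- if (length(rows))
      colMeans(matrix(ensemble$xyz[rows, , 1], ncol = 3L)) else
        rep(NA_real_, 3L)
    list(members = labels[m], residues = sites$residue_index[m],
         anchor = anchor)
  })
  patches <- patches[order(-vapply(patches,
                                   function(p) length(p$members),
                                   integer(1)))]
  structure(patches, class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patch(es)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  patch %d (%d sites): %s\n", i, length(x[[i]]$members),
                paste(x[[i]]$members, collapse = ", ")))
  invisible(x)
}
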