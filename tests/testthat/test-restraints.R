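site1 <- function() zinc_site("site I", data.frame(
  residue_index = c(92L, 95L, 111L, 114L),
  residue_name = c("CYS", "HIS", "CYS", "CYS"),
  donor_atom = c("SG", "NE2", "SG", "SG")))

site2 <- function() zinc_site("site II", data.frame(
  residue_index = c(103L, 106L, 120L, 123L),
  residue_name = c("CYS", "ASP", "HIS", "HIS"),
  donor_atom = c("SG", "OD1", "NE2", "NE2")))

test_that("zinc sites validate ligand chemistry", {
  expect_error(zinc_site("x", data.frame(residue_index = 1L,
                                         residue_name = "CYS",
                                         donor_atom = "SG")), "2-4")
  expect_error(zinc_site("x", data.frame(
    residue_index = c(1L, 2L), residue_name = c("CYS", "HIS"),
    donor_atom = c("NE2", "NE2"))), "not valid")
  expect_error(zinc_site("x", data.frame(
    residue_index = c(1L, 2L), residue_name = c("CYS", "GLU"),
    donor_atom = c("SG", "OE1"))), "unsupported")
})

test_that("zinc restraint generation enumerates the tetrahedral scheme", {
  ## empty degenerate site
  empty <- zinc_site("none", data.frame(residue_index = integer(),
                                        residue_name = character(),
                                        donor_atom = character()))
  expect_equal(nrow(generate_zinc_restraints(empty)), 0L)

  ## 3 Cys + 1 His: 4 Zn-donor + 3 arm tethers + 3 SG-SG + 3 NE2-SG = 13
  r1 <- generate_zinc_restraints(site1())
  expect_equal(nrow(r1), 13L)
  expect_true(all(r1$kind == "zinc"))
  expect_equal(sum(r1$atom_i == "ZN" &
                     r1$atom_j %in% c("SG", "NE2", "OD1", "OD2")), 4L)
  expect_equal(sum(r1$atom_i == "ZN" & r1$atom_j %in% c("CB", "CG")), 3L)
  expect_equal(sum(r1$atom_i == "SG" & r1$atom_j == "SG"), 3L)
  expect_equal(sum(r1$atom_i == "NE2" & r1$atom_j == "SG"), 3L)

  ## 1 Cys + 1 Asp + 2 His: 4 Zn-donor + 2 tethers + 0 SG-SG + 2 NE2-SG = 8
  r2 <- generate_zinc_restraints(site2())
  expect_equal(nrow(r2), 8L)
  expect_equal(sum(r2$atom_i == "SG" & r2$atom_j == "SG"), 0L)
  expect_equal(sum(r2$atom_i == "NE2" & r2$atom_j == "SG"), 2L)

  ## bounds come from the scheme table
  sg <- r1[r1$atom_i == "SG" & r1$atom_j == "SG", ]
  expect_true(all(sg$lower == 3.55 & sg$upper == 3.95))

  ## deterministic and order-invariant in ligand listing
  shuffled <- zinc_site("site I", site1()$ligands[c(3, 1, 4, 2), ])
  expect_identical(write_restraints(generate_zinc_restraints(shuffled)),
                   write_restraints(r1))
})

test_that("NOE classification bins by sequence separation exhaustively", {
  mk <- function(seps, kind = "NOE") restraint_list(data.frame(
    res_i = 10L, name_i = "ALA", atom_i = "HA",
    res_j = 10L + seps, name_j = "ALA", atom_j = "HN",
    lower = 0, upper = 5, kind = kind))
  rc <- classify_noe(mk(c(0, 1, 2, 4, 5, 9)))
  expect_equal(rc$intra, 1L)
  expect_equal(rc$sequential, 1L)
  expect_equal(rc$medium, 2L)
  expect_equal(rc$long, 2L)
  expect_equal(rc$total, 6L)
  expect_equal(rc$total, rc$intra + rc$sequential + rc$medium + rc$long)

  empty <- classify_noe(restraint_list())
  expect_equal(empty$total, 0L)

  mixed <- restraint_list(rbind(as.data.frame(mk(c(0, 3, 7))),
                                as.data.frame(mk(2, kind = "zinc"))))
  cm <- classify_noe(mixed)
  expect_equal(cm$total, 3L)
  expect_equal(cm$ignored, 1L)

  ## random separations: bins stay disjoint and exhaustive
  seps <- with_seed(42L, sample(0:20, 60, replace = TRUE))
  seps <- seps[seps > 0 | seq_along(seps) %% 2 == 0]
  rr <- classify_noe(mk(seps))
  expect_equal(rr$intra + rr$sequential + rr$medium + rr$long, rr$total)
})

test_that("violation counting is per restraint with a max-over-models excess", {
  ens <- gen_ensemble(ensemble_recipe("hairpin", 10L, core_sigma = 0,
                                      n_models = 3L, seed = 3L))
  rl <- gen_restraints_from_structure(ens, contact_cutoff = 5, slack = 0.2)

  ## restraints derived from the structure itself: no violations
  rep0 <- check_violations(rl, ens, threshold = 0.5)
  expect_equal(rep0$count, 0L)

  ## shrink one upper bound 0.6 A below the true distance: 1 violation
  plant <- function(delta) {
    r <- as.data.frame(rl)
    r$upper[1] <- r$upper[1] - 0.2 - delta   # remove slack, cut below truth
    restraint_list(r)
  }
  rep1 <- check_violations(plant(0.6), ens, threshold = 0.5)
  expect_equal(rep1$count, 1L)
  expect_gt(rep1$violations$max_excess[1], 0.5)

  ## 0.4 A below truth is within the 0.5 A threshold
  expect_equal(check_violations(plant(0.4), ens, threshold = 0.5)$count, 0L)

  ## count is non-increasing in the threshold
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                   function(th) check_violations(plant(0.6), ens,
                                                 threshold = th)$count,
                   integer(1))
  expect_true(all(diff(counts) <= 0))

  ## unresolvable atoms are skipped with a warning
  bad <- restraint_list(data.frame(
    res_i = 1L, name_i = "ALA", atom_i = "XX", res_j = 2L,
    name_j = "ALA", atom_j = "CA", lower = 0, upper = 5, kind = "NOE"))
  expect_warning(repb <- check_violations(bad, ens), "skipped")
  expect_equal(repb$n_skipped, 1L)
  expect_equal(repb$count, 0L)
})
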