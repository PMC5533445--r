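test_that("rigid superposition recovers exact transforms", {
  a <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 2, 0, 1, 1, 1), 4, 3, byrow = TRUE)

  sp0 <- superpose(a, a)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)

  R <- rot_xyz(0.4, -1.1, 2.3)
  b <- a %*% t(R) + matrix(c(3, -2, 7), 4, 3, byrow = TRUE)
  sp <- superpose(a, b)
  expect_lt(sp$rmsd, 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)

  ## displaced-atom toy matches the brute-force rotational minimum
  b2 <- a; b2[4, ] <- b2[4, ] + c(0.9, -0.4, 0.3)
  expect_equal(superpose(a, b2)$rmsd, brute_rmsd(a, b2), tolerance = 1e-6)

  ## symmetry and rigid-motion invariance
  expect_equal(superpose(a, b2)$rmsd, superpose(b2, a)$rmsd,
               tolerance = 1e-9)
  b3 <- b2 %*% t(rot_z(57)) + matrix(c(-4, 0.5, 2), 4, 3, byrow = TRUE)
  expect_equal(superpose(a, b3)$rmsd, superpose(a, b2)$rmsd,
               tolerance = 1e-9)

  expect_error(superpose(a[1:2, ], a[1:2, ]), ">= 3")
  lin <- cbind(0:3, 0, 0)
  expect_error(superpose(lin, lin), "collinear")
})

test_that("average pairwise RMSD matches direct enumeration", {
  ## duplicate models: exactly zero
  ens0 <- gen_ensemble(ensemble_recipe("helix", 10L, core_sigma = 0,
                                       n_models = 4L))
  st0 <- average_pairwise_rmsd(ens0, atom_set = "backbone")
  expect_equal(st0$mean, 0, tolerance = 1e-12)
  expect_equal(st0$sd, 0, tolerance = 1e-12)

  ## jittered ensemble: agrees with a by-hand loop over pairs and with
  ## the analytic expectation. Per-atom differences between two models
  ## have variance 2 sigma^2 in each of 3 coordinates, so the expected
  ## pairwise RMSD is sqrt(6) sigma (within 10%, superposition shrinks it
  ## slightly).
  sigma <- 0.25
  ens <- gen_ensemble(ensemble_recipe("helix", 40L, core_sigma = sigma,
                                      n_models = 3L, seed = 5L))
  st <- average_pairwise_rmsd(ens, atom_set = "heavy")
  sel <- which(toupper(ens$atoms$element) != "H")
  by_hand <- mean(c(
    superpose(ens$xyz[sel, , 1], ens$xyz[sel, , 2])$rmsd,
    superpose(ens$xyz[sel, , 1], ens$xyz[sel, , 3])$rmsd,
    superpose(ens$xyz[sel, , 2], ens$xyz[sel, , 3])$rmsd))
  expect_equal(st$mean, by_hand, tolerance = 1e-12)
  expect_lt(abs(st$mean - sqrt(6) * sigma) / (sqrt(6) * sigma), 0.10)

  ## residue selection restricts the atom set
  stsel <- average_pairwise_rmsd(ens, residues = 1:10, "backbone")
  expect_equal(stsel$n_atoms, 30L)
  expect_error(average_pairwise_rmsd(ens, residues = 900:910),
               "empty")
})

test_that("heavy-atom RMSD is at least backbone RMSD on jittered ensembles", {
  ens <- gen_ensemble(ensemble_recipe("helix", 20L, core_sigma = 0.3,
                                      n_models = 5L, seed = 9L))
  bb <- average_pairwise_rmsd(ens, atom_set = "backbone")
  hv <- average_pairwise_rmsd(ens, atom_set = "heavy")
  ## uniform isotropic jitter: both estimate the same dispersion, but the
  ## larger heavy-atom set cannot fit better than its backbone subset
  expect_gte(hv$mean, bb$mean * 0.95)
})

test_that("ordered-residue detection separates rigid core from planted tail", {
  rigid <- gen_ensemble(ensemble_recipe("helix", 12L, core_sigma = 0,
                                        n_models = 4L))
  ordr <- ordered_residues(rigid, 1.0)
  expect_equal(ordr$residues, 1:12)

  ens <- gen_ensemble(ensemble_recipe("helix+tail", 18L,
                                      core_sigma = 0.3, tail_sigma = 3,
                                      n_models = 10L, seed = 2L))
  tail_res <- attr(ens, "tail_residues")
  ord <- ordered_residues(ens, 1.0)
  ## the wildly jittered tail also degrades the global CA superposition,
  ## so only the tail's exclusion is guaranteed, not full core inclusion
  expect_false(any(tail_res %in% ord$residues))
  expect_true(mean(ord$rmsf[as.character(tail_res)]) >
                mean(ord$rmsf[as.character(attr(ens, "core_residues"))]))
})

test_that("DSSP-style assignment finds helices, sheets and coil", {
  helix <- gen_ensemble(ensemble_recipe("helix", 12L, n_models = 1L))
  st <- secondary_structure(helix)
  expect_true(all(st[3:10] == "H"))

  hairpin <- gen_ensemble(ensemble_recipe("hairpin", 12L, n_models = 1L))
  sh <- secondary_structure(hairpin)
  expect_gte(sum(sh == "E"), 6)
  expect_true(all(sh[6:7] != "E"))  # the turn itself is not strand

  ## a fully extended isolated strand has no ladder partner: coil
  ext <- gen_ensemble(ensemble_recipe("helix", 10L, n_models = 1L))
  bb <- build_backbone(rep(-139, 10), rep(135, 10))
  iso <- structure_ensemble(bb$atoms, bb$xyz)
  expect_true(all(secondary_structure(iso) == "C"))

  ## invariant under rigid motion
  moved <- helix
  moved$xyz[, , 1] <- helix$xyz[, , 1] %*% t(rot_xyz(1, 0.5, -0.7)) +
    matrix(c(10, -5, 3), nrow(helix$atoms), 3, byrow = TRUE)
  expect_identical(secondary_structure(moved), st)
})

test_that("ensemble secondary-structure frequencies are tabulated", {
  ens <- gen_ensemble(ensemble_recipe("helix", 12L, core_sigma = 0.1,
                                      n_models = 4L, seed = 8L))
  prof <- element_frequency(ens)
  expect_equal(dim(prof$states), c(4L, 12L))
  expect_true(all(abs(rowSums(prof$frequency) - 1) < 1e-12))
  expect_true(all(prof$consensus[5:9] == "H"))
})

test_that("SASA quadrature matches closed forms and occlusion limits", {
  ## isolated atom: exact sphere area within 0.5%
  one <- atom_sasa(matrix(0, 1, 3), "C")
  exact <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(one - exact) / exact, 0.005)

  ## atom enclosed in a tight shell of neighbors: zero
  shell <- sphere_points(60L) * 2.0
  sasa <- atom_sasa(rbind(c(0, 0, 0), shell), rep("C", 61L))
  expect_equal(sasa[1], 0)

  ## two-atom total SASA decreases monotonically on approach
  dists <- seq(8, 0, length.out = 21)
  totals <- vapply(dists, function(d)
    sum(atom_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c("C", "C"))),
    numeric(1))
  expect_true(all(diff(totals) <= 1e-9))

  ## unknown element falls back with a warning
  expect_warning(atom_sasa(matrix(0, 1, 3), "Q"), "default radius")
})

test_that("accessibility classifies burial by relative side-chain exposure", {
  ens <- gen_ensemble(ensemble_recipe("helix", 10L, n_models = 1L))
  acc <- accessibility(ens, n_points = 240L)
  expect_equal(nrow(acc), 10L)
  expect_true(all(acc$sc_sasa >= 0))
  ## CB-only alanines on an exposed ideal helix are not buried
  expect_false(any(acc$buried[3:8]))
  expect_true(all(acc$buried == (!is.na(acc$rel_exposure) &
                                   acc$rel_exposure < 0.15)))
})

test_that("patch clustering recovers planted spatial clusters", {
  expect_length(cluster_patches(
    gen_ensemble(ensemble_recipe("helix", 6L, n_models = 1L)),
    integer()), 0L)

  ## two residue groups far apart: exactly two patches with the planted
  ## membership (single linkage at 8 A)
  bb <- build_backbone(rep(-57, 8), rep(-47, 8))
  far <- bb
  far$xyz <- rbind(bb$xyz, sweep(bb$xyz, 2, c(60, 0, 0), "+"))
  far$atoms <- rbind(bb$atoms, transform(bb$atoms,
                                         residue_index = residue_index + 8L))
  ens <- structure_ensemble(far$atoms, far$xyz)
  p <- cluster_patches(ens, c(1:3, 9:12), linkage_cutoff = 8)
  expect_length(p, 2L)
  expect_setequal(p[[1]]$residues, 9:12)
  expect_setequal(p[[2]]$residues, 1:3)

  ## brute-force single linkage oracle on the same distance relation:
  ## residues 1:3 chain together, 9:12 chain together, groups never join
  expect_true(all(vapply(p, function(q)
    all(q$residues <= 8) || all(q$residues > 8), logical(1))))

  ## patch count is non-increasing in the linkage cutoff
  counts <- vapply(c(4, 8, 20, 80), function(co)
    length(cluster_patches(ens, c(1:3, 9:12), co)), integer(1))
  expect_true(all(diff(counts) <= 0))

  ## unresolvable sites are dropped with a warning
  expect_warning(cluster_patches(ens, c(1, 99)), "dropped")
})
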