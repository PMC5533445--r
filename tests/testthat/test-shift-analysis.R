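test_that("composite CSP follows the two-nuclei combination rule", {
  apo <- make_peaks(1:3, H = c(8.0, 8.2, 8.4), N = c(118, 120, 122))

  ## identical lists: all zero
  z <- compute_csp(apo, apo)
  expect_true(all(z$csp == 0))

  ## hand value: ddH 0.06, ddN 0.52 -> sqrt(0.0036 + 0.0064) = 0.10
  b <- make_peaks(1:3, H = c(8.06, 8.2, 8.5), N = c(118.52, 120, 122))
  rec <- compute_csp(apo, b)
  expect_equal(rec$csp[1], 0.10, tolerance = 1e-12)
  ## proton-only change passes through unscaled
  expect_equal(rec$csp[3], 0.1, tolerance = 1e-12)

  ## symmetric in spectra order, invariant to shift-change sign
  rev_rec <- compute_csp(b, apo)
  expect_equal(rec$csp, rev_rec$csp, tolerance = 1e-14)

  ## scale factor 1 reduces to the Euclidean norm
  e <- compute_csp(apo, b, scale_N = 1)
  expect_equal(e$csp[1], sqrt(0.06^2 + 0.52^2), tolerance = 1e-12)

  ## unmatched peaks reported, never dropped silently
  extra <- make_peaks(1:4, H = c(8.06, 8.2, 8.5, 9), N = c(118.52, 120, 122, 125))
  expect_warning(rec2 <- compute_csp(apo, extra), "unmatched")
  expect_equal(attr(rec2, "unmatched"), "4 backbone")
  expect_equal(nrow(rec2), 3L)
})

test_that("significance selection is inclusive at the cutoff", {
  rec <- structure(data.frame(
    residue_index = 1:3, site = "backbone", delta_H = c(0.09, 0.10, 0.11),
    delta_N = 0, csp = c(0.09, 0.10, 0.11)),
    class = c("csp_records", "data.frame"))
  expect_equal(select_significant(rec, 0.10)$residue_index, 2:3)
  expect_equal(nrow(select_significant(rec, 0.5)), 0L)
  expect_equal(nrow(select_significant(rec, 0)), 3L)

  sc <- rec; sc$site <- c("backbone", "sidechain", "backbone")
  expect_equal(select_significant(sc, 0.10)$site_label, c("2sc", "3"))
})

test_that("titration trajectories track the 1:1 fast-exchange isotherm", {
  sites <- data.frame(residue_index = 1:4, site = "backbone",
                      H0 = c(8, 8.1, 8.2, 8.3), N0 = c(118, 119, 120, 121),
                      dH_max = c(0, 0.1, 0.15, 0.05),
                      dN_max = c(0, 0.8, 1.2, 0.3))
  model <- binding_model(kd = 1, protein_concentration = 200)
  tit <- gen_titration(model, sites)
  traj <- titration_trajectory(tit)

  ## no flags, non-decreasing in equivalents for every site
  expect_false(any(traj$non_monotone))
  expect_true(all(apply(traj$csp, 1, function(v) all(diff(v) >= 0))))

  ## at 2 equivalents of a tight binder the CSP is within 2% of the
  ## planted maximum
  planted <- sqrt(sites$dH_max^2 + (sites$dN_max / 6.5)^2)
  got <- traj$csp[, ncol(traj$csp)]
  expect_equal(unname(got[2:4]), planted[2:4], tolerance = 0.02)

  ## identical spectra at all points: zero trajectories, no flags
  flat <- gen_titration(binding_model(1, 200),
                        transform(sites, dH_max = 0, dN_max = 0))
  tf <- titration_trajectory(flat)
  expect_true(all(tf$csp == 0))
  expect_false(any(tf$non_monotone))
})

test_that("CSI classification calls helix and strand runs, else coil", {
  rc <- random_coil_table()
  ala <- function(atom) rc$shift[rc$residue_name == "ALA" & rc$atom == atom]

  mk <- function(ca_off = rep(0, 30), cb_off = rep(0, 30)) {
    make_shifts(1:30, rep("ALA", 30),
                CA = ala("CA") + ca_off, CB = ala("CB") + cb_off)
  }
  ## observed == random coil: all coil
  expect_true(all(csi_classify(mk())$state == "C"))

  ## +3 ppm CA on residues 10-17: helix there, coil elsewhere
  off <- rep(0, 30); off[10:17] <- 3
  st <- csi_classify(mk(ca_off = off))
  expect_equal(unname(st$state[st$residue_index %in% 10:17]), rep("H", 8))
  expect_true(all(st$state[!st$residue_index %in% 10:17] == "C"))

  ## -2 CA and +2 CB on residues 5-9: strand
  ca <- rep(0, 30); ca[5:9] <- -2
  cb <- rep(0, 30); cb[5:9] <- 2
  st2 <- csi_classify(mk(ca_off = ca, cb_off = cb))
  expect_equal(unname(st2$state[st2$residue_index %in% 5:9]), rep("E", 5))

  ## runs shorter than the consensus length stay coil
  short <- rep(0, 30); short[10:12] <- 3
  expect_true(all(csi_classify(mk(ca_off = short))$state == "C"))
})

test_that("CSI depends only on secondary shifts and is idempotent", {
  rc <- random_coil_table()
  ala_ca <- rc$shift[rc$residue_name == "ALA" & rc$atom == "CA"]
  off <- rep(0, 12); off[3:10] <- 3
  obs <- make_shifts(1:12, rep("ALA", 12), CA = ala_ca + off)
  base <- csi_classify(obs)

  ## apply the same referencing offset to both tables: unchanged
  rc2 <- as.data.frame(rc)
  rc2$shift[rc2$atom == "CA"] <- rc2$shift[rc2$atom == "CA"] + 1.7
  obs2 <- as.data.frame(obs)
  obs2$shift[obs2$atom == "CA"] <- obs2$shift[obs2$atom == "CA"] + 1.7
  shifted <- csi_classify(shift_table(obs2), random_coil = shift_table(rc2))
  expect_equal(shifted$state, base$state)

  ## idempotent: same input, same output
  expect_equal(csi_classify(obs)$state, base$state)

  ## residues missing CA or missing from the reference are skipped
  odd <- make_shifts(c(1, 2), c("ALA", "XXX"), CA = c(52.5, 60))
  expect_warning(sk <- csi_classify(odd), "random-coil")
  expect_equal(sk$residue_index, 1L)
})

test_that("zinc-coordination scores are logistic along the centroid axis", {
  free_c <- c(CA = 59.0, CB = 28.0)
  bound_c <- c(CA = 58.5, CB = 31.5)
  tab <- make_shifts(1:2, rep("CYS", 2),
                     CA = c(free_c["CA"], bound_c["CA"]),
                     CB = c(free_c["CB"], bound_c["CB"]))
  sc <- zinc_probability(tab, 1:2)
  expect_lt(sc$score[1], 0.5)
  expect_gt(sc$score[2], 0.5)

  ## monotone along the segment between the centroids (20-point scan)
  t_seq <- seq(0, 1, length.out = 20)
  tab2 <- make_shifts(seq_along(t_seq), rep("CYS", length(t_seq)),
                      CA = free_c["CA"] + t_seq * (bound_c["CA"] - free_c["CA"]),
                      CB = free_c["CB"] + t_seq * (bound_c["CB"] - free_c["CB"]))
  sc2 <- zinc_probability(tab2, seq_along(t_seq))
  expect_true(all(diff(sc2$score) > 0))
  expect_true(all(sc2$score >= 0 & sc2$score <= 1))

  ## missing CB: omitted with warning
  tab3 <- make_shifts(1:2, rep("CYS", 2), CA = c(58, 58),
                      CB = c(31, NA))
  expect_warning(sc3 <- zinc_probability(tab3, 1:2), "omitted")
  expect_equal(sc3$residue_index, 1L)
})
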