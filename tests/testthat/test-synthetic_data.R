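test_that("phantom compartments have the advertised orientations", {
  ph <- make_phantom(phantom_spec())
  expect_equal(names(which.max(ph$tensors$projection[1:3])), "dzz")
  expect_equal(names(which.max(ph$tensors$association[1:3])), "dyy")
  expect_equal(names(which.max(ph$tensors$subcortical[1:3])), "dxx")
  expect_setequal(unique(as.vector(ph$labels)),
                  c("background", "csf", "projection", "association",
                    "subcortical"))
  # all ROIs sit in the left (negative x) half
  expect_true(all(ph$rois$cx < 0))
})

test_that("the perivascular boost is exactly additive on Dxx", {
  base <- make_phantom(phantom_spec())
  boosted <- make_phantom(phantom_spec(perivascular_boost = 0.4e-3))
  expect_equal(boosted$tensors$projection["dxx"],
               base$tensors$projection["dxx"] + 0.4e-3)
  expect_equal(boosted$tensors$association["dxx"],
               base$tensors$association["dxx"] + 0.4e-3)
  expect_equal(boosted$tensors$projection[c("dyy", "dzz")],
               base$tensors$projection[c("dyy", "dzz")])
  expect_equal(boosted$analytic_alps, 2)
})

test_that("grids too small for the ROI sphere are rejected", {
  # 10 x 10 x 8 at (2, 2, 2.5) mm still fits 5 mm spheres
  ph <- make_phantom(phantom_spec(dims = c(10, 10, 8)))
  expect_s3_class(ph, "alps_phantom")
  rd <- roi_axis_means(ph$ground_truth, ph$rois)
  expect_true(all(c(rd$n_vox_proj, rd$n_vox_assoc) >= 1))
  # a 4-voxel-wide left half (2 voxel blocks in x) cannot hold one
  expect_error(make_phantom(phantom_spec(dims = c(4, 10, 8))),
               class = "alps_validation_error")
})

test_that("the forward signal model matches its closed form", {
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  spec <- isotropic_phantom_spec(d = 1e-3, dims = c(10, 10, 8), s0 = 700)
  ph <- make_phantom(spec)
  dwi <- simulate_dwi(ph, gtab = gt, noise_sigma = 0)
  expect_equal(unique(as.vector(dwi$signal[, , , 1])), 700)      # b0: S = s0
  expect_equal(unique(round(as.vector(dwi$signal[, , , 2]), 9)),
               round(700 * exp(-1), 9))                          # s0 e^-1
})

test_that("DWI simulation is seed-reproducible", {
  ph <- make_phantom(small_phantom_spec(noise_sigma = 20))
  a <- simulate_dwi(ph, seed = 99)
  b <- simulate_dwi(ph, seed = 99)
  c <- simulate_dwi(ph, seed = 100)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
  expect_error(simulate_dwi(ph, noise_sigma = -1),
               class = "alps_validation_error")
})

test_that("simulated cohorts recover the specified margins at large n", {
  spec <- cohort_spec(n = c(NC = 10000, PDN = 10000, `PD-MCI` = 10000,
                            PDD = 10000))
  co <- simulate_cohort(spec, seed = 21)
  means <- tapply(co$nuclear_dna, co$group, mean)
  target <- c(NC = 19.34, PDN = 31.35, `PD-MCI` = 32.03, PDD = 46.13)
  expect_true(all(abs(means[names(target)] - target) / target < 0.02))
  # ages too (untruncated Gaussian margins)
  age_means <- tapply(co$age, co$group, mean)
  age_target <- c(NC = 61.53, PDN = 60.08, `PD-MCI` = 63.80, PDD = 65.76)
  expect_true(all(abs(age_means[names(age_target)] - age_target) /
                    age_target < 0.02))
})

test_that("rank-correlation targets are recovered within 0.03 at n = 10000", {
  spec <- cohort_spec(n = c(NC = 10000, PDN = 2, `PD-MCI` = 2, PDD = 2))
  co <- simulate_cohort(spec, seed = 31)
  nc <- co[co$group == "NC", ]
  for (pair in list(c("nuclear_dna", -0.278), c("mito_dna", -0.201),
                    c("mmse", 0.222), c("casi", 0.178))) {
    rho <- suppressMessages(
      spearman_cor(nc, "alps", pair[[1]])$statistic)
    expect_lt(abs(rho - as.numeric(pair[[2]])), 0.03)
  }
  # PD-only targets, checked within one PD group
  spec2 <- cohort_spec(n = c(NC = 2, PDN = 10000, `PD-MCI` = 2, PDD = 2))
  pdn <- simulate_cohort(spec2, seed = 32)
  pdn <- pdn[pdn$group == "PDN", ]
  rho_updrs <- spearman_cor(pdn, "alps", "updrs_total")$statistic
  expect_lt(abs(rho_updrs - (-0.307)), 0.03)
})

test_that("marginals are distributionally faithful (KS at n = 10000)", {
  spec <- cohort_spec(n = c(NC = 10000, PDN = 2, `PD-MCI` = 2, PDD = 2))
  co <- simulate_cohort(spec, seed = 41)
  nc <- co[co$group == "NC", ]
  ks <- suppressWarnings(stats::ks.test(nc$age, "pnorm", 61.53, 4.75))
  expect_gt(ks$p.value, 0.01)
  # untruncated z-scores are standard normal in NC
  ks2 <- suppressWarnings(stats::ks.test(nc$z_attention, "pnorm", 0, 1))
  expect_gt(ks2$p.value, 0.01)
})

test_that("zero-SD margins are deterministic and classified consistently", {
  margins <- default_margins()
  for (v in names(margins)) margins[[v]]$sd[] <- 0
  spec <- cohort_spec(margins = margins)
  co <- simulate_cohort(spec, seed = 51)
  pd <- co[co$group != "NC", ]
  expect_true(all(tapply(pd$alps, droplevels(pd$group),
                         function(v) length(unique(v))) == 1))
  zcols <- c("z_attention", "z_executive", "z_language", "z_memory",
             "z_visuospatial")
  lab <- classify_cognitive_status(as.matrix(pd[, zcols]), pd$mmse)
  expect_equal(lab, as.character(pd$group))
})

test_that("cohort generation is seed-reproducible", {
  expect_identical(simulate_cohort(cohort_spec(), seed = 61),
                   simulate_cohort(cohort_spec(), seed = 61))
  expect_false(identical(simulate_cohort(cohort_spec(), seed = 61),
                         simulate_cohort(cohort_spec(), seed = 62)))
})

test_that("an impossible correlation matrix is rejected", {
  expect_error(cohort_spec(rho_alps = c(nuclear_dna = -0.99,
                                        mito_dna = -0.99, mmse = 0.99,
                                        casi = 0.99, updrs_total = -0.99)),
               class = "alps_validation_error")
  expect_error(cohort_spec(rho_alps = c(mmse = 1)),
               class = "alps_validation_error")
})
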