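test_that("design matrix has the closed-form tensor-model coefficients", {
  gt <- gradient_table(c(0, 1000, 1000),
                       rbind(c(0, 0, 0), c(1, 0, 0),
                             c(1 / sqrt(2), 1 / sqrt(2), 0)))
  X <- design_matrix(gt)
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0, 0, 0, 0))      # b0 row
  expect_equal(unname(X[2, c("log_s0", "dxx")]), c(1, -1000))
  expect_equal(unname(X[2, c("dxy", "dxz", "dyz")]), c(0, 0, 0))
  # g = (1,1,0)/sqrt(2): gx*gy = 1/2, so the Dxy coefficient is -2b/2 = -b
  expect_equal(unname(X[3, "dxy"]), -1000)
  expect_equal(unname(X[3, c("dxx", "dyy")]), c(-500, -500))
})

test_that("noiseless OLS recovers isotropic and anisotropic tensors exactly", {
  gt <- default_gradient_table()
  iso <- c(0.7e-3, 0.7e-3, 0.7e-3, 0, 0, 0)
  fit <- fit_tensor_voxel(oracle_signal(iso, gt, s0 = 1000), gt)
  expect_equal(unlist(fit[c("dxx", "dyy", "dzz")]),
               c(dxx = 0.7e-3, dyy = 0.7e-3, dzz = 0.7e-3),
               tolerance = 1e-10)
  expect_equal(unlist(fit[c("dxy", "dxz", "dyz")]),
               c(dxy = 0, dxz = 0, dyz = 0), tolerance = 1e-13)
  expect_equal(fit$s0, 1000, tolerance = 1e-8)

  aniso <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  fit2 <- fit_tensor_voxel(oracle_signal(aniso, gt, s0 = 500), gt)
  expect_equal(unname(unlist(fit2[c("dxx", "dyy", "dzz", "dxy", "dxz",
                                    "dyz")])),
               aniso, tolerance = 1e-10)
})

test_that("arbitrary SPD tensors round-trip through simulate + fit", {
  withr::local_seed(3)
  gt <- default_gradient_table()
  for (rep in 1:25) {
    d6 <- random_spd_tensor()
    fit <- fit_tensor_voxel(oracle_signal(d6, gt, s0 = 800), gt)
    got <- unname(unlist(fit[c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")]))
    expect_lt(max(abs(got - d6)) / max(abs(d6)), 1e-8)
  }
})

test_that("OLS fit agrees with an independent lm-based route", {
  withr::local_seed(4)
  gt <- default_gradient_table()
  for (rep in 1:100) {
    d6 <- random_spd_tensor()
    sig <- oracle_signal(d6, gt, s0 = 1200)
    fit <- fit_tensor_voxel(sig, gt)
    ora <- oracle_lm_tensor(sig, gt)
    got <- unlist(fit[c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")])
    expect_lt(max(abs(got - ora[1:6]) / pmax(abs(ora[1:6]), 1e-12)), 1e-6)
    expect_lt(abs(fit$s0 - ora["s0"]) / ora["s0"], 1e-6)
  }
})

test_that("too few distinct directions raises an estimation error", {
  dirs <- rbind(diag(3), c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2))
  gt <- gradient_table(c(0, rep(1000, 5)), rbind(c(0, 0, 0), dirs))
  sig <- rep(1, 6)
  expect_error(fit_tensor_voxel(sig, gt), class = "alps_estimation_error")
  # and a repeated direction does not count as distinct
  gt2 <- gradient_table(c(0, rep(1000, 6)),
                        rbind(c(0, 0, 0), dirs, dirs[1, , drop = FALSE]))
  expect_error(fit_tensor_voxel(rep(1, 7), gt2),
               class = "alps_estimation_error")
})

test_that("volume fit reproduces phantom ground truth voxelwise", {
  ph <- make_phantom(small_phantom_spec(perivascular_boost = 0.2e-3))
  dwi <- simulate_dwi(ph, noise_sigma = 0)
  tf <- fit_tensor_volume(dwi)
  expect_equal(tf$tensor, ph$ground_truth$tensor, tolerance = 1e-9)
  # uniform compartments give a constant FA inside each block
  fa_proj <- tf$maps$fa[ph$labels == "projection"]
  expect_lt(diff(range(fa_proj)), 1e-9)
  # MD identity holds at every voxel
  expect_equal(tf$maps$md,
               (tf$maps$dxx + tf$maps$dyy + tf$maps$dzz) / 3,
               tolerance = 1e-12)
  expect_error(fit_tensor_volume(dwi, mask = array(FALSE, dim(ph$labels))),
               class = "alps_validation_error")
})

test_that("tensor error shrinks as noise falls", {
  spec0 <- small_phantom_spec()
  ph <- make_phantom(spec0)
  errs <- sapply(c(40, 20, 10), function(sigma) {
    mean(sapply(1:3, function(s) {
      dwi <- simulate_dwi(ph, noise_sigma = sigma, seed = 100 + s)
      tf <- fit_tensor_volume(dwi)
      mean(abs(tf$tensor - ph$ground_truth$tensor))
    }))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("FA, MD and colour-FA follow their closed forms", {
  expect_equal(fa(c(1e-3, 1e-3, 1e-3, 0, 0, 0)), 0)
  expect_equal(fa(c(1e-3, 0, 0, 0, 0, 0)), 1)          # single-axis limit
  expect_equal(fa(rep(0, 6)), 0)                       # degenerate tensor
  d <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  expect_equal(md(d), 0.7666667e-3, tolerance = 1e-6)
  expect_equal(fa(d), 0.7990222, tolerance = 1e-6)
  expect_equal(axis_diffusivities(d),
               c(dxx = 1.7e-3, dyy = 0.3e-3, dzz = 0.3e-3))

  cz <- color_fa(c(0.3e-3, 0.3e-3, 1.7e-3, 0, 0, 0))
  expect_gt(cz["b"], max(cz[c("r", "g")]))             # projection: blue
  cx <- color_fa(c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0))
  expect_gt(cx["r"], max(cx[c("g", "b")]))             # subcortical: red
  expect_equal(unname(color_fa(c(1e-3, 1e-3, 1e-3, 0, 0, 0))), c(0, 0, 0))
})

test_that("FA is rotation invariant; axis diffusivities are not", {
  withr::local_seed(5)
  for (rep in 1:20) {
    d6 <- random_spd_tensor()
    R <- random_rotation()
    dr <- rotate_tensor(d6, R)
    expect_equal(fa(dr), fa(d6), tolerance = 1e-10)
    expect_equal(md(dr), md(d6), tolerance = 1e-10)
  }
  # a pure rotation moves diffusivity between axes
  d6 <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  expect_false(isTRUE(all.equal(axis_diffusivities(rotate_tensor(d6, Rz)),
                                axis_diffusivities(d6))))
})
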