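test_that("cv_distance is the centroid-to-centroid distance", {
  anchors <- rbind(c(0, 0), c(0, 0))
  lig <- ligand(c(0, 0), c(0, 0))
  expect_equal(cv_distance(lig, anchors), 0)
  # 3-4-5 triangle on the centroids
  lig2 <- ligand(c(3, 4), c(3, 4))
  expect_equal(cv_distance(lig2, c(0, 0)), 5)
  # random configuration vs brute-force centroid arithmetic
  set.seed(3)
  for (i in 1:5) {
    p <- matrix(stats::rnorm(8), 4, 2)
    lig3 <- ligand(p[1, ], p[2, ])
    a <- p[3:4, ]
    cen_l <- (p[1, ] + p[2, ]) / 2
    cen_a <- colMeans(a)
    expect_equal(cv_distance(lig3, a), sqrt(sum((cen_l - cen_a)^2)))
  }
  expect_error(cv_distance(lig, matrix(0, 1, 3)), "dimension")
})

test_that("deposit_hill follows the tempering rule", {
  b <- bias_state(0, hill_params(tempered = FALSE))
  b <- deposit_hill(b, cv = 2)
  expect_equal(b$hills$height, 0.3) # default initial height
  expect_equal(bias_potential(b, 2), 0.3)

  # tempered deposit onto an empty bias: exp(0) = 1
  bt <- bias_state(0, hill_params(tempered = TRUE, bias_factor = 10))
  bt <- deposit_hill(bt, cv = 2)
  expect_equal(bt$hills$height, 0.3)

  # tempered deposit where V_bias(cv) = (bias_factor - 1) kBT: height h0/e
  b9 <- bias_state(0, hill_params(initial_height = 9, tempered = FALSE))
  b9 <- deposit_hill(b9, cv = 5)
  expect_equal(bias_potential(b9, 5), 9)
  b9$params <- hill_params(initial_height = 0.3, tempered = TRUE,
                           bias_factor = 10)
  b9 <- deposit_hill(b9, cv = 5)
  expect_equal(b9$hills$height[2], 0.3 / exp(1), tolerance = 1e-12)
})

test_that("bias potential and gradient match their closed forms", {
  b <- bias_state(0)
  expect_equal(bias_potential(b, c(-1, 0, 5)), c(0, 0, 0))
  expect_equal(bias_gradient(b, c(-1, 0, 5)), c(0, 0, 0))

  b$hills <- data.frame(time = 0, center = 5, height = 0.3, width = 1)
  expect_equal(bias_potential(b, 5), 0.3)
  expect_equal(bias_gradient(b, 5), 0)
  expect_equal(bias_potential(b, 6), 0.3 * exp(-0.5))
  # finite-difference check of the gradient
  h <- 1e-5
  for (s in c(3.7, 5.4, 6.9)) {
    fd <- (bias_potential(b, s + h) - bias_potential(b, s - h)) / (2 * h)
    expect_equal(bias_gradient(b, s), fd, tolerance = 1e-6)
  }
})

test_that("bias is non-negative and pointwise non-decreasing in hills", {
  set.seed(21)
  b <- bias_state(0, hill_params(width = 0.7, tempered = FALSE))
  grid <- seq(0, 10, by = 0.25)
  v_prev <- bias_potential(b, grid)
  for (i in 1:25) {
    b <- deposit_hill(b, cv = stats::runif(1, 0, 10))
    v <- bias_potential(b, grid)
    expect_true(all(v >= 0))
    expect_true(all(v >= v_prev - 1e-12))
    v_prev <- v
  }
})

test_that("metadynamics run is deterministic and reduces to Langevin at zero height", {
  land <- build_landscape(landscape_spec())
  cfg <- quick_config(n_steps = 5000, save_stride = 50)
  pose <- docking_pose(land)

  m1 <- run_metad(land, cfg, hill_params(), start = pose, seed = 13)
  m2 <- run_metad(land, cfg, hill_params(), start = pose, seed = 13)
  expect_identical(m1$bias$hills, m2$bias$hills)
  expect_identical(m1$trajectory$cf3, m2$trajectory$cf3)

  m0 <- run_metad(land, cfg, hill_params(initial_height = 0), start = pose,
                  seed = 13)
  l0 <- run_langevin(land, cfg, pose, seed = 13)
  expect_identical(m0$trajectory$cf3, l0$cf3)

  expect_error(run_metad(land, cfg, hill_params(deposition_interval = 333),
                         start = pose, seed = 1), "divide")
})

test_that("engine hill heights replay exactly through the R tempering rule", {
  land <- build_landscape(landscape_spec())
  cfg <- quick_config(n_steps = 20000, save_stride = 200)
  m <- run_metad(land, cfg, hill_params(), seed = 4)
  h <- m$bias$hills
  expect_gt(nrow(h), 10)
  replay <- bias_state(land$spec$deep_pocket_center, m$bias$params)
  for (i in seq_len(nrow(h))) {
    replay <- deposit_hill(replay, h$center[i], step_time = h$time[i])
    expect_equal(replay$hills$height[i], h$height[i], tolerance = 1e-10)
  }
})

test_that("free-energy estimator handles empty, single-hill and tempered biases", {
  b <- bias_state(0, hill_params(tempered = FALSE))
  grid <- seq(0, 10, by = 0.1)
  prof0 <- estimate_free_energy(b, grid)
  expect_true(all(prof0$f == 0))

  b1 <- deposit_hill(b, cv = 5)
  prof1 <- estimate_free_energy(b1, grid)
  gauss <- 0.3 * exp(-(grid - 5)^2 / (2 * 0.5^2))
  expect_equal(prof1$f, -gauss - min(-gauss), tolerance = 1e-12)
  expect_equal(min(prof1$f), 0)

  # tempered rescaling: factor bias_factor / (bias_factor - 1)
  bt <- bias_state(0, hill_params(tempered = TRUE, bias_factor = 10))
  bt <- deposit_hill(bt, cv = 5)
  pt <- estimate_free_energy(bt, grid)
  expect_equal(max(pt$f), (10 / 9) * 0.3, tolerance = 1e-12)

  expect_error(estimate_free_energy(b, numeric(0)), "grid")
  expect_error(estimate_free_energy(b, c(2, 1)), "grid")
})
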