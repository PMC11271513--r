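#' Gaussian hill parameters for metadynamics
#'
#' @param initial_height Hill height before any tempering (kBT; default 0.3,
#'   the conventional value for ligand-unbinding runs).
#' @param width Hill width in collective-variable units.
#' @param deposition_interval Steps between hill depositions.
#' @param tempered Use well-tempered height damping (default `TRUE`).
#' @param bias_factor Well-tempered bias factor (> 1; used iff `tempered`).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(initial_height = 0.3, width = 0.5,
                        deposition_interval = 500, tempered = TRUE,
                        bias_factor = 10) {
  if (initial_height < 0) stop("`initial_height` must be non-negative")
  if (width <= 0) stop("`width` must be positive")
  if (deposition_interval < 1) stop("`deposition_interval` must be >= 1")
  if (tempered && bias_factor <= 1) stop("`bias_factor` must exceed 1")
  structure(list(initial_height = initial_height, width = width,
                 deposition_interval = as.integer(deposition_interval),
                 tempered = tempered, bias_factor = bias_factor),
            class = "hill_params")
}

#' Create an empty metadynamics bias state
#'
#' @param anchor_set Matrix (one anchor per row) or vector of collective
#'   variable anchor coordinates; the CV is the distance from the ligand
#'   probe centroid to the centroid of this set.
#' @param params A [hill_params()].
#' @return An object of class `bias_state` with an empty hill list.
#' @export
bias_state <- function(anchor_set, params = hill_params()) {
  a <- if (is.matrix(anchor_set)) anchor_set else matrix(anchor_set, nrow = 1)
  if (nrow(a) < 1) stop("`anchor_set` must be non-empty")
  structure(list(hills = data.frame(time = numeric(), center = numeric(),
                                    height = numeric(), width = numeric()),
                 anchor_set = a, anchor_centroid = colMeans(a),
                 params = params),
            class = "bias_state")
}

#' Distance collective variable
#'
#' Euclidean distance between the ligand probe centroid and the centroid of
#' the anchor set (the toy analogue of the distance between the ligand center
#' of mass and the binding-residue center of mass).
#'
#' @param frame A [ligand()].
#' @param anchor_set Matrix (one anchor per row) or single coordinate vector.
#' @return Non-negative scalar distance.
#' @export
cv_distance <- function(frame, anchor_set) {
  stopifnot(inherits(frame, "ligand"))
  a <- if (is.matrix(anchor_set)) anchor_set else matrix(anchor_set, nrow = 1)
  if (nrow(a) < 1) stop("`anchor_set` must be non-empty")
  if (ncol(a) != length(frame$probe_cf3)) stop("anchor dimension mismatch")
  centroid <- (frame$probe_cf3 + frame$probe_o1) / 2
  sqrt(sum((centroid - colMeans(a))^2))
}

#' Collective variable series of a trajectory
#'
#' @param trajectory A `trajectory`.
#' @param anchor_set As in [cv_distance()].
#' @return Numeric vector, one CV value per frame.
#' @export
trajectory_cv <- function(trajectory, anchor_set) {
  a <- if (is.matrix(anchor_set)) anchor_set else matrix(anchor_set, nrow = 1)
  if (ncol(a) != ncol(trajectory$cf3)) stop("anchor dimension mismatch")
  cen <- (trajectory$cf3 + trajectory$o1) / 2
  ac <- colMeans(a)
  sqrt(rowSums((cen - matrix(ac, nrow(cen), ncol(cen), byrow = TRUE))^2))
}

#' Deposit one Gaussian hill
#'
#' Appends a hill at the given CV value. In well-tempered mode the appended
#' height is `initial_height * exp(-V_bias(cv) / ((bias_factor - 1) kBT))`,
#' evaluated on the bias accumulated so far; otherwise the height is
#' `initial_height`.
#'
#' @param bias A [bias_state()].
#' @param cv CV value at which to center the hill.
#' @param params A [hill_params()] (defaults to the state's own).
#' @param step_time Simulation time stamp recorded with the hill.
#' @param kBT Thermal energy used in the tempering rule.
#' @return The updated `bias_state`.
#' @export
deposit_hill <- function(bias, cv, params = bias$params, step_time = NA_real_,
                         kBT = 1) {
  stopifnot(inherits(bias, "bias_state"), inherits(params, "hill_params"))
  h <- params$initial_height
  if (params$tempered)
    h <- h * exp(-bias_potential(bias, cv) / ((params$bias_factor - 1) * kBT))
  bias$hills <- rbind(bias$hills,
                      data.frame(time = step_time, center = cv, height = h,
                                 width = params$width))
  bias
}

#' Evaluate the accumulated bias potential
#'
#' `V_bias(cv) = sum_i h_i exp(-(cv - c_i)^2 / (2 w_i^2))`; non-negative and
#' pointwise non-decreasing as hills accumulate.
#'
#' @param bias A [bias_state()].
#' @param cv Numeric vector of CV values.
#' @return Bias energies at `cv`.
#' @export
bias_potential <- function(bias, cv) {
  h <- bias$hills
  if (nrow(h) == 0) return(rep(0, length(cv)))
  vapply(cv, function(s)
    sum(h$height * exp(-(s - h$center)^2 / (2 * h$width^2))), numeric(1))
}

#' Analytic derivative of the bias potential
#'
#' @inheritParams bias_potential
#' @return dV_bias/dcv at `cv`.
#' @export
bias_gradient <- function(bias, cv) {
  h <- bias$hills
  if (nrow(h) == 0) return(rep(0, length(cv)))
  vapply(cv, function(s)
    sum(h$height * exp(-(s - h$center)^2 / (2 * h$width^2)) *
          (-(s - h$center) / h$width^2)), numeric(1))
}

#' Run metadynamics on a landscape
#'
#' Integrates the same overdamped Langevin dynamics as [run_langevin()] under
#' the potential `U + V_bias(cv)`, depositing one Gaussian hill every
#' `deposition_interval` steps at the instantaneous CV value.
#'
#' @inheritParams run_langevin
#' @param params A [hill_params()].
#' @param anchor_set CV anchors (default: the deep-pocket center, i.e. the
#'   binding-site centroid analogue).
#' @return A list with elements `trajectory` and `bias` (a `bias_state`
#'   holding the deposited hills).
#' @export
run_metad <- function(landscape, config, params = hill_params(),
                      anchor_set = NULL, start = docking_pose(landscape),
                      seed = 1) {
  if (is.null(anchor_set)) anchor_set <- landscape$spec$deep_pocket_center
  if (config$n_steps %% params$deposition_interval != 0)
    stop("`deposition_interval` must divide `n_steps`")
  bias0 <- bias_state(anchor_set, params)
  res <- run_engine(landscape, config, start, seed, bias = bias0)
  bias0$hills <- data.frame(time = res$hills$time, center = res$hills$center,
                            height = res$hills$height,
                            width = rep(params$width, nrow(res$hills)))
  list(trajectory = res$trajectory, bias = bias0)
}

#' Reconstruct a free-energy profile from the accumulated bias
#'
#' Non-tempered runs: `f = -V_bias`; well-tempered runs:
#' `f = -(bias_factor / (bias_factor - 1)) V_bias`. The profile is shifted so
#' that its minimum is zero ("minimum-anchored" convention). An empty bias
#' yields a flat zero profile.
#'
#' Because the instantaneous bias fluctuates around the converging profile,
#' the estimate can optionally be time-averaged over the tail of the
#' deposition history (`average_tail`), the usual variance-reduction choice
#' for well-tempered runs; `average_tail = 0` uses the final bias only.
#'
#' @param bias A [bias_state()].
#' @param grid Increasing numeric vector of CV values.
#' @param tempered,bias_factor Override the bias state's own hill parameters
#'   (rarely needed).
#' @param kBT Thermal energy (reserved; the tempered rescaling is
#'   temperature-free in these reduced units).
#' @param average_tail Fraction of the deposition history (from the end)
#'   over which the profile is averaged (default 0.5).
#' @return An object of class `free_energy_profile`: data frame `grid`, `f`,
#'   attribute `offset_convention`.
#' @export
estimate_free_energy <- function(bias, grid, tempered = bias$params$tempered,
                                 bias_factor = bias$params$bias_factor,
                                 kBT = 1, average_tail = 0.5) {
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be non-empty and increasing")
  if (average_tail < 0 || average_tail >= 1)
    stop("`average_tail` must be in [0, 1)")
  h <- bias$hills
  n <- nrow(h)
  if (n == 0) {
    v <- rep(0, length(grid))
  } else {
    # checkpoint-averaged bias: hill i enters the profile at checkpoint i,
    # so averaging checkpoints k0..n weights hill i by its dwell fraction
    k0 <- max(1, n - max(1, floor(average_tail * n)) + 1)
    w <- (n - pmax(seq_len(n), k0) + 1) / (n - k0 + 1)
    v <- vapply(grid, function(s)
      sum(w * h$height * exp(-(s - h$center)^2 / (2 * h$width^2))),
      numeric(1))
  }
  f <- if (tempered) -(bias_factor / (bias_factor - 1)) * v else -v
  f <- f - min(f)
  structure(data.frame(grid = grid, f = f),
            offset_convention = "minimum-anchored",
            class = c("free_energy_profile", "data.frame"))
}

#' Free-energy difference between two basins of a profile
#'
#' Reports `f` at the profile minimum inside basin B minus that inside basin
#' A, each basin given as a CV interval.
#'
#' @param profile A [estimate_free_energy()] result.
#' @param basin_a,basin_b Length-2 numeric CV intervals.
#' @return Scalar free-energy difference (B minus A), in kBT.
#' @export
profile_delta_f <- function(profile, basin_a, basin_b) {
  fa <- min(profile$f[profile$grid >= basin_a[1] & profile$grid <= basin_a[2]])
  fb <- min(profile$f[profile$grid >= basin_b[1] & profile$grid <= basin_b[2]])
  fb - fa
}

#' Boltzmann-quadrature free-energy difference between two basins
#'
#' Independent equilibrium reference for 1-D landscapes: numerically
#' integrates the Boltzmann weight of the scalar potential over each basin
#' (folding the CV's sign degeneracy, since the distance CV maps x and -x to
#' the same value) and returns `-kBT log(Z_B / Z_A)`.
#'
#' @param landscape A 1-D [build_landscape()] result.
#' @param basin_a,basin_b CV intervals (non-negative).
#' @param anchor CV anchor coordinate (default: deep pocket center).
#' @param kBT Thermal energy.
#' @param n Quadrature points per basin.
#' @return Scalar free-energy difference (B minus A), in kBT.
#' @export
quadrature_delta_f <- function(landscape, basin_a, basin_b,
                               anchor = landscape$spec$deep_pocket_center,
                               kBT = 1, n = 20001) {
  if (landscape$spec$dimensionality != 1)
    stop("quadrature reference implemented for 1-D landscapes")
  zb <- function(basin) {
    s <- seq(basin[1], basin[2], length.out = n)
    u_plus <- landscape_potential(landscape, matrix(anchor + s, ncol = 1))
    u_minus <- landscape_potential(landscape, matrix(anchor - s, ncol = 1))
    q <- exp(-u_plus / kBT) + exp(-u_minus / kBT)
    sum((q[-1] + q[-n]) / 2) * (s[2] - s[1])
  }
  -kBT * log(zb(basin_b) / zb(basin_a))
}
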