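#' Configure the overdamped Langevin integrator
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics with a rigid
#' bond projection after each step. Reduced units: energy in kBT, time in
#' simulation units.
#'
#' @param temperature Thermal energy kBT (>= 0; 0 gives deterministic
#'   gradient descent).
#' @param friction Friction coefficient (> 0).
#' @param timestep Integration timestep (> 0).
#' @param n_steps Number of integration steps.
#' @param save_stride Save a frame every `save_stride` steps (the initial
#'   state is always saved, so `n_steps / save_stride + 1` frames result).
#' @return An object of class `langevin_config`.
#' @export
langevin_config <- function(temperature = 1, friction = 1, timestep = 0.005,
                            n_steps = 200000, save_stride = 200) {
  if (timestep <= 0) stop("`timestep` must be positive")
  if (friction <= 0) stop("`friction` must be positive")
  if (temperature < 0) stop("`temperature` must be non-negative")
  if (n_steps < 1 || save_stride < 1 || n_steps %% save_stride != 0)
    stop("`save_stride` must divide `n_steps`")
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride)),
            class = "langevin_config")
}

#' Run unbiased Langevin dynamics of a ligand on a landscape
#'
#' @param landscape A [build_landscape()] result.
#' @param config A [langevin_config()].
#' @param start A [ligand()] giving the initial state. A zero bond length
#'   selects point-ligand mode (a single probe; useful for 1-D benchmarks).
#' @param seed Integer seed; identical `(landscape, config, start, seed)`
#'   give bit-identical trajectories.
#' @return A `trajectory` object: `times`, coordinate matrices `cf3` and
#'   `o1` (one frame per row), `bond_length`, `seed` and `config_hash`.
#' @export
run_langevin <- function(landscape, config, start, seed) {
  run_engine(landscape, config, start, seed, bias = NULL)$trajectory
}

# shared driver for run_langevin / run_metad
run_engine <- function(landscape, config, start, seed, bias) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(config, "langevin_config"), inherits(start, "ligand"))
  d <- landscape$spec$dimensionality
  if (length(start$probe_cf3) != d) stop("start ligand dimension mismatch")
  do_metad <- !is.null(bias)
  seed <- as.integer(seed)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  res <- cpp_run_dynamics(
    landscape$wells$center, landscape$wells$depth, landscape$wells$width,
    as.integer(landscape$wells$bead),
    landscape$spec$confinement_radius, landscape$spec$wall_k,
    start$probe_cf3, start$probe_o1, start$bond_length,
    config$temperature, config$friction, config$timestep,
    config$n_steps, config$save_stride,
    do_metad,
    if (do_metad) bias$anchor_centroid else numeric(d),
    if (do_metad) bias$params$initial_height else 0,
    if (do_metad) bias$params$width else 1,
    if (do_metad) bias$params$deposition_interval else 1L,
    if (do_metad) bias$params$tempered else FALSE,
    if (do_metad) bias$params$bias_factor else 2)

  traj <- structure(
    list(times = res$times, cf3 = res$cf3, o1 = res$o1,
         bond_length = start$bond_length, seed = seed,
         config_hash = config_hash(list(landscape$spec, config,
                                        start[c("probe_cf3", "probe_o1")],
                                        if (do_metad) bias$params))),
    class = "trajectory")
  list(trajectory = traj,
       hills = data.frame(time = res$hill_time, center = res$hill_center,
                          height = res$hill_height))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$cf3), " frames, ",
      ncol(x$cf3), "D, bond ", format(x$bond_length),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `trajectory` object.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) nrow(trajectory$cf3)

#' Extract one frame of a trajectory as a ligand
#' @param trajectory A `trajectory` object.
#' @param i Frame index (1-based).
#' @return A [ligand()].
#' @export
trajectory_frame <- function(trajectory, i) {
  stopifnot(i >= 1, i <= n_frames(trajectory))
  ligand(trajectory$cf3[i, ], trajectory$o1[i, ])
}

# small stable polynomial hash of an R object's serialized bytes, hex string
# (exact in double arithmetic: intermediate values stay below 2^53)
config_hash <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Derive a per-stage substream seed from a global seed
#'
#' Matched WT/mutant comparisons need coupled noise: the same stage index
#' under the same global seed yields the same substream seed. Kept below
#' 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Non-negative integer stage index.
#' @return Integer seed.
#' @export
substream_seed <- function(seed, stage) {
  as.integer((as.double(seed %% 65011) * 33013 + stage * 7907 + 17) %% 2147483647)
}
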