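# shared fixtures: small landscapes and configs used across test files

# 1-D double well used for free-energy benchmarks: deep well at x = 0,
# metastable well at x = 10, small flat bulk, point ligand
double_well_1d <- function() {
  build_landscape(landscape_spec(
    dimensionality = 1, deep_pocket_center = 0,
    met_anchor = 6, met_pocket_offset = 4,
    bulk_radius = 15, confinement_radius = 16))
}

# CV anchor placed away from the deep well so both basins sit in the
# interior of CV space (distance CVs have a reflective boundary at zero)
dw_anchor <- -3
dw_basin_a <- c(1, 6)   # deep well at cv = 3
dw_basin_b <- c(10, 16) # met well at cv = 13

quick_config <- function(n_steps = 20000, save_stride = 100) {
  langevin_config(n_steps = n_steps, save_stride = save_stride)
}

# deterministic synthetic trajectory from explicit coordinates
manual_trajectory <- function(cf3, o1, times = seq_len(nrow(cf3)) - 1) {
  structure(list(times = times, cf3 = cf3, o1 = o1,
                 bond_length = sqrt(sum((cf3[1, ] - o1[1, ])^2)),
                 seed = 0L, config_hash = "manual"),
            class = "trajectory")
}
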