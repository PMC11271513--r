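#' Default end-to-end pipeline configuration
#'
#' A nested configuration for the wild-type versus gatekeeper-mutant
#' comparison pipeline: simulate metadynamics runs on both landscapes with
#' matched seeds, post-process trajectories (RMSD, dissociation tally, gate
#' occupancy), score differential residue contacts (Qb), reconstruct the
#' free-energy profile, and fit the simulated pharmacology assays.
#'
#' @param seed Global seed; per-stage substreams are derived from it.
#' @param n_runs Metadynamics runs per genotype.
#' @param n_steps,save_stride Integrator settings per run.
#' @return A `pipeline_config` (nested list).
#' @export
default_pipeline_config <- function(seed = 1, n_runs = 5, n_steps = 200000,
                                    save_stride = 200) {
  structure(list(
    seed = as.integer(seed),
    n_runs = as.integer(n_runs),
    landscape = list(wt = list(genotype = "WT"),
                     mutant = list(genotype = "M124V")),
    simulation = list(temperature = 1, friction = 1, timestep = 0.005,
                      n_steps = as.integer(n_steps),
                      save_stride = as.integer(save_stride)),
    metad = list(initial_height = 0.3, width = 0.5,
                 deposition_interval = 500, tempered = TRUE,
                 bias_factor = 10),
    analysis = list(threshold = 30, persistence = 1, snapshot_stride = 1,
                    contact_cutoff = 4.5),
    kinetics = list(washout_t_half = 9.41, washout_times = c(0, 1, 3, 6, 24),
                    pk_t_half = 6.65, pk_c0 = 1000,
                    pk_times = c(0.5, 1, 2, 4, 8, 24),
                    ic50 = 6.4, hill = 1)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected (strict mode) and all nested specifications are
#' validated; missing keys fall back to the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(default_pipeline_config(), user, prefix = NULL)
}

#' Save a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

merge_config <- function(defaults, user, prefix) {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    full <- paste(c(prefix, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      value <- user[[key]]
      if (length(value) > 0 && is.numeric(defaults[[key]]) &&
          !is.numeric(value))
        stop("type mismatch at configuration key: ", full)
      defaults[[key]] <- value
    }
  }
  defaults
}

validate_pipeline_config <- function(config) {
  if (config$n_runs < 1) stop("`n_runs` must be >= 1")
  if (config$metad$initial_height <= 0)
    stop("invalid configuration: metad.initial_height must be positive")
  if (config$analysis$threshold <= 0)
    stop("invalid configuration: analysis.threshold must be positive")
  invisible(config)
}

#' Run the wild-type versus mutant comparison pipeline
#'
#' Per genotype: metadynamics runs with matched per-run seeds, ligand RMSD
#' and the dissociation tally, snapshot gate classification with occupancy
#' statistics, and the free-energy profile from the final bias. Across
#' genotypes: the Qb table comparing contacts of a ligand on the wild-type
#' landscape against one on a landscape without the Met well. Simulated
#' washout, pharmacokinetic and concentration-response assays are generated
#' and refit. Fully reproducible from `(config, seed)`.
#'
#' @param config A `pipeline_config`.
#' @return A `pipeline_bundle` list: per-genotype results, the Qb table,
#'   kinetics fits, and a `summary` list collating the headline numbers.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  validate_pipeline_config(config)
  sim <- config$simulation
  lconf <- langevin_config(sim$temperature, sim$friction, sim$timestep,
                           sim$n_steps, sim$save_stride)
  hp <- hill_params(config$metad$initial_height, config$metad$width,
                    config$metad$deposition_interval, config$metad$tempered,
                    config$metad$bias_factor)
  criterion <- dissociation_criterion(config$analysis$threshold,
                                      config$analysis$persistence)

  genotype_stage <- function(genotype, stage_offset) {
    spec <- landscape_spec(genotype = genotype)
    land <- build_landscape(spec)
    pose <- docking_pose(land)
    runs <- lapply(seq_len(config$n_runs), function(i) {
      run_metad(land, lconf, hp, start = pose,
                seed = substream_seed(config$seed, stage_offset + i))
    })
    rmsd <- lapply(runs, function(r) ligand_rmsd(r$trajectory, pose))
    events <- vapply(rmsd, detect_dissociation, integer(1),
                     criterion = criterion)
    kofn <- count_dissociations(events)
    labels <- do.call(rbind, lapply(runs, function(r) {
      snaps <- subsample_snapshots(r$trajectory,
                                   stride = config$analysis$snapshot_stride)
      classify_gates(pair_distances(snaps, spec$met_anchor))
    }))
    stats <- gate_occupancy_stats(labels)
    profile <- estimate_free_energy(runs[[length(runs)]]$bias,
                                    grid = seq(0, spec$bulk_radius + 5,
                                               by = 0.1))
    list(landscape = land, runs = runs, rmsd = rmsd, events = events,
         k_of_n = kofn, labels = labels, gate_stats = stats,
         profile = profile)
  }

  wt <- genotype_stage("WT", 100)
  mut <- genotype_stage("M124V", 200)

  qb <- pipeline_qb(config, wt)
  kin <- pipeline_kinetics(config)

  summary <- list(
    seed = config$seed,
    dissociations = list(wt = wt$k_of_n, mutant = mut$k_of_n),
    gate_frequencies = list(
      wt = as.list(wt$gate_stats$frequencies),
      mutant = as.list(mut$gate_stats$frequencies)),
    gate_medians_wt = wt$gate_stats$medians[c("gateA_deep", "gateB_met")],
    top_qb_residue = rank_residues(qb, 1),
    kinetics = kin$summary)

  structure(list(wt = wt, mutant = mut, qb = qb, kinetics = kin,
                 summary = summary, config = config),
            class = "pipeline_bundle")
}

# Qb stage: ligand A snapshots from the WT landscape vs ligand B from a
# landscape with the Met well effectively removed; anchors are the
# gatekeeper analogue plus deep-pocket reference residues.
pipeline_qb <- function(config, wt_stage) {
  spec <- wt_stage$landscape$spec
  anchors <- rbind(Met124 = spec$met_anchor,
                   deep1 = spec$deep_pocket_center + c(2, rep(0, spec$dimensionality - 1)),
                   deep2 = spec$deep_pocket_center - c(2, rep(0, spec$dimensionality - 1)))
  cutoff <- config$analysis$contact_cutoff
  snaps_a <- lapply(wt_stage$runs, function(r)
    subsample_snapshots(r$trajectory, stride = config$analysis$snapshot_stride))
  bits_a <- do.call(rbind, lapply(snaps_a, function(s)
    unclass(compute_fingerprints(s, anchors, cutoff, "ligandA"))))

  nomet <- build_landscape(landscape_spec(genotype = "M124V",
                                          met_scale_m124v = 0))
  sim <- config$simulation
  lconf <- langevin_config(sim$temperature, sim$friction, sim$timestep,
                           sim$n_steps, sim$save_stride)
  hp <- hill_params(config$metad$initial_height, config$metad$width,
                    config$metad$deposition_interval, config$metad$tempered,
                    config$metad$bias_factor)
  bits_b <- do.call(rbind, lapply(seq_len(config$n_runs), function(i) {
    r <- run_metad(nomet, lconf, hp, start = docking_pose(nomet),
                   seed = substream_seed(config$seed, 300 + i))
    s <- subsample_snapshots(r$trajectory,
                             stride = config$analysis$snapshot_stride)
    unclass(compute_fingerprints(s, anchors, cutoff, "ligandB"))
  }))
  qb_score(tally_bits(fingerprint_matrix(bits_a, "ligandA")),
           tally_bits(fingerprint_matrix(bits_b, "ligandB")))
}

pipeline_kinetics <- function(config) {
  kc <- config$kinetics
  washout <- generate_washout_dataset(kc$washout_t_half, kc$washout_times,
                                      seed = substream_seed(config$seed, 401))
  pk <- generate_pk_dataset(kc$pk_c0, kc$pk_t_half, kc$pk_times,
                            seed = substream_seed(config$seed, 402))
  dr <- generate_dose_response(kc$ic50, kc$hill,
                               seed = substream_seed(config$seed, 403))
  fit_w <- fit_one_phase_decay(washout$x, washout$y)
  fit_pk <- fit_log_linear_pk(pk$x, pk$y)
  fit_dr <- fit_4pl(dr$x, dr$y)
  list(washout = list(data = washout, fit = fit_w),
       pk = list(data = pk, fit = fit_pk),
       dose_response = list(data = dr, fit = fit_dr),
       summary = list(washout_t_half = fit_w$t_half,
                      pk_t_half = fit_pk$t_half,
                      ic50 = fit_dr$ic50))
}

#' Write / read a pipeline result bundle
#'
#' Writes the tabular artifacts (per-genotype trajectories as CSV, hills,
#' pose labels, the Qb table) plus a machine-readable `summary.json`; the
#' bundle is regenerable bit-identically from `(config, seed)`.
#'
#' @param bundle A [run_pipeline()] result.
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_results <- function(bundle, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (g in c("wt", "mutant")) {
    stage <- bundle[[g]]
    for (i in seq_along(stage$runs)) {
      write_trajectory(stage$runs[[i]]$trajectory,
                       file.path(directory, sprintf("%s_run%02d.csv", g, i)))
      write_hills(stage$runs[[i]]$bias,
                  file.path(directory, sprintf("%s_hills%02d.csv", g, i)))
    }
    write_csv_full(stage$labels,
                   file.path(directory, paste0(g, "_labels.csv")))
    write_profile(stage$profile,
                  file.path(directory, paste0(g, "_profile.csv")))
  }
  write_csv_full(bundle$qb, file.path(directory, "qb_table.csv"))
  jsonlite::write_json(bundle$summary, file.path(directory, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_config(bundle$config, file.path(directory, "config.yaml"))
  invisible(directory)
}

#' @rdname write_results
#' @export
read_results <- function(directory) {
  sfile <- file.path(directory, "summary.json")
  cfile <- file.path(directory, "config.yaml")
  missing <- c(sfile, cfile)[!file.exists(c(sfile, cfile))]
  if (length(missing) > 0)
    stop("missing expected files: ", paste(missing, collapse = ", "))
  list(summary = jsonlite::read_json(sfile, simplifyVector = TRUE),
       config = load_config(cfile),
       qb = utils::read.csv(file.path(directory, "qb_table.csv")))
}
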