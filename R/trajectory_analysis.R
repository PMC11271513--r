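#' Ligand RMSD series relative to a reference pose
#'
#' Per frame, the root mean square deviation of the two probe beads from the
#' reference pose, computed in the fixed receptor frame (no superposition:
#' the toy receptor is rigid, so protein alignment is the identity).
#'
#' @param trajectory A `trajectory`.
#' @param reference A [ligand()] reference pose (e.g. the docking pose).
#' @return An `rmsd_series`: data frame `time`, `rmsd` with the reference
#'   stored as an attribute.
#' @export
ligand_rmsd <- function(trajectory, reference) {
  stopifnot(inherits(reference, "ligand"))
  if (ncol(trajectory$cf3) != length(reference$probe_cf3))
    stop("reference probe dimension mismatch")
  d <- ncol(trajectory$cf3)
  d_cf3 <- rowSums((trajectory$cf3 -
                      matrix(reference$probe_cf3, nrow(trajectory$cf3), d,
                             byrow = TRUE))^2)
  d_o1 <- rowSums((trajectory$o1 -
                     matrix(reference$probe_o1, nrow(trajectory$o1), d,
                            byrow = TRUE))^2)
  structure(data.frame(time = trajectory$times,
                       rmsd = sqrt((d_cf3 + d_o1) / 2)),
            reference = reference,
            class = c("rmsd_series", "data.frame"))
}

#' Dissociation criterion
#'
#' The conventional threshold rule: the ligand counts as dissociated once its
#' RMSD from the reference pose exceeds `threshold` for `persistence`
#' consecutive frames.
#'
#' @param threshold RMSD threshold (length units, > 0; default 30, the
#'   standard cutoff mirroring the 30 A rule on all-atom trajectories).
#' @param persistence Consecutive frames required above threshold.
#' @return An object of class `dissociation_criterion`.
#' @export
dissociation_criterion <- function(threshold = 30, persistence = 1) {
  if (threshold <= 0) stop("`threshold` must be positive")
  if (persistence < 1) stop("`persistence` must be >= 1")
  structure(list(threshold = threshold, persistence = as.integer(persistence)),
            class = "dissociation_criterion")
}

#' Detect the first dissociation event in an RMSD series
#'
#' @param series An [ligand_rmsd()] result (or any data frame with an `rmsd`
#'   column).
#' @param criterion A [dissociation_criterion()].
#' @return The 1-based index of the first frame at which the RMSD has been
#'   above threshold for `persistence` consecutive frames, or `NA_integer_`
#'   if no event occurs.
#' @export
detect_dissociation <- function(series, criterion = dissociation_criterion()) {
  rmsd <- series$rmsd
  if (length(rmsd) == 0) stop("empty RMSD series")
  above <- rmsd > criterion$threshold
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= criterion$persistence) return(i - criterion$persistence + 1L)
  }
  NA_integer_
}

#' Tally dissociation events across runs
#'
#' @param run_events Vector or list of per-run event indices
#'   (`NA` = no event), as returned by [detect_dissociation()].
#' @return List `k` (runs with an event) and `n` (total runs).
#' @export
count_dissociations <- function(run_events) {
  ev <- unlist(lapply(run_events, function(e) if (is.null(e)) NA_integer_ else e))
  if (length(ev) == 0) stop("`run_events` must be non-empty")
  list(k = sum(!is.na(ev)), n = length(ev))
}

#' Per-frame distances from the gatekeeper anchor to both probes
#'
#' The toy analogue of measuring, in every snapshot, the distance from the
#' gatekeeper methionine gamma-carbon to the CF3-group carbon and to the
#' carboxylic-acid O1 oxygen of the ligand.
#'
#' @param trajectory A `trajectory`.
#' @param met_anchor Anchor coordinates (default: taken from the trajectory's
#'   landscape is not stored, so pass explicitly).
#' @return Data frame `time`, `d_cf3`, `d_o1`.
#' @export
pair_distances <- function(trajectory, met_anchor) {
  d <- ncol(trajectory$cf3)
  if (length(met_anchor) != d) stop("anchor dimension mismatch")
  a <- matrix(met_anchor, nrow(trajectory$cf3), d, byrow = TRUE)
  data.frame(time = trajectory$times,
             d_cf3 = sqrt(rowSums((trajectory$cf3 - a)^2)),
             d_o1 = sqrt(rowSums((trajectory$o1 - a)^2)))
}

#' Gate classification windows
#'
#' Rectangular windows in the (gatekeeper-CF3 distance, gatekeeper-O1
#' distance) plane defining the two metastable pose families: gate A (the
#' deep, near-docking pose) and gate B (the Met-pocket pose, distal ring
#' close to the gatekeeper). Intervals are closed on the lower bound and open
#' on the upper. Defaults are oriented so that the canonical gate medians
#' (9.42, 9.97) and (6.27, 12.95) fall inside gate A and gate B respectively.
#'
#' @param gateA_cf3,gateA_o1 Gate-A intervals for the CF3 and O1 distances.
#' @param gateB_cf3,gateB_o1 Gate-B intervals.
#' @param unbound_cutoff Both distances at or above this value label the
#'   frame unbound.
#' @return An object of class `gate_windows`.
#' @export
gate_windows <- function(gateA_cf3 = c(7.8, 12.5), gateA_o1 = c(7.5, 12.5),
                         gateB_cf3 = c(2.5, 7.8), gateB_o1 = c(10, 15),
                         unbound_cutoff = 25) {
  for (iv in list(gateA_cf3, gateA_o1, gateB_cf3, gateB_o1))
    if (length(iv) != 2 || iv[1] >= iv[2])
      stop("window intervals must be increasing length-2 vectors")
  overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]
  if (overlap(gateA_cf3, gateB_cf3) && overlap(gateA_o1, gateB_o1))
    stop("gate A and gate B rectangles must be disjoint")
  structure(list(gateA_cf3 = gateA_cf3, gateA_o1 = gateA_o1,
                 gateB_cf3 = gateB_cf3, gateB_o1 = gateB_o1,
                 unbound_cutoff = unbound_cutoff),
            class = "gate_windows")
}

#' Classify snapshots into pose gates
#'
#' Exhaustive, exclusive labelling of each snapshot: `gateA_deep` if the
#' distance pair falls in the gate-A rectangle, `gateB_met` in the gate-B
#' rectangle, `unbound` if both distances are at or beyond the unbound
#' cutoff, `other_bound` otherwise.
#'
#' @param distance_pairs A [pair_distances()] result (columns `d_cf3`,
#'   `d_o1`).
#' @param windows A [gate_windows()].
#' @return A `pose_labels` data frame: the input plus a `label` factor.
#' @export
classify_gates <- function(distance_pairs, windows = gate_windows()) {
  stopifnot(inherits(windows, "gate_windows"))
  inside <- function(x, iv) x >= iv[1] & x < iv[2]
  in_a <- inside(distance_pairs$d_cf3, windows$gateA_cf3) &
    inside(distance_pairs$d_o1, windows$gateA_o1)
  in_b <- inside(distance_pairs$d_cf3, windows$gateB_cf3) &
    inside(distance_pairs$d_o1, windows$gateB_o1)
  unb <- distance_pairs$d_cf3 >= windows$unbound_cutoff &
    distance_pairs$d_o1 >= windows$unbound_cutoff
  label <- rep("other_bound", nrow(distance_pairs))
  label[unb] <- "unbound"
  label[in_b] <- "gateB_met"
  label[in_a] <- "gateA_deep"
  out <- distance_pairs
  out$label <- factor(label, levels = c("gateA_deep", "gateB_met",
                                        "other_bound", "unbound"))
  class(out) <- c("pose_labels", "data.frame")
  out
}

#' Subsample equally spaced snapshots from a trajectory
#'
#' Frames `1, 1 + stride, 1 + 2 stride, ...` (the first frame is always
#' included), emulating the convention of picking snapshots at fixed time
#' intervals from each run.
#'
#' @param trajectory A `trajectory`.
#' @param stride Keep every `stride`-th frame (>= 1, <= frame count).
#' @param target_count Alternatively, a desired snapshot count; the stride is
#'   `floor(n / target_count)`.
#' @return A `trajectory` containing the selected frames.
#' @export
subsample_snapshots <- function(trajectory, stride = NULL,
                                target_count = NULL) {
  n <- n_frames(trajectory)
  if (is.null(stride)) {
    if (is.null(target_count)) stop("give `stride` or `target_count`")
    stride <- max(1L, n %/% as.integer(target_count))
  }
  if (stride < 1 || stride > n) stop("`stride` must be in [1, frame count]")
  idx <- seq(1L, n, by = as.integer(stride))
  out <- trajectory
  out$times <- trajectory$times[idx]
  out$cf3 <- trajectory$cf3[idx, , drop = FALSE]
  out$o1 <- trajectory$o1[idx, , drop = FALSE]
  out
}

#' Gate occupancy frequencies and per-gate median distances
#'
#' @param labels A [classify_gates()] result.
#' @return List `frequencies` (named, sums to 1 over the four labels) and
#'   `medians` (per gate label, the medians of `d_cf3` and `d_o1` over the
#'   frames carrying that label; the usual midpoint convention averages the
#'   central pair for even counts).
#' @export
gate_occupancy_stats <- function(labels) {
  if (nrow(labels) == 0) stop("empty pose label series")
  freq <- table(labels$label) / nrow(labels)
  meds <- lapply(levels(labels$label), function(lv) {
    sel <- labels$label == lv
    if (!any(sel)) return(c(d_cf3 = NA_real_, d_o1 = NA_real_))
    c(d_cf3 = stats::median(labels$d_cf3[sel]),
      d_o1 = stats::median(labels$d_o1[sel]))
  })
  names(meds) <- levels(labels$label)
  list(frequencies = c(freq), medians = meds)
}

#' Two-group pose clustering on the pairwise frame-RMSD matrix
#'
#' Partitions snapshots by k-medoids (PAM) on the matrix of pairwise ligand
#' RMSDs between frames, the standard way of splitting a snapshot pool into
#' pose families (e.g. deep pocket vs Met pocket).
#'
#' @param snapshots A `trajectory` (typically subsampled).
#' @param k Number of clusters (default 2).
#' @param seed Integer seed (PAM with BUILD initialization is deterministic;
#'   the seed is fixed regardless so the contract is explicit).
#' @return List `assignments` (integer vector), `medoids` (frame indices),
#'   `means` (per cluster, mean CF3 and O1 positions), `dissimilarity`
#'   (the pairwise RMSD `dist`).
#' @export
cluster_poses <- function(snapshots, k = 2, seed = 1) {
  n <- n_frames(snapshots)
  if (n < k) stop("fewer snapshots than clusters")
  flat <- cbind(snapshots$cf3, snapshots$o1)
  # RMSD between two frames = euclidean distance of concatenated coords
  # divided by sqrt(number of probes)
  dmat <- stats::dist(flat) / sqrt(2)
  if (n == k) {
    assignments <- seq_len(n) # singletons: nothing to optimize
    medoids <- seq_len(n)
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    fit <- cluster::pam(dmat, k = k, diss = TRUE, cluster.only = FALSE)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    assignments <- fit$clustering
    medoids <- fit$id.med
  }
  means <- lapply(seq_len(k), function(g) {
    sel <- assignments == g
    list(cf3 = colMeans(snapshots$cf3[sel, , drop = FALSE]),
         o1 = colMeans(snapshots$o1[sel, , drop = FALSE]))
  })
  list(assignments = assignments, medoids = medoids, means = means,
       dissimilarity = dmat)
}
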