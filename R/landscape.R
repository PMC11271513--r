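#' Specify a coarse-grained two-pocket receptor landscape
#'
#' The landscape emulates the dissociation geometry of a slow-dissociating
#' antagonist bound to a GPCR: a primary "deep pocket" well at the docking
#' position and a secondary metastable "Met pocket" well next to a gatekeeper
#' methionine analogue, situated on the exit path toward bulk solvent.
#' Energies are in units of kBT and lengths in reduced, angstrom-like units,
#' so the conventional 30-unit dissociation threshold plays the role of the
#' 30 A rule used on all-atom trajectories.
#'
#' The Met-pocket well acts on the CF3 probe bead only (the hydrophobic
#' distal-ring contact that the gatekeeper methionine makes), while the deep
#' pocket well attracts both probe beads. The `M124V` genotype rescales the
#' Met-pocket depth by `met_scale_m124v`, modelling the valine mutant's
#' reduced - but not abolished - gatekeeper interaction.
#'
#' @param dimensionality Number of spatial dimensions (1 or 2; default 2).
#' @param deep_pocket_center Coordinates of the deep-pocket well minimum.
#' @param deep_pocket_depth Depth of the deep-pocket well per probe bead
#'   (kBT, > 0).
#' @param deep_pocket_width Gaussian width of the deep pocket (length units).
#' @param met_anchor Coordinates of the gatekeeper residue analogue (the
#'   reference point for gate distance measurements).
#' @param met_pocket_depth Depth of the Met-pocket well (kBT, > 0) before any
#'   genotype scaling.
#' @param met_pocket_width Gaussian width of the Met pocket.
#' @param met_pocket_center Coordinates of the Met-pocket well minimum.
#'   Default: `met_pocket_offset` length units beyond `met_anchor` along the
#'   axis from the deep pocket through the anchor (the exit path).
#' @param met_pocket_offset Distance from `met_anchor` to the default
#'   Met-pocket well center.
#' @param genotype `"WT"` or `"M124V"`.
#' @param met_scale_m124v Factor in \[0, 0.3\] applied to `met_pocket_depth`
#'   for the `M124V` genotype.
#' @param bulk_radius Radius beyond which the potential is flat (bulk).
#' @param confinement_radius Radius of the soft harmonic confinement wall.
#' @param wall_k Spring constant of the confinement wall (kBT / length^2).
#'
#' @return An object of class `landscape_spec`.
#' @seealso [build_landscape()]
#' @export
landscape_spec <- function(dimensionality = 2,
                           deep_pocket_center = rep(0, dimensionality),
                           deep_pocket_depth = 6,
                           deep_pocket_width = 3.5,
                           met_anchor = c(8, rep(0, dimensionality - 1)),
                           met_pocket_depth = 7,
                           met_pocket_width = 3,
                           met_pocket_center = NULL,
                           met_pocket_offset = 6,
                           genotype = c("WT", "M124V"),
                           met_scale_m124v = 0.1,
                           bulk_radius = 30,
                           confinement_radius = 34,
                           wall_k = 5) {
  genotype <- match.arg(genotype)
  stopifnot(dimensionality >= 1)
  if (deep_pocket_depth <= 0 || met_pocket_depth <= 0)
    stop("pocket depths must be positive")
  if (deep_pocket_width <= 0 || met_pocket_width <= 0)
    stop("pocket widths must be positive")
  if (length(deep_pocket_center) != dimensionality ||
      length(met_anchor) != dimensionality)
    stop("coordinate dimensions do not match `dimensionality`")
  if (met_scale_m124v < 0 || met_scale_m124v > 0.3)
    stop("`met_scale_m124v` must lie in [0, 0.3]")
  if (bulk_radius <= sqrt(sum((deep_pocket_center - met_anchor)^2)))
    stop("`bulk_radius` must exceed the deep-pocket / met-anchor separation")
  if (confinement_radius < bulk_radius)
    stop("`confinement_radius` must be >= `bulk_radius`")

  if (is.null(met_pocket_center)) {
    axis <- met_anchor - deep_pocket_center
    nrm <- sqrt(sum(axis^2))
    if (nrm < 1e-12) stop("met_anchor coincides with the deep pocket center")
    met_pocket_center <- met_anchor + met_pocket_offset * axis / nrm
  }
  if (length(met_pocket_center) != dimensionality)
    stop("`met_pocket_center` dimension mismatch")

  structure(
    list(dimensionality = dimensionality,
         deep_pocket_center = as.numeric(deep_pocket_center),
         deep_pocket_depth = deep_pocket_depth,
         deep_pocket_width = deep_pocket_width,
         met_anchor = as.numeric(met_anchor),
         met_pocket_depth = met_pocket_depth,
         met_pocket_width = met_pocket_width,
         met_pocket_center = as.numeric(met_pocket_center),
         genotype = genotype,
         met_scale_m124v = met_scale_m124v,
         bulk_radius = bulk_radius,
         confinement_radius = confinement_radius,
         wall_k = wall_k),
    class = "landscape_spec")
}

#' Build a potential-energy landscape from a specification
#'
#' Assembles the Gaussian wells (deep pocket on both beads, Met pocket on the
#' CF3 bead) and the confinement wall into a `landscape` object that the
#' dynamics engine and the scalar potential evaluators consume. For the
#' `M124V` genotype the Met-pocket depth is rescaled by the spec's
#' `met_scale_m124v`.
#'
#' @param spec A [landscape_spec()].
#' @return An object of class `landscape` with elements `spec` and `wells`
#'   (data frame of well centers, depths, widths and bead selectors).
#' @export
build_landscape <- function(spec) {
  if (!inherits(spec, "landscape_spec")) stop("`spec` must be a landscape_spec")
  met_depth <- spec$met_pocket_depth *
    if (spec$genotype == "M124V") spec$met_scale_m124v else 1
  centers <- rbind(spec$deep_pocket_center, spec$met_pocket_center)
  wells <- list(center = centers,
                depth = c(spec$deep_pocket_depth, met_depth),
                width = c(spec$deep_pocket_width, spec$met_pocket_width),
                bead = c(0L, 1L)) # 0 = all beads, 1 = CF3 only
  structure(list(spec = spec, wells = wells), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  s <- x$spec
  cat("<landscape> ", s$genotype, ", ", s$dimensionality, "D\n", sep = "")
  cat("  deep pocket: depth", format(x$wells$depth[1]), "kBT at (",
      paste(format(s$deep_pocket_center), collapse = ", "), ")\n")
  cat("  Met pocket:  depth", format(x$wells$depth[2]), "kBT at (",
      paste(format(s$met_pocket_center), collapse = ", "), ")\n")
  invisible(x)
}

#' Evaluate the scalar potential field of a landscape
#'
#' Returns the potential energy experienced by a CF3-like probe at the given
#' position(s): the sum of all Gaussian wells plus the confinement wall. The
#' field is continuous, minimal near the deep-pocket center, has a secondary
#' minimum near the Met pocket iff its (genotype-scaled) depth is positive,
#' and decays to zero in bulk (inside the confinement wall).
#'
#' @param landscape A [build_landscape()] result.
#' @param position Numeric vector (one point) or matrix (one point per row).
#' @return Numeric vector of energies (kBT).
#' @export
landscape_potential <- function(landscape, position) {
  x <- to_coord_matrix(position, landscape$spec$dimensionality)
  w <- landscape$wells
  u <- numeric(nrow(x))
  for (i in seq_along(w$depth)) {
    r2 <- rowSums((x - matrix(w$center[i, ], nrow(x), ncol(x), byrow = TRUE))^2)
    u <- u - w$depth[i] * exp(-r2 / (2 * w$width[i]^2))
  }
  r <- sqrt(rowSums(x^2))
  over <- pmax(r - landscape$spec$confinement_radius, 0)
  u + 0.5 * landscape$spec$wall_k * over^2
}

#' Analytic gradient of the scalar potential field
#'
#' @inheritParams landscape_potential
#' @return Matrix of gradients, one row per input position.
#' @export
landscape_gradient <- function(landscape, position) {
  x <- to_coord_matrix(position, landscape$spec$dimensionality)
  w <- landscape$wells
  g <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(w$depth)) {
    dx <- x - matrix(w$center[i, ], nrow(x), ncol(x), byrow = TRUE)
    r2 <- rowSums(dx^2)
    g <- g + (w$depth[i] * exp(-r2 / (2 * w$width[i]^2)) / w$width[i]^2) * dx
  }
  r <- sqrt(rowSums(x^2))
  over <- pmax(r - landscape$spec$confinement_radius, 0)
  wall <- ifelse(r > 0, landscape$spec$wall_k * over / pmax(r, 1e-300), 0)
  g + wall * x
}

#' Total potential energy of a rigid two-probe ligand
#'
#' The deep-pocket well (and wall) act on both probe beads; the Met-pocket
#' well acts on the CF3 probe only. This is the energy the dynamics engine
#' integrates.
#'
#' @param landscape A [build_landscape()] result.
#' @param cf3,o1 Probe coordinates.
#' @return Scalar energy (kBT).
#' @export
ligand_energy <- function(landscape, cf3, o1) {
  w <- landscape$wells
  s <- landscape$spec
  e <- 0
  for (i in seq_along(w$depth)) {
    beads <- if (w$bead[i] == 0L) list(cf3, o1)
             else if (w$bead[i] == 1L) list(cf3) else list(o1)
    for (b in beads) {
      r2 <- sum((b - w$center[i, ])^2)
      e <- e - w$depth[i] * exp(-r2 / (2 * w$width[i]^2))
    }
  }
  for (b in list(cf3, o1)) {
    over <- max(sqrt(sum(b^2)) - s$confinement_radius, 0)
    e <- e + 0.5 * s$wall_k * over^2
  }
  e
}

#' Construct a rigid two-probe ligand state
#'
#' A minimal ligand representation: the CF3-group carbon analogue and the
#' carboxylic-acid O1 oxygen analogue, held at a fixed separation.
#'
#' @param probe_cf3,probe_o1 Probe coordinates (equal length).
#' @param tol Tolerance used when later checking the rigid bond.
#' @return An object of class `ligand` with fields `probe_cf3`, `probe_o1`
#'   and `bond_length`.
#' @export
ligand <- function(probe_cf3, probe_o1, tol = 1e-8) {
  if (length(probe_cf3) != length(probe_o1))
    stop("probe coordinate dimensions differ")
  structure(list(probe_cf3 = as.numeric(probe_cf3),
                 probe_o1 = as.numeric(probe_o1),
                 bond_length = sqrt(sum((probe_cf3 - probe_o1)^2)),
                 tol = tol),
            class = "ligand")
}

#' Default bound ligand pose for a landscape
#'
#' Places the ligand across the deep pocket along the exit axis, CF3 end
#' toward the gatekeeper anchor, with the given bond length.
#'
#' @param landscape A [build_landscape()] result.
#' @param bond_length Rigid probe separation (default 6.6 length units).
#' @return A [ligand()].
#' @export
docking_pose <- function(landscape, bond_length = 6.6) {
  s <- landscape$spec
  axis <- s$met_anchor - s$deep_pocket_center
  axis <- axis / sqrt(sum(axis^2))
  ligand(s$deep_pocket_center + 0.5 * bond_length * axis,
         s$deep_pocket_center - 0.5 * bond_length * axis)
}

# coerce a vector or matrix of positions to a coordinate matrix
to_coord_matrix <- function(position, d) {
  if (is.matrix(position)) {
    if (ncol(position) != d) stop("position dimension mismatch")
    position
  } else {
    if (length(position) != d) stop("position dimension mismatch")
    matrix(position, 1, d)
  }
}
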