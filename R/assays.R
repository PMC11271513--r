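#' Simulate a washout recovery time-course
#'
#' One-phase exponential recovery of the agonist response after antagonist
#' washout: `y(t) = plateau + (initial - plateau) exp(-ln2 t / t_half)` plus
#' additive Gaussian noise. The default shape (0% recovering toward 100%)
#' emulates the fraction of receptors spared from antagonist binding as the
#' complex dissociates.
#'
#' @param t_half Complex dissociation half-life (h, > 0).
#' @param times Non-negative, strictly increasing sampling times (h).
#' @param plateau Response as t -> Inf (% of control).
#' @param initial Response at t = 0 (%).
#' @param noise_sd Additive noise s.d. (%).
#' @param seed Integer seed.
#' @return An `assay_dataset`: `kind`, `x`, `y`, `noise_sd`, `seed`,
#'   `true_params`.
#' @export
generate_washout_dataset <- function(t_half, times = c(0, 1, 3, 6, 24),
                                     plateau = 100, initial = 0,
                                     noise_sd = 0, seed = 1) {
  if (t_half <= 0) stop("`t_half` must be positive")
  check_time_axis(times)
  y <- plateau + (initial - plateau) * exp(-log(2) * times / t_half)
  y <- add_noise(y, noise_sd, seed)
  assay_dataset("washout", times, y, noise_sd, seed,
                list(t_half = t_half, plateau = plateau, initial = initial))
}

#' Simulate an IV-bolus plasma concentration decay
#'
#' One-compartment elimination: `C(t) = c0 exp(-ln2 t / t_half)`. Noise is
#' additive by default or multiplicative log-normal-like
#' (`y * (1 + noise)`) when `noise_type = "multiplicative"`.
#'
#' @param c0 Initial plasma concentration (arbitrary units, > 0).
#' @param t_half Elimination half-life (h, > 0).
#' @param times Sampling times (h).
#' @param noise_sd Noise s.d. (same units as `y`, or relative for
#'   multiplicative noise).
#' @param noise_type `"additive"` or `"multiplicative"`.
#' @param seed Integer seed.
#' @return An `assay_dataset`.
#' @export
generate_pk_dataset <- function(c0, t_half, times = c(0.5, 1, 2, 4, 8, 24),
                                noise_sd = 0, noise_type = c("additive",
                                                             "multiplicative"),
                                seed = 1) {
  if (t_half <= 0) stop("`t_half` must be positive")
  if (c0 <= 0) stop("`c0` must be positive")
  noise_type <- match.arg(noise_type)
  check_time_axis(times)
  y <- c0 * exp(-log(2) * times / t_half)
  if (noise_sd > 0) {
    eps <- seeded_noise(length(y), noise_sd, seed)
    y <- if (noise_type == "additive") y + eps else y * (1 + eps)
  }
  assay_dataset("pk", times, y, noise_sd, seed,
                list(c0 = c0, t_half = t_half, noise_type = noise_type))
}

#' Simulate a sigmoidal concentration-response curve
#'
#' Four-parameter logistic:
#' `y = bottom + (top - bottom) / (1 + (c / ic50)^hill)` plus additive noise.
#' With `hill > 0` the response falls with concentration (an inhibition
#' curve).
#'
#' @param ic50 Midpoint concentration (nM, > 0).
#' @param hill Hill slope.
#' @param top,bottom Upper and lower asymptotes (%).
#' @param concs Positive test concentrations (nM).
#' @param noise_sd Additive noise s.d. (%).
#' @param seed Integer seed.
#' @return An `assay_dataset`.
#' @export
generate_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                                   concs = 10^seq(-1, 3, by = 0.5),
                                   noise_sd = 0, seed = 1) {
  if (ic50 <= 0) stop("`ic50` must be positive")
  if (any(concs <= 0)) stop("concentrations must be positive")
  y <- bottom + (top - bottom) / (1 + (concs / ic50)^hill)
  y <- add_noise(y, noise_sd, seed)
  assay_dataset("dose_response", concs, y, noise_sd, seed,
                list(ic50 = ic50, hill = hill, top = top, bottom = bottom))
}

assay_dataset <- function(kind, x, y, noise_sd, seed, true_params) {
  stopifnot(all(is.finite(y)))
  structure(list(kind = kind, x = as.numeric(x), y = as.numeric(y),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 true_params = true_params),
            class = "assay_dataset")
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat("<assay_dataset> ", x$kind, ", ", length(x$x), " points, noise_sd ",
      format(x$noise_sd), "\n", sep = "")
  invisible(x)
}

check_time_axis <- function(times) {
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
}

add_noise <- function(y, noise_sd, seed) {
  if (noise_sd > 0) y <- y + seeded_noise(length(y), noise_sd, seed)
  y
}

# draw seeded Gaussian noise without clobbering the caller's RNG stream
seeded_noise <- function(n, sd, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  eps <- stats::rnorm(n, 0, sd)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  eps
}
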