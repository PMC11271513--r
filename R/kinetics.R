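#' Fit a one-phase exponential decay
#'
#' Least-squares fit of `y = plateau - span * exp(-k * t)` — the standard
#' model for washout recovery time-courses, where the response climbs from
#' `plateau - span` at t = 0 toward `plateau` as the antagonist-receptor
#' complex dissociates. The complex half-life is `ln2 / k`.
#'
#' Initialization is deterministic: the plateau starts at the response at
#' the latest time (inflated slightly), the rate from a log-linear pre-fit
#' of `plateau0 - y`.
#'
#' @param times Sampling times (h); at least 3 distinct values.
#' @param responses Responses (% of control).
#' @param plateau_fixed Optionally constrain the plateau to a known value
#'   (e.g. 100) instead of fitting it.
#' @return A `one_phase_decay_fit`: `k`, `t_half`, `plateau`, `span`,
#'   `residual_sse`, `converged`, `fitted`.
#' @export
fit_one_phase_decay <- function(times, responses, plateau_fixed = NULL) {
  stopifnot(length(times) == length(responses))
  if (length(unique(times)) < 3) stop("need >= 3 distinct time points")
  if (stats::sd(responses) == 0)
    stop("degenerate data: responses are constant (no decay to fit)")

  rising <- responses[which.max(times)] >= responses[which.min(times)]
  p0 <- if (!is.null(plateau_fixed)) plateau_fixed
        else if (rising) max(responses) + 0.05 * diff(range(responses))
        else min(responses) - 0.05 * diff(range(responses))
  s0 <- p0 - responses[which.min(times)]
  resid0 <- p0 - responses
  pos <- resid0 * sign(s0) > 0
  k0 <- if (sum(pos) >= 2)
    max(1e-6, -stats::coef(stats::lm(log(abs(resid0[pos])) ~ times[pos]))[[2]])
  else log(2) / (diff(range(times)) / 3)

  df <- data.frame(t = times, y = responses)
  fit <- tryCatch({
    if (is.null(plateau_fixed))
      minpack.lm::nlsLM(y ~ plateau - span * exp(-k * t), data = df,
                        start = list(plateau = p0, span = s0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    else
      minpack.lm::nlsLM(y ~ plateau_fixed - span * exp(-k * t), data = df,
                        start = list(span = s0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
  }, error = function(e) NULL)

  if (is.null(fit)) {
    out <- list(k = NA_real_, t_half = NA_real_, plateau = NA_real_,
                span = NA_real_, residual_sse = NA_real_, converged = FALSE,
                fitted = rep(NA_real_, length(times)))
    return(structure(out, class = "one_phase_decay_fit"))
  }
  cf <- stats::coef(fit)
  k <- cf[["k"]]
  plateau <- if (is.null(plateau_fixed)) cf[["plateau"]] else plateau_fixed
  converged <- is.finite(k) && k > 0
  structure(list(k = k, t_half = if (converged) log(2) / k else NA_real_,
                 plateau = plateau, span = cf[["span"]],
                 residual_sse = sum(stats::resid(fit)^2),
                 converged = converged, fitted = stats::fitted(fit)),
            class = "one_phase_decay_fit")
}

#' @export
print.one_phase_decay_fit <- function(x, ...) {
  cat("<one_phase_decay_fit> t_half =", format(x$t_half), "h, plateau =",
      format(x$plateau), ", converged:", x$converged, "\n")
  invisible(x)
}

#' Log-linear terminal-phase pharmacokinetic fit
#'
#' Linear regression of log concentration against time over the terminal
#' phase of an IV-bolus plasma time-course. The elimination half-life is
#' `ln2 / kel` with `kel` the negative slope.
#'
#' @param times Sampling times (h).
#' @param concentrations Positive plasma concentrations.
#' @param terminal_points Number of latest points to use (default: all).
#' @return List `kel`, `t_half`, `c0` (back-extrapolated intercept),
#'   `r_squared`, `converged`. A non-negative slope (rising concentrations)
#'   is flagged with `converged = FALSE`.
#' @export
fit_log_linear_pk <- function(times, concentrations, terminal_points = NULL) {
  stopifnot(length(times) == length(concentrations))
  if (!is.null(terminal_points)) {
    sel <- order(times)[utils::tail(seq_along(times), terminal_points)]
    times <- times[sel]; concentrations <- concentrations[sel]
  }
  if (length(times) < 3) stop("need >= 3 points in the terminal window")
  if (any(concentrations <= 0))
    stop("non-positive concentrations in the terminal window")
  fit <- stats::lm(log(concentrations) ~ times)
  slope <- stats::coef(fit)[[2]]
  kel <- -slope
  converged <- kel > 0
  ly <- log(concentrations)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((ly - mean(ly))^2)
  list(kel = kel,
       t_half = if (converged) log(2) / kel else NA_real_,
       c0 = exp(stats::coef(fit)[[1]]),
       r_squared = r2,
       converged = converged)
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (c / ic50)^hill)`.
#' With `hill > 0` this is a falling inhibition curve whose midpoint is the
#' IC50. Initialization is deterministic, from the data quartiles.
#'
#' @param concentrations Positive concentrations (nM); at least 4 spanning
#'   the inflection.
#' @param responses Responses (%).
#' @return A `four_pl_fit`: `ic50`, `hill`, `top`, `bottom`,
#'   `residual_sse`, `converged`, `fitted`.
#' @export
fit_4pl <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 4) stop("need >= 4 concentrations")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (stats::sd(responses) == 0)
    stop("degenerate data: responses are constant (flat curve)")

  top0 <- max(responses); bot0 <- min(responses)
  mid <- (top0 + bot0) / 2
  ic0 <- concentrations[which.min(abs(responses - mid))]
  falling <- stats::cor(log(concentrations), responses) < 0
  h0 <- if (falling) 1 else -1

  df <- data.frame(conc = concentrations, y = responses)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + (conc / ic50)^hill),
                      data = df,
                      start = list(bottom = bot0, top = top0, ic50 = ic0,
                                   hill = h0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, residual_sse = NA_real_,
                          converged = FALSE,
                          fitted = rep(NA_real_, length(responses))),
                     class = "four_pl_fit"))
  }
  cf <- stats::coef(fit)
  converged <- is.finite(cf[["ic50"]]) && cf[["ic50"]] > 0 &&
    cf[["top"]] > cf[["bottom"]]
  structure(list(ic50 = cf[["ic50"]], hill = cf[["hill"]], top = cf[["top"]],
                 bottom = cf[["bottom"]],
                 residual_sse = sum(stats::resid(fit)^2),
                 converged = converged, fitted = stats::fitted(fit)),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("<four_pl_fit> ic50 =", format(x$ic50), "nM, hill =", format(x$hill),
      ", top/bottom =", format(x$top), "/", format(x$bottom), "\n")
  invisible(x)
}
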