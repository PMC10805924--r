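#' Adaptation-curve parameters
#'
#' Bundle the three parameters of the target-choice adaptation model:
#' adaptation `tau` (non-negative; 0 = random choice, large values approach
#' a perfect small-subset discriminator), shift `delta` (horizontal offset
#' of the curve in trials; the lag with which attentional control settings
#' follow the environment), and bias `beta` (ratio-independent vertical
#' preference for the pentagon shape, applied on the log-odds scale).
#'
#' @param tau Non-negative adaptation strength.
#' @param delta Shift in trials (may be fractional or negative).
#' @param beta Pentagon bias on the log-odds scale.
#' @return An object of class `adaptation_params`.
#' @export
adaptation_params <- function(tau, delta = 0, beta = 0) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0)
    stop("tau must be a single non-negative number")
  stopifnot(is.numeric(delta), length(delta) == 1, is.finite(delta),
            is.numeric(beta), length(beta) == 1, is.finite(beta))
  structure(list(tau = tau, delta = delta, beta = beta),
            class = "adaptation_params")
}

#' @export
print.adaptation_params <- function(x, ...) {
  cat(sprintf("adaptation parameters: tau = %g, delta = %g trials, beta = %g\n",
              x$tau, x$delta, x$beta))
  invisible(x)
}

#' Objective pentagon-distractor proportion of a schedule
#'
#' @param schedule Schedule data.frame (from [build_cycle()] or
#'   [build_session()]).
#' @return Numeric vector, one value per trial: the proportion of
#'   distractors that are pentagons (0 on star plateaus, 1 on pentagon
#'   plateaus, linear in between).
#' @export
objective_proportion <- function(schedule) {
  tot <- schedule$n_star + schedule$n_pentagon
  if (any(tot <= 0)) stop("schedule has trials without distractors")
  schedule$n_pentagon / tot
}

# Objective proportion shifted right by `delta` trials within each block,
# with linear interpolation between integer positions and flat
# extrapolation beyond the block bounds (before a block starts the
# environment is taken to sit at its opening plateau).
lagged_proportion <- function(schedule, delta) {
  q <- objective_proportion(schedule)
  blk <- if ("block" %in% names(schedule)) schedule$block else
    rep(1L, nrow(schedule))
  out <- numeric(length(q))
  for (b in unique(blk)) {
    i <- which(blk == b)
    # use the recorded within-block trial index so filtered data keep their
    # schedule positions; the objective trajectory is piecewise linear in
    # the trial index, so interpolation over gaps stays essentially exact
    pos <- if ("trial" %in% names(schedule)) schedule$trial[i] else seq_along(i)
    out[i] <- if (length(i) == 1) q[i] else
      stats::approx(pos, q[i], xout = pos - delta, rule = 2)$y
  }
  out
}

# Steepness link between adaptation tau and the choice log-odds: the
# log-odds of selecting the star target is GAIN * tau * (2q - 1) where q is
# the lagged pentagon-distractor proportion. GAIN = 6 makes tau = 1
# correspond to a curve whose plateaus essentially reach 0/1 (asymptote
# plogis(6) = .9975) and reproduces the published group-mode worked
# examples; see the methods vignette.
.acvs_gain <- 6

#' Evaluate the adaptation curve on a schedule
#'
#' Maps schedule position to the probability of selecting the star target.
#' The curve is a chain of logistic segments: the log-odds of a star
#' choice are proportional (gain x `tau`) to the signed shape imbalance of
#' the distractor set, evaluated `delta` trials in the past (linear
#' interpolation, flat before block start), minus the pentagon bias
#' `beta`. Plateaus sit at `plogis(+/- gain * tau -/+ beta)` and the
#' transitions rise and fall sigmoidally between them.
#'
#' @param params An [adaptation_params()] object.
#' @param schedule Schedule data.frame.
#' @param gain Steepness-link constant between `tau` and the log-odds
#'   (default `6`, the package's calibrated value; see vignette).
#' @return Numeric vector of star-selection probabilities, strictly inside
#'   (0, 1), aligned to the rows of `schedule`.
#' @seealso [unique_target_prob()], [plateau_condition_means()]
#' @export
adaptation_curve <- function(params, schedule, gain = .acvs_gain) {
  if (!inherits(params, "adaptation_params"))
    params <- do.call(adaptation_params, as.list(params)[c("tau", "delta", "beta")])
  if (nrow(schedule) == 0) return(numeric(0))
  qlag <- lagged_proportion(schedule, params$delta)
  p <- stats::plogis(2 * gain * params$tau * (qlag - 0.5) - params$beta)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Probability of selecting the unique-shape target
#'
#' On trials where the two distractor subsets differ in size, the "unique"
#' target is the one whose shape matches the smaller subset (on plateaus,
#' the shape singleton). Converts a star-selection curve into the
#' probability of selecting the unique target; `NA` where the subsets are
#' equal (e.g. the transition midpoint T7).
#'
#' @param schedule Schedule data.frame.
#' @param p_star Star-selection probabilities from [adaptation_curve()].
#' @return Numeric vector of unique-target selection probabilities.
#' @export
unique_target_prob <- function(schedule, p_star) {
  stopifnot(length(p_star) == nrow(schedule))
  ifelse(schedule$n_star == schedule$n_pentagon, NA_real_,
         ifelse(schedule$n_star < schedule$n_pentagon, p_star, 1 - p_star))
}

#' Plateau-phase mean unique-target selection by starting-plateau condition
#'
#' Builds one main block for each starting-plateau condition, evaluates
#' the adaptation curve, and averages the predicted unique-target
#' selection probability over the plateau trials of the block's starting
#' type (the cycle-start plateaus plus the final plateau). These are the
#' two values a fitted group-level curve "reaches in the plateau phases"
#' for the two conditions.
#'
#' @param params An [adaptation_params()] object.
#' @param cycles_per_block Cycles per main block (default 3).
#' @param gain See [adaptation_curve()].
#' @return Named numeric vector with elements `star_start` and
#'   `pentagon_start`: mean unique-target selection probability per
#'   condition.
#' @export
plateau_condition_means <- function(params, cycles_per_block = 3,
                                    gain = .acvs_gain) {
  vapply(c(star_start = "star", pentagon_start = "pentagon"), function(s) {
    blk <- build_session(n_practice = 0, n_main = 1,
                         cycles_per_main = cycles_per_block,
                         first_block_start = s)
    p_star <- adaptation_curve(params, blk, gain = gain)
    p_uni <- unique_target_prob(blk, p_star)
    sel <- !is.na(blk$plateau) & blk$plateau == s
    mean(p_uni[sel])
  }, numeric(1))
}

#' Bernoulli log-likelihood of observed choices under the adaptation curve
#'
#' @param params An [adaptation_params()] object.
#' @param data Trial data.frame holding the schedule columns plus a
#'   `choice` column (`"star"`/`"pentagon"`). The lag is applied within
#'   each `block` (and, if present, within each `participant`).
#' @param gain See [adaptation_curve()].
#' @return The summed log-likelihood (a single finite number for finite
#'   parameters).
#' @export
adaptation_loglik <- function(params, data, gain = .acvs_gain) {
  if (!all(c("choice", "n_star", "n_pentagon") %in% names(data)))
    stop("data must carry choice, n_star and n_pentagon columns")
  if (!all(data$choice %in% c("star", "pentagon")))
    stop("choice must be 'star' or 'pentagon' on every trial")
  split_by <- if ("participant" %in% names(data)) data$participant else
    rep(1L, nrow(data))
  ll <- 0
  for (pp in unique(split_by)) {
    d <- data[split_by == pp, , drop = FALSE]
    p <- adaptation_curve(params, d, gain = gain)
    ll <- ll + sum(ifelse(d$choice == "star", log(p), log1p(-p)))
  }
  ll
}
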