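#' Per-participant mean response times by cycle phase
#'
#' Averages RTs separately over plateau trials (phases `P1`-`P3`) and
#' transition trials (`T1`-`T13`) for each participant. Participants
#' lacking trials in either phase are dropped with a warning.
#'
#' @param data Preprocessed trial data.frame with `participant`, `phase`
#'   and `rt_ms` columns.
#' @return Data.frame with `participant`, `plateau_ms`, `transition_ms`.
#' @export
mean_rt_by_phase <- function(data) {
  stopifnot(all(c("participant", "phase", "rt_ms") %in% names(data)))
  is_plateau <- grepl("^P", data$phase)
  out <- do.call(rbind, lapply(split(data, data$participant), function(d) {
    pl <- grepl("^P", d$phase)
    data.frame(participant = d$participant[1],
               plateau_ms = if (any(pl)) mean(d$rt_ms[pl]) else NA_real_,
               transition_ms = if (any(!pl)) mean(d$rt_ms[!pl]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  miss <- is.na(out$plateau_ms) | is.na(out$transition_ms)
  if (any(miss)) {
    warning(sum(miss), " participant(s) lacked trials in one phase and were dropped")
    out <- out[!miss, , drop = FALSE]
  }
  out
}

# Kruschke-style BEST model: Student-t observation model per group,
# data-scaled vague priors, shifted-exponential normality parameter.
.best_model_string <- "
model {
  for (i in 1:Na) { ya[i] ~ dt(mu[1], 1 / sigma[1]^2, nu) }
  for (i in 1:Nb) { yb[i] ~ dt(mu[2], 1 / sigma[2]^2, nu) }
  for (g in 1:2) {
    mu[g] ~ dnorm(pooled_mean, 1 / (1000 * pooled_sd)^2)
    sigma[g] ~ dunif(pooled_sd / 1000, pooled_sd * 1000)
  }
  nu <- nu_minus_one + 1
  nu_minus_one ~ dexp(1 / 29)
  diff <- mu[1] - mu[2]
}"

#' Bayesian two-group comparison (BEST)
#'
#' Estimates each group's location with a Student-t observation model
#' (vague, data-scaled priors on locations and scales; shifted-exponential
#' prior on the normality parameter) and summarises the posterior of the
#' difference of means, as in Kruschke's "Bayesian estimation supersedes
#' the t test" procedure.
#'
#' @param group_a,group_b Numeric vectors (e.g. per-participant mean RTs
#'   in ms); each needs `n >= 2` and non-zero pooled variance.
#' @param chains,tune,draws Sampler settings (per chain).
#' @param seed Integer seed (deterministic given data and seed).
#' @return A list of class `best_result`: `group_a` / `group_b`
#'   (mode and 95% HDI of each mean), `difference` (mode, HDI,
#'   `frac_below` / `frac_above` zero), and `draws` (matrix of monitored
#'   draws).
#' @export
best_compare <- function(group_a, group_b, chains = 3, tune = 500,
                         draws = 1000, seed = 1) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 finite observations")
  pooled_sd <- stats::sd(c(group_a, group_b))
  if (!is.finite(pooled_sd) || pooled_sd == 0)
    stop("degenerate input: pooled standard deviation is zero")
  jdata <- list(ya = group_a, yb = group_b,
                Na = length(group_a), Nb = length(group_b),
                pooled_mean = mean(c(group_a, group_b)),
                pooled_sd = pooled_sd)
  inits <- lapply(seq_len(chains), function(ch) {
    list(mu = c(mean(group_a), mean(group_b)),
         sigma = c(max(stats::sd(group_a), pooled_sd / 100),
                   max(stats::sd(group_b), pooled_sd / 100)),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 103 + ch) %% .Machine$integer.max)
  })
  jm <- rjags::jags.model(textConnection(.best_model_string), data = jdata,
                          inits = inits, n.chains = chains, n.adapt = tune,
                          quiet = TRUE)
  sm <- rjags::coda.samples(jm, c("mu", "diff", "sigma", "nu"),
                            n.iter = draws)
  mat <- as.matrix(sm)
  d <- mat[, "diff"]
  res <- list(
    group_a = list(mode = posterior_mode(mat[, "mu[1]"]),
                   hdi = hdi(mat[, "mu[1]"])),
    group_b = list(mode = posterior_mode(mat[, "mu[2]"]),
                   hdi = hdi(mat[, "mu[2]"])),
    difference = list(mode = posterior_mode(d), hdi = hdi(d),
                      frac_below = mean(d < 0), frac_above = mean(d > 0)),
    draws = mat)
  class(res) <- "best_result"
  res
}

#' @export
print.best_result <- function(x, ...) {
  f <- function(nm, s) cat(sprintf("  %-10s %8.3g [%.3g, %.3g]\n", nm,
                                   s$mode, s$hdi[1], s$hdi[2]))
  cat("BEST two-group comparison\n")
  f("group A", x$group_a); f("group B", x$group_b)
  f("A - B", x$difference)
  cat(sprintf("  P(diff < 0) = %.3f, P(diff > 0) = %.3f\n",
              x$difference$frac_below, x$difference$frac_above))
  invisible(x)
}

#' Plateau-vs-transition RT comparison
#'
#' Convenience wrapper: computes per-participant phase means with
#' [mean_rt_by_phase()] and compares the plateau and transition mean
#' vectors with [best_compare()] (two-group framing; the difference is
#' reported as transition minus plateau).
#'
#' @param data Preprocessed trial data.frame.
#' @param ... Passed to [best_compare()].
#' @return A `best_result` (group A = transition, group B = plateau).
#' @export
rt_phase_comparison <- function(data, ...) {
  m <- mean_rt_by_phase(data)
  best_compare(m$transition_ms, m$plateau_ms, ...)
}
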