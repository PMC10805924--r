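#' Settings for the hierarchical adaptation-curve fit
#'
#' Collects prior constants, sampler settings and the schedule design
#' needed to rebuild the objective shape-ratio trajectory inside the
#' sampler. Priors are weakly informative and fully overridable: the group
#' location of log-tau is normal (default mean -1, sd 2, covering
#' adaptation strengths from ~0.01 to ~10), the group shift and bias
#' locations are normal centered at 0, and all group scales have
#' half-normal hyperpriors.
#'
#' @param chains,tune,draws,thin MCMC settings (defaults 4 chains, 1000
#'   adaptation iterations, 1000 retained draws per chain).
#' @param full_scale If `TRUE`, raise `draws` to 20000 (publication-scale
#'   runs).
#' @param seed Integer seed; chains get distinct derived seeds.
#' @param priors Named list overriding any of `mu_logtau`, `mu_delta`,
#'   `mu_beta` (each `c(mean, sd)`), `sigma_logtau_sd`, `sigma_delta_sd`,
#'   `sigma_beta_sd` (half-normal scales), `delta_bound` (truncation of
#'   the shift, in trials).
#' @param gain Steepness link of the adaptation curve (see
#'   [adaptation_curve()]).
#' @param design Named list describing the block design used to rebuild
#'   the shape-ratio trajectory: `cycles_per_block`, `plateau_len`,
#'   `transition_len`, `n_distractors`.
#' @return A list of class `hier_spec`.
#' @export
hier_spec <- function(chains = 4, tune = 1000, draws = 1000, thin = 1,
                      full_scale = FALSE, seed = 1,
                      priors = list(), gain = .acvs_gain,
                      design = list()) {
  pr <- list(mu_logtau = c(-1, 2), sigma_logtau_sd = 1,
             mu_delta = c(0, 3), sigma_delta_sd = 2,
             mu_beta = c(0, 1), sigma_beta_sd = 1,
             delta_bound = 9)
  pr[names(priors)] <- priors
  dg <- list(cycles_per_block = 3, plateau_len = 3, transition_len = 13,
             n_distractors = 14)
  dg[names(design)] <- design
  if (full_scale) draws <- 20000
  structure(list(chains = chains, tune = tune, draws = draws, thin = thin,
                 seed = seed, priors = pr, gain = gain, design = dg),
            class = "hier_spec")
}

.hier_model_string <- "
model {
  for (c in 1:C) {
    qs[c] <- interp.lin(pos[c] - delta[subj[c]], grid, qA)
    qp[c] <- interp.lin(pos[c] - delta[subj[c]], grid, qB)
    qhat[c] <- equals(btype[c], 1) * qs[c] + equals(btype[c], 2) * qp[c]
    logit(p[c]) <- 2 * gain * tau[subj[c]] * (qhat[c] - 0.5) - beta[subj[c]]
    y[c] ~ dbin(p[c], n[c])
  }
  for (s in 1:S) {
    ltau[s] ~ dnorm(mu_lt, 1 / sig_lt^2)
    tau[s] <- exp(ltau[s])
    delta[s] ~ dnorm(mu_d, 1 / sig_d^2) T(-dbound, dbound)
    beta[s] ~ dnorm(mu_b, 1 / sig_b^2)
  }
  mu_lt ~ dnorm(p_mu_lt[1], 1 / p_mu_lt[2]^2)
  sig_lt ~ dnorm(0, 1 / p_sig_lt^2) T(0,)
  mu_d ~ dnorm(p_mu_d[1], 1 / p_mu_d[2]^2)
  sig_d ~ dnorm(0, 1 / p_sig_d^2) T(0,)
  mu_b ~ dnorm(p_mu_b[1], 1 / p_mu_b[2]^2)
  sig_b ~ dnorm(0, 1 / p_sig_b^2) T(0,)
  tau_group <- exp(mu_lt)
}"

# Objective trajectory of one block (pentagon-distractor proportion per
# trial), padded flat on both sides so lagged lookups stay in range.
.block_grid <- function(start, design, pad) {
  blk <- build_session(n_practice = 0, n_main = 1,
                       cycles_per_main = design$cycles_per_block,
                       first_block_start = start,
                       plateau_len = design$plateau_len,
                       transition_len = design$transition_len,
                       n_distractors = design$n_distractors)
  q <- objective_proportion(blk)
  len <- length(q)
  grid <- seq(1 - pad, len + pad)
  list(grid = grid,
       q = stats::approx(seq_len(len), q, xout = grid, rule = 2)$y,
       len = len)
}

#' Fit the hierarchical Bayesian adaptation model
#'
#' Participant-level adaptation parameters (log-tau, delta, beta) are
#' drawn from group-level normal distributions whose locations and scales
#' get weakly-informative hyperpriors; observed choices are Bernoulli with
#' probability given by the adaptation curve. Sampling runs in JAGS;
#' identical seeds give identical results. Group-level parameters are
#' reported on the natural scale (`tau` is `exp` of the log-tau location,
#' i.e. the population median adaptation strength).
#'
#' @param data Trial data.frame with columns `participant`, `block_start`
#'   (`"star"`/`"pentagon"`), `trial` (1-based position within block) and
#'   `choice` (`"star"`/`"pentagon"`). Typically a preprocessed
#'   main-block [simulate_study()] dataset or imported trial log.
#' @param spec A [hier_spec()].
#' @return An object of class `acvs_fit`: list with `summary` (one row
#'   per reported parameter: mode, 95% HDI, split-Rhat, effective sample
#'   size), `group` (named list of posterior draw vectors for group
#'   `tau`, `delta`, `beta`), `participant` (per-participant summary),
#'   `draws` (the full `coda::mcmc.list`), `participants` (level key),
#'   `warnings`.
#' @export
fit_hierarchical <- function(data, spec = hier_spec()) {
  need <- c("participant", "block_start", "trial", "choice")
  if (!all(need %in% names(data)))
    stop("data must carry columns: ", paste(need, collapse = ", "))
  if (nrow(data) == 0) stop("no trials to fit")
  if (!all(data$choice %in% c("star", "pentagon")))
    stop("choice must be 'star' or 'pentagon'")

  pr <- spec$priors
  pad <- ceiling(pr$delta_bound) + 2
  gA <- .block_grid("star", spec$design, pad)
  gB <- .block_grid("pentagon", spec$design, pad)
  if (any(data$trial < 1 | data$trial > gA$len))
    stop("trial positions outside the configured block design")

  ids <- sort(unique(data$participant))
  subj <- match(data$participant, ids)
  btype <- ifelse(data$block_start == "star", 1L, 2L)
  agg <- stats::aggregate(cbind(y = data$choice == "star", n = 1L),
                          by = list(subj = subj, btype = btype,
                                    pos = data$trial),
                          FUN = sum)

  jdata <- list(C = nrow(agg), S = length(ids),
                pos = agg$pos, subj = agg$subj, btype = agg$btype,
                y = agg$y, n = agg$n,
                grid = gA$grid, qA = gA$q, qB = gB$q,
                gain = spec$gain, dbound = pr$delta_bound,
                p_mu_lt = pr$mu_logtau, p_sig_lt = pr$sigma_logtau_sd,
                p_mu_d = pr$mu_delta, p_sig_d = pr$sigma_delta_sd,
                p_mu_b = pr$mu_beta, p_sig_b = pr$sigma_beta_sd)

  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(mu_lt = -2, mu_d = 0, mu_b = 0,
         sig_lt = 0.5, sig_d = 0.5, sig_b = 0.5,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (spec$seed * 101 + ch) %% .Machine$integer.max)
  })
  jm <- rjags::jags.model(textConnection(.hier_model_string), data = jdata,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = spec$tune, quiet = TRUE)
  monitors <- c("tau_group", "mu_d", "mu_b", "sig_lt", "sig_d", "sig_b",
                "tau", "delta", "beta")
  draws <- rjags::coda.samples(jm, monitors, n.iter = spec$draws * spec$thin,
                               thin = spec$thin)

  mat <- as.matrix(draws)
  group <- list(tau = mat[, "tau_group"], delta = mat[, "mu_d"],
                beta = mat[, "mu_b"])
  gpars <- c(tau = "tau_group", delta = "mu_d", beta = "mu_b",
             sigma_logtau = "sig_lt", sigma_delta = "sig_d",
             sigma_beta = "sig_b")
  summ <- do.call(rbind, lapply(names(gpars), function(nm) {
    x <- mat[, gpars[[nm]]]
    h <- hdi(x)
    data.frame(param = nm, mode = posterior_mode(x),
               hdi_low = h[1], hdi_high = h[2],
               rhat = split_rhat(draws, gpars[[nm]]),
               ess = unname(coda::effectiveSize(draws[, gpars[[nm]]])),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  ppar <- do.call(rbind, lapply(c("tau", "delta", "beta"), function(par) {
    do.call(rbind, lapply(seq_along(ids), function(s) {
      x <- mat[, sprintf("%s[%d]", par, s)]
      h <- hdi(x)
      data.frame(participant = ids[s], param = par,
                 mode = posterior_mode(x), hdi_low = h[1], hdi_high = h[2],
                 stringsAsFactors = FALSE)
    }))
  }))

  warns <- character(0)
  bad <- summ$param[!is.na(summ$rhat) & summ$rhat > 1.01]
  if (length(bad))
    warns <- c(warns, sprintf("split-Rhat > 1.01 for: %s",
                              paste(bad, collapse = ", ")))
  for (w in warns) warning(w, call. = FALSE)

  structure(list(summary = summ, group = group, participant = ppar,
                 draws = draws, participants = ids, spec = spec,
                 warnings = warns),
            class = "acvs_fit")
}

#' @export
print.acvs_fit <- function(x, ...) {
  cat(sprintf("Hierarchical adaptation-curve fit: %d participants, %d draws\n",
              length(x$participants), length(x$group$tau)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-13s %6.3g [%.3g, %.3g]\n",
                s$param[i], s$mode[i], s$hdi_low[i], s$hdi_high[i]))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Posterior mode of a sample of draws
#'
#' The argmax of a Gaussian-kernel density estimate (Silverman's
#' rule-of-thumb bandwidth, 512-point grid). A degenerate sample returns
#' its common value.
#'
#' @param draws Numeric vector of posterior draws.
#' @return The estimated mode (a single number).
#' @export
posterior_mode <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0) stop("no draws supplied")
  if (stats::var(draws) < .Machine$double.eps) return(stats::median(draws))
  d <- stats::density(draws, n = 512)
  d$x[which.max(d$y)]
}

#' Highest-density interval of a sample of draws
#'
#' The shortest interval containing `ceiling(mass * n)` of the sorted
#' draws.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass of the interval (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1)
    stop("mass must lie strictly between 0 and 1")
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n == 0) stop("no draws supplied")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Posterior contrast between two sets of draws
#'
#' Summarises the distribution of `a - b`, pairing draws by index after
#' truncating both vectors to the shorter length. Used e.g. for
#' first-vs-last-block or cross-experiment parameter comparisons.
#'
#' @param draws_a,draws_b Numeric vectors of posterior draws.
#' @return List with `mode`, `hdi` (`c(low, high)`), `frac_below` /
#'   `frac_above` (posterior mass below/above zero) and the difference
#'   `draws`.
#' @export
contrast <- function(draws_a, draws_b) {
  if (length(draws_a) == 0 || length(draws_b) == 0)
    stop("both draw vectors must be non-empty")
  n <- min(length(draws_a), length(draws_b))
  d <- draws_a[seq_len(n)] - draws_b[seq_len(n)]
  list(mode = posterior_mode(d), hdi = hdi(d),
       frac_below = mean(d < 0), frac_above = mean(d > 0),
       draws = d)
}

#' Split-Rhat convergence diagnostic for one monitored parameter
#'
#' Each chain is split in half and the usual potential-scale-reduction
#' statistic is computed over the resulting half-chains.
#'
#' @param draws A `coda::mcmc.list`.
#' @param param Column name of the monitored parameter.
#' @return The split-Rhat value (`NA` if fewer than 2 half-chains or no
#'   variance).
#' @export
split_rhat <- function(draws, param) {
  halves <- list()
  for (ch in seq_along(draws)) {
    x <- as.numeric(draws[[ch]][, param])
    n2 <- floor(length(x) / 2)
    if (n2 < 2) next
    halves <- c(halves, list(x[1:n2], x[(n2 + 1):(2 * n2)]))
  }
  m <- length(halves)
  if (m < 2) return(NA_real_)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}
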