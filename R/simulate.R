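# Deterministic substream seed derived from a root seed and a stream name.
.sub_seed <- function(seed, name) {
  (as.integer(seed) %% 65011 * 32749 +
     sum(utf8ToInt(name)) * 257) %% 2147483629L + 1L
}

#' Configuration for a synthetic ACVS study
#'
#' Defaults emulate the study conditions of the shape-based experiments:
#' a session of 2 practice and 4 main blocks (466 trials), a cohort whose
#' adaptation parameters scatter around group values in the range the
#' task produces, response times slower on transitions than plateaus,
#' and small rates of wrong-digit reports, timeouts and anticipatory
#' responses to exercise the exclusion filters.
#'
#' @param n_participants Cohort size.
#' @param tau,delta,beta Group-level parameter values (`tau` is the
#'   population median adaptation; participants draw
#'   `exp(N(log tau, sd_logtau))`).
#' @param sd_logtau,sd_delta,sd_beta Between-participant SDs (`delta`,
#'   `beta` are normal around the group value).
#' @param n_practice,n_main,cycles_per_main Session design (passed to
#'   [build_session()]).
#' @param rt_plateau_ms Mean RT on plateau trials (lognormal model).
#' @param rt_transition_offset_ms Added mean RT on transition trials.
#' @param rt_sdlog Lognormal scale of RTs.
#' @param wrong_digit_rate Probability a trial's report is a digit not in
#'   the display (scored incorrect).
#' @param timeout_rate Probability a trial's RT is replaced by a timeout
#'   (uniform 5001-8000 ms).
#' @param fast_rt_rate Probability a trial's RT is replaced by an
#'   anticipatory response (uniform 30-99 ms).
#' @param n_chance_participants Number of planted chance-level
#'   participants (no adaptation, ~50% accuracy; their blocks fail the
#'   75% accuracy filter).
#' @param generate_fixations Also simulate displays and fixation
#'   sequences (slower; default `FALSE`).
#' @param fixation_agent `"stay"` (first fixation per the target-landing
#'   schedule, intermediate fixations biased toward the eventually chosen
#'   shape with probability `p_stay`, last fixation on the chosen target),
#'   `"uniform_item"` (every fixation lands on a uniformly random item;
#'   chance level 1/16 per item) or `"uniform_shape"` (every fixation
#'   picks a shape class by fair coin, then an item of that class; the
#'   null for chosen-vs-non-chosen shape contrasts).
#' @param p_stay Stay-with-subset probability of the `"stay"` agent.
#' @param n_fix_mean Mean number of fixations per trial (minimum 2).
#' @param target_first_base,target_first_gain First fixations land on a
#'   (random) target with probability `base + gain * |2q - 1|`, where `q`
#'   is the objective pentagon proportion; otherwise on a random
#'   distractor. `base = 2/16`, `gain = 0` reproduces a uniform first
#'   fixation.
#' @param fix_jitter_px Gaussian jitter of fixation landing points around
#'   item centers.
#' @param seed Root seed; all stages draw from named substreams.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_participants = 30,
                              tau = 0.1, delta = 1.2, beta = 0.15,
                              sd_logtau = 0.5, sd_delta = 0.5, sd_beta = 0.3,
                              n_practice = 2, n_main = 4, cycles_per_main = 3,
                              rt_plateau_ms = 950,
                              rt_transition_offset_ms = 60,
                              rt_sdlog = 0.35,
                              wrong_digit_rate = 0.025,
                              timeout_rate = 0.001,
                              fast_rt_rate = 0,
                              n_chance_participants = 0,
                              generate_fixations = FALSE,
                              fixation_agent = c("stay", "uniform_item",
                                                 "uniform_shape"),
                              p_stay = 0.8, n_fix_mean = 4,
                              target_first_base = 2 / 16,
                              target_first_gain = 0.2,
                              fix_jitter_px = 15,
                              seed = 1) {
  fixation_agent <- match.arg(fixation_agent)
  cfg <- as.list(environment())
  stopifnot(tau >= 0, sd_logtau >= 0, sd_delta >= 0, sd_beta >= 0,
            wrong_digit_rate >= 0, wrong_digit_rate <= 1,
            timeout_rate >= 0, timeout_rate <= 1,
            fast_rt_rate >= 0, fast_rt_rate <= 1,
            p_stay >= 0, p_stay <= 1,
            n_chance_participants <= n_participants)
  class(cfg) <- "sim_config"
  cfg
}

#' Draw a cohort of participant-level adaptation parameters
#'
#' Participants are drawn from the same group distributions the
#' hierarchical model assumes: `tau` lognormal around the group median,
#' `delta` and `beta` normal. Planted chance-level participants get
#' `tau = 0`, `beta = 0`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional override of the cohort substream seed.
#' @return Data.frame with `participant`, `tau`, `delta`, `beta`,
#'   `chance` (planted chance-level flag) and `first_block_start`
#'   (balanced across the cohort).
#' @export
draw_participants <- function(config, seed = NULL) {
  set.seed(if (is.null(seed)) .sub_seed(config$seed, "cohort") else seed)
  n <- config$n_participants
  tau <- exp(stats::rnorm(n, log(config$tau), config$sd_logtau))
  if (config$tau == 0) tau <- rep(0, n)
  out <- data.frame(
    participant = seq_len(n),
    tau = tau,
    delta = stats::rnorm(n, config$delta, config$sd_delta),
    beta = stats::rnorm(n, config$beta, config$sd_beta),
    chance = rep(c(FALSE, TRUE),
                 c(n - config$n_chance_participants,
                   config$n_chance_participants)),
    first_block_start = rep(c("star", "pentagon"), length.out = n))
  out$tau[out$chance] <- 0
  out$beta[out$chance] <- 0
  out
}

.simulate_fixations_one <- function(trial, display, choice, config, q) {
  n_items <- nrow(display)
  agent <- config$fixation_agent
  n_fix <- 2L + stats::rpois(1, max(config$n_fix_mean - 2, 0))
  targets <- which(display$role == "target")
  chosen_target <- targets[display$shape[targets] == choice]
  items <- integer(n_fix)
  if (agent == "uniform_item") {
    items <- sample.int(n_items, n_fix, replace = TRUE)
  } else if (agent == "uniform_shape") {
    sh <- sample(c("star", "pentagon"), n_fix, replace = TRUE)
    items <- vapply(sh, function(s) {
      pool <- which(display$shape == s)
      pool[sample.int(length(pool), 1)]
    }, integer(1))
  } else {
    p_first <- min(1, max(0, config$target_first_base +
                            config$target_first_gain * abs(2 * q - 1)))
    items[1] <- if (stats::runif(1) < p_first)
      targets[sample.int(length(targets), 1)] else
        sample(setdiff(seq_len(n_items), targets), 1)
    if (n_fix > 2) for (j in 2:(n_fix - 1)) {
      pool <- if (stats::runif(1) < config$p_stay)
        which(display$shape == choice) else seq_len(n_items)
      items[j] <- pool[sample.int(length(pool), 1)]
    }
    items[n_fix] <- chosen_target
  }
  dur <- stats::runif(n_fix, 150, 350)
  data.frame(fix_index = seq_len(n_fix),
             x_px = display$x_px[items] + stats::rnorm(n_fix, 0, config$fix_jitter_px),
             y_px = display$y_px[items] + stats::rnorm(n_fix, 0, config$fix_jitter_px),
             onset_ms = cumsum(c(0, dur[-n_fix])),
             duration_ms = dur,
             true_item = items)
}

#' Simulate a complete synthetic ACVS study
#'
#' Builds each participant's session schedule, draws target choices as
#' Bernoulli realizations of that participant's adaptation curve, draws
#' lognormal response times with a plateau/transition offset, injects
#' wrong-digit, timeout and anticipatory contamination at the configured
#' rates, and (optionally) renders displays and simulates item-level
#' fixation sequences biased toward the eventually chosen shape.
#'
#' @param config A [simulation_config()].
#' @param seed Optional override of the root seed in `config`.
#' @return List of class `sim_study`: `trials` (choice dataset),
#'   `fixations` and `displays` (or `NULL`), and `truth` (cohort table,
#'   group values, config) for recovery tests.
#' @export
simulate_study <- function(config = simulation_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  cohort <- draw_participants(config)
  set.seed(.sub_seed(config$seed, "choices"))

  all_trials <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sched <- build_session(n_practice = config$n_practice,
                           n_main = config$n_main,
                           cycles_per_main = config$cycles_per_main,
                           first_block_start = cohort$first_block_start[i])
    if (nrow(sched) == 0) next
    pars <- adaptation_params(cohort$tau[i], cohort$delta[i], cohort$beta[i])
    p_star <- adaptation_curve(pars, sched)
    sched$participant <- cohort$participant[i]
    sched$p_star <- p_star
    sched$choice <- ifelse(stats::rbinom(nrow(sched), 1, p_star) == 1,
                           "star", "pentagon")
    all_trials[[i]] <- sched
  }
  trials <- do.call(rbind, all_trials)
  if (is.null(trials)) stop("empty session design")

  n <- nrow(trials)
  # target digits: two distinct digits from 1-4 per trial
  d1 <- sample.int(4, n, replace = TRUE)
  d2 <- ((d1 - 1 + sample.int(3, n, replace = TRUE)) %% 4) + 1
  trials$digit_star <- d1
  trials$digit_pentagon <- d2
  wrong_rate <- ifelse(trials$participant %in%
                         cohort$participant[cohort$chance],
                       0.5, config$wrong_digit_rate)
  wrong <- stats::runif(n) < wrong_rate
  chosen_digit <- ifelse(trials$choice == "star", d1, d2)
  other <- vapply(seq_len(n), function(j)
    sample(setdiff(1:4, c(d1[j], d2[j])), 1), integer(1))
  trials$digit_reported <- ifelse(wrong, other, chosen_digit)
  trials$correct <- trials$digit_reported == d1 |
    trials$digit_reported == d2

  set.seed(.sub_seed(config$seed, "rts"))
  m <- ifelse(grepl("^P", trials$phase), config$rt_plateau_ms,
              config$rt_plateau_ms + config$rt_transition_offset_ms)
  trials$rt_ms <- stats::rlnorm(n, log(m) - config$rt_sdlog^2 / 2,
                                config$rt_sdlog)
  u <- stats::runif(n)
  timeout <- u < config$timeout_rate
  fast <- !timeout & u < config$timeout_rate + config$fast_rt_rate
  trials$rt_ms[timeout] <- stats::runif(sum(timeout), 5001, 8000)
  trials$rt_ms[fast] <- stats::runif(sum(fast), 30, 99)
  rownames(trials) <- NULL

  fixations <- displays <- NULL
  if (config$generate_fixations) {
    set.seed(.sub_seed(config$seed, "fixations"))
    q <- objective_proportion(trials)
    fx <- vector("list", n); dp <- vector("list", n)
    for (j in seq_len(n)) {
      disp <- render_display(trials[j, ])
      f <- .simulate_fixations_one(trials[j, ], disp, trials$choice[j],
                                   config, q[j])
      key <- trials[j, c("participant", "block", "trial")]
      dp[[j]] <- cbind(key, disp, row.names = NULL)
      fx[[j]] <- cbind(key, f, row.names = NULL)
    }
    displays <- do.call(rbind, dp)
    fixations <- do.call(rbind, fx)
  }

  structure(list(trials = trials, fixations = fixations,
                 displays = displays,
                 truth = list(cohort = cohort,
                              group = list(tau = config$tau,
                                           delta = config$delta,
                                           beta = config$beta),
                              config = config)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("synthetic ACVS study: %d participants, %d trials%s\n",
              length(unique(x$trials$participant)), nrow(x$trials),
              if (is.null(x$fixations)) "" else
                sprintf(", %d fixations", nrow(x$fixations))))
  invisible(x)
}
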