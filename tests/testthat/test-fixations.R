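make_fix <- function(x, y, idx = seq_along(x)) {
  data.frame(fix_index = idx, x_px = x, y_px = y)
}

test_that("fixations go to the nearest item, with documented tie-breaking", {
  disp <- two_item_display()
  f <- assign_fixations(make_fix(c(100, 300, 200), c(100, 100, 100)), disp)
  expect_equal(f$item, c(1, 2, 1))          # equidistant -> lowest index
  expect_equal(f$tie, c(FALSE, FALSE, TRUE))

  # off-canvas fixations still assigned, but flagged
  f2 <- assign_fixations(make_fix(-50, 90), disp)
  expect_equal(f2$item, 1)
  expect_true(f2$off_canvas)
})

test_that("assignment matches an exhaustive distance scan on random layouts", {
  set.seed(99)
  trial <- build_cycle("star")[8, ]
  disp <- render_display(trial, seed = 15)
  fx <- make_fix(runif(200, 0, 1920), runif(200, 0, 1080))
  got <- assign_fixations(fx, disp)$item
  oracle <- vapply(seq_len(200), function(i) {
    d <- sqrt((fx$x_px[i] - disp$x_px)^2 + (fx$y_px[i] - disp$y_px)^2)
    disp$item[which.min(d)]
  }, integer(1))
  expect_identical(got, oracle)
})

# tiny hand-built study: one participant, plateau trials only
plateau_fixture <- function(n_trials = 6, first_on_unique = TRUE) {
  trials <- do.call(rbind, lapply(seq_len(n_trials), function(t) {
    data.frame(participant = 1L, block = 1L, trial = t, cycle_pos = t %% 3 + 1,
               block_start = "star", phase = paste0("P", t %% 3 + 1),
               n_star = 14L, n_pentagon = 0L, plateau = "star",
               choice = "pentagon", stringsAsFactors = FALSE)
  }))
  displays <- do.call(rbind, lapply(seq_len(n_trials), function(t) {
    cbind(participant = 1L, block = 1L, trial = t,
          render_display(trials[t, ], seed = 100 + t))
  }))
  fixations <- do.call(rbind, lapply(seq_len(n_trials), function(t) {
    disp <- displays[displays$trial == t, ]
    uni <- disp[disp$shape == "pentagon", ]   # the unique pentagon target
    data.frame(participant = 1L, block = 1L, trial = t, fix_index = 1L,
               x_px = uni$x_px, y_px = uni$y_px,
               onset_ms = 0, duration_ms = 200)
  }))
  list(trials = trials, displays = displays, fixations = fixations)
}

test_that("normalized proportions hit 1.0 for an always-on-unique first fixation", {
  fx <- plateau_fixture()
  tab <- assign_fixation_table(fx$fixations, fx$displays)
  out <- normalized_shape_proportions(tab, fx$trials, "first")
  pent <- out[out$shape == "pentagon", ]
  star <- out[out$shape == "star", ]
  expect_equal(pent$norm_prop, rep(1, nrow(pent)))   # 1 fixation / 1 item
  expect_equal(star$norm_prop, rep(0, nrow(star)))
})

test_that("a uniform-random fixation lands at .0625 per shape after normalization", {
  cfg <- simulation_config(n_participants = 12, n_main = 1, n_practice = 0,
                           generate_fixations = TRUE,
                           fixation_agent = "uniform_item", n_fix_mean = 2,
                           timeout_rate = 0, wrong_digit_rate = 0, seed = 42)
  st <- simulate_study(cfg)
  tab <- assign_fixation_table(st$fixations, st$displays)
  out <- normalized_shape_proportions(tab, st$trials, "first")
  onpl <- out[out$cycle_pos %in% 1:3, ]       # plateau cycle positions
  agg <- as.vector(tapply(onpl$norm_prop, onpl$shape, mean))
  expect_equal(agg, c(1 / 16, 1 / 16), tolerance = 0.25)
})

test_that("equal shape counts make normalization a fixed rescaling of raw proportions", {
  # T7 display: 7 + 7 distractors, 8 items per shape class
  trial <- data.frame(participant = 1L, block = 1L, trial = 1L,
                      cycle_pos = 10L, block_start = "star", phase = "T7",
                      n_star = 7L, n_pentagon = 7L, plateau = NA_character_,
                      choice = "star")
  disp <- cbind(participant = 1L, block = 1L, trial = 1L,
                render_display(trial, seed = 5))
  stars <- disp[disp$shape == "star", ]
  fx <- data.frame(participant = 1L, block = 1L, trial = 1L,
                   fix_index = 1:4,
                   x_px = c(stars$x_px[1:3], disp$x_px[disp$shape == "pentagon"][1]),
                   y_px = c(stars$y_px[1:3], disp$y_px[disp$shape == "pentagon"][1]))
  tab <- assign_fixation_table(fx, disp)
  out <- normalized_shape_proportions(tab, trial, "total")
  raw <- c(pentagon = 0.25, star = 0.75)
  expect_equal(out$norm_prop[order(out$shape)], unname(raw / 8))
  # ordering preserved
  expect_gt(out$norm_prop[out$shape == "star"],
            out$norm_prop[out$shape == "pentagon"])
})

test_that("an agent that only fixates chosen-shape items maxes the chosen proportion", {
  fx <- plateau_fixture()        # all fixations on the chosen pentagon target
  tab <- assign_fixation_table(fx$fixations, fx$displays)
  out <- chosen_vs_nonchosen_plateau(tab, fx$trials, n_boot = 500, seed = 1)
  uc <- out$unique_chosen
  expect_equal(uc$chosen[uc$measure == "first"], 1)
  expect_equal(uc$nonchosen[uc$measure == "first"], 0)
  expect_equal(uc$diff[uc$measure == "last"], 1)
  expect_null(out$nonunique_chosen)   # that class never occurs here
})

test_that("a uniform agent yields chosen-vs-nonchosen differences straddling zero", {
  cfg <- simulation_config(n_participants = 8, n_main = 1, n_practice = 0,
                           tau = 0, sd_logtau = 0, beta = 0, sd_beta = 0,
                           generate_fixations = TRUE,
                           fixation_agent = "uniform_shape", n_fix_mean = 4,
                           timeout_rate = 0, wrong_digit_rate = 0, seed = 9)
  st <- simulate_study(cfg)
  tab <- assign_fixation_table(st$fixations, st$displays)
  # 99% intervals: four simultaneous null checks
  out <- chosen_vs_nonchosen_plateau(tab, st$trials, n_boot = 2000,
                                     mass = 0.99, seed = 2)
  for (cls in c("unique_chosen", "nonunique_chosen")) {
    d <- out[[cls]]
    for (m in c("first", "last")) {
      r <- d[d$measure == m, ]
      expect_true(r$diff_lo <= 0 && r$diff_hi >= 0,
                  label = paste(cls, m, "interval straddles 0"))
      expect_lt(abs(r$diff), 0.25)
    }
  }
})

test_that("errors are raised when no plateau trials are available", {
  fx <- plateau_fixture()
  tr <- fx$trials
  tr$plateau <- NA_character_
  tab <- assign_fixation_table(fx$fixations, fx$displays)
  expect_error(chosen_vs_nonchosen_plateau(tab, tr), "plateau")
})

test_that("first fixations on targets track the planted landing schedule", {
  # always-on-target agent
  cfg <- simulation_config(n_participants = 3, n_main = 1, n_practice = 0,
                           generate_fixations = TRUE, fixation_agent = "stay",
                           target_first_base = 1, target_first_gain = 0,
                           timeout_rate = 0, wrong_digit_rate = 0, seed = 17)
  st <- simulate_study(cfg)
  tab <- assign_fixation_table(st$fixations, st$displays)
  out <- first_fixation_on_target_by_position(tab, st$trials)
  expect_equal(out$prop, rep(1, nrow(out)))

  # cycle-modulated landing probability: plateaus above the transition center
  cfg2 <- simulation_config(n_participants = 10, n_main = 1, n_practice = 0,
                            generate_fixations = TRUE, fixation_agent = "stay",
                            target_first_base = 0.1, target_first_gain = 0.6,
                            timeout_rate = 0, wrong_digit_rate = 0, seed = 18)
  st2 <- simulate_study(cfg2)
  tab2 <- assign_fixation_table(st2$fixations, st2$displays)
  out2 <- first_fixation_on_target_by_position(tab2, st2$trials)
  plateau_pos <- c(1:3, 17:19)
  mid_pos <- c(9:10, 25:26)
  expect_gt(mean(out2$prop[out2$cycle_pos %in% plateau_pos]),
            mean(out2$prop[out2$cycle_pos %in% mid_pos]) + 0.15)
})
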