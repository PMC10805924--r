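test_that("a cycle follows the plateau/transition structure", {
  for (start in c("star", "pentagon")) {
    cyc <- build_cycle(start)
    expect_equal(nrow(cyc), 32)
    expect_true(all(cyc$n_star + cyc$n_pentagon == 14))
    # starting plateau: zero distractors of the opposite shape
    opp <- if (start == "star") "n_pentagon" else "n_star"
    expect_true(all(cyc[[opp]][1:3] == 0))
    # transitions change each count by exactly one per trial
    trans <- grepl("^T", cyc$phase)
    steps <- diff(cyc$n_pentagon)
    expect_true(all(abs(steps[trans[-1]]) == 1))
    # plateau trials have zero distractors of exactly one shape
    pl <- grepl("^P", cyc$phase)
    expect_true(all(cyc$n_star[pl] == 0 | cyc$n_pentagon[pl] == 0))
    # transition midpoint has equal shape counts
    expect_true(all(cyc$n_star[cyc$phase == "T7"] == 7))
    expect_true(all(cyc$n_pentagon[cyc$phase == "T7"] == 7))
  }
})

test_that("the smallest legal cycle matches its construction rule", {
  cyc <- build_cycle("star", plateau_len = 1, transition_len = 1,
                     n_distractors = 2)
  expect_equal(cyc$n_pentagon, c(0L, 1L, 2L, 1L))
  expect_equal(cyc$n_star, c(2L, 1L, 0L, 1L))
  expect_error(build_cycle("star", plateau_len = 0), "plateau_len")
  expect_error(build_cycle("star", n_distractors = 5, transition_len = 13),
               "n_distractors")
})

test_that("sessions assemble blocks with the printed lengths and alternation", {
  s1 <- build_session(2, 4)
  expect_equal(nrow(s1), 466)
  s2 <- build_session(2, 8)
  expect_equal(nrow(s2), 862)
  expect_equal(nrow(build_session(0, 0)), 0)

  lens <- as.vector(tapply(s1$trial, s1$block, max))
  expect_equal(lens, c(35, 35, 99, 99, 99, 99))
  types <- as.vector(tapply(s1$block_type, s1$block, `[`, 1))
  expect_equal(types, c("practice", "practice", rep("main", 4)))

  starts <- as.vector(tapply(s1$block_start, s1$block, `[`, 1))
  expect_true(all(starts[-1] != starts[-length(starts)]))

  # each block starts and ends on its starting-plateau type
  for (b in unique(s1$block)) {
    d <- s1[s1$block == b, ]
    expect_equal(d$plateau[1], d$block_start[1])
    expect_equal(d$plateau[nrow(d)], d$block_start[1])
  }
})

test_that("the objective proportion is piecewise linear with plateaus at 0 and 1", {
  s <- build_session(0, 2)
  q <- objective_proportion(s)
  for (b in unique(s$block)) {
    qb <- q[s$block == b]
    d <- diff(qb)
    expect_true(all(abs(d) < 1e-12 | abs(abs(d) - 1 / 14) < 1e-12))
    pl <- grepl("^P", s$phase[s$block == b])
    expect_true(all(qb[pl] %in% c(0, 1)))
    expect_true(all(qb[!pl] > 0 & qb[!pl] < 1))
  }
})

test_that("displays realize the schedule trial exactly", {
  s <- build_session(0, 1)
  trial <- s[10, ]  # a transition trial
  disp <- render_display(trial, seed = 42)
  expect_equal(nrow(disp), 16)
  expect_equal(sum(disp$color == "black"), 14)
  expect_equal(sum(disp$color == "blue"), 2)
  expect_equal(sort(disp$shape[disp$role == "target"]),
               c("pentagon", "star"))
  expect_equal(sum(disp$shape == "star" & disp$role == "distractor"),
               trial$n_star)
  expect_equal(sum(disp$shape == "pentagon" & disp$role == "distractor"),
               trial$n_pentagon)
  # all grid positions distinct, on the 5 x 7 grid
  expect_equal(anyDuplicated(disp[, c("grid_row", "grid_col")]), 0)
  expect_true(all(disp$grid_row %in% 0:4 & disp$grid_col %in% 0:6))
  # target digits distinct in 1-4; distractor digits in 5-8
  td <- disp$digit[disp$role == "target"]
  expect_length(unique(td), 2)
  expect_true(all(td %in% 1:4))
  expect_true(all(disp$digit[disp$role == "distractor"] %in% 5:8))
})

test_that("on a pentagon plateau the star target is the only star item", {
  s <- build_session(0, 1, first_block_start = "pentagon")
  trial <- s[1, ]  # pentagon plateau
  disp <- render_display(trial, seed = 7)
  stars <- disp[disp$shape == "star", ]
  expect_equal(nrow(stars), 1)
  expect_equal(stars$role, "target")
  expect_equal(stars$color, "blue")
})

test_that("display rendering is deterministic given a seed", {
  trial <- build_cycle("star")[5, ]
  expect_identical(render_display(trial, seed = 123),
                   render_display(trial, seed = 123))
})
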