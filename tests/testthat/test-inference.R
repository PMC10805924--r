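test_that("posterior_mode behaves on degenerate, symmetric and skewed samples", {
  expect_equal(posterior_mode(rep(3.7, 500)), 3.7)
  expect_error(posterior_mode(numeric(0)), "no draws")
  set.seed(1)
  z <- rnorm(1e5)
  expect_lt(abs(posterior_mode(z)), 0.05)
  sq <- z^2  # strongly right-skewed: mode well below mean
  expect_lt(posterior_mode(sq), mean(sq))
})

# independent oracle: exhaustive scan over all sorted windows
hdi_oracle <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  best <- c(Inf, NA, NA)
  for (i in 1:(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < best[1]) best <- c(w, x[i], x[i + m - 1])
  }
  best[2:3]
}

test_that("hdi equals the exhaustive sorted-window oracle", {
  expect_equal(hdi(rep(2, 200)), c(2, 2))
  expect_error(hdi(rnorm(100), mass = 1.2), "mass")
  set.seed(2)
  z <- rnorm(1e5)
  expect_equal(hdi(z), c(-1.96, 1.96), tolerance = 0.05 / 1.96)
  for (x in list(rexp(501), rt(400, df = 3), c(rnorm(300), rnorm(200, 5)),
                 runif(137))) {
    for (m in c(0.5, 0.8, 0.95)) {
      expect_identical(hdi(x, m), hdi_oracle(x, m))
    }
  }
})

test_that("hdi mass is within 1/n of its target", {
  set.seed(3)
  x <- rgamma(2000, 2)
  h <- hdi(x, 0.9)
  expect_equal(mean(x >= h[1] & x <= h[2]), 0.9, tolerance = 2 / 2000)
})

test_that("posterior contrasts summarise paired differences", {
  set.seed(4)
  a <- rnorm(5000)
  z <- contrast(a, a)
  expect_equal(z$mode, 0)
  expect_true(z$hdi[1] <= 0 && z$hdi[2] >= 0)
  sh <- contrast(a, a + 1)
  expect_equal(sh$mode, -1)
  expect_equal(sh$frac_below, 1)
  expect_error(contrast(numeric(0), a), "non-empty")
})

test_that("the hierarchical fit is reproducible given a seed", {
  st <- simulate_study(simulation_config(n_participants = 6, n_main = 1,
                                         n_practice = 0, seed = 31))
  f1 <- suppressWarnings(fit_hierarchical(st$trials, quick_spec(9, tune = 150, draws = 150)))
  f2 <- suppressWarnings(fit_hierarchical(st$trials, quick_spec(9, tune = 150, draws = 150)))
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$group, f2$group)
  f3 <- suppressWarnings(fit_hierarchical(st$trials, quick_spec(10, tune = 150, draws = 150)))
  expect_false(identical(f1$group$tau, f3$group$tau))
})

test_that("fit input contracts are enforced", {
  st <- simulate_study(simulation_config(n_participants = 2, n_main = 1,
                                         n_practice = 0, seed = 1))
  d <- st$trials
  d$choice <- NULL
  expect_error(fit_hierarchical(d, quick_spec(1)), "choice")
  expect_error(fit_hierarchical(st$trials[0, ], quick_spec(1)), "no trials")
  bad <- st$trials
  bad$trial[1] <- 1000
  expect_error(fit_hierarchical(bad, quick_spec(1)), "positions")
})

test_that("participant estimates shrink from no-pooling toward the group", {
  cfg <- simulation_config(n_participants = 20, n_main = 2, n_practice = 0,
                           seed = 21)
  st <- simulate_study(cfg)
  fit <- suppressWarnings(fit_hierarchical(
    st$trials, hier_spec(chains = 2, tune = 300, draws = 500, seed = 3)))
  mat <- as.matrix(fit$draws)
  npool <- t(sapply(fit$participants, function(pp) {
    d <- st$trials[st$trials$participant == pp, ]
    nll <- function(th) -adaptation_loglik(
      adaptation_params(exp(th[1]), th[2], th[3]), d)
    o <- optim(c(log(0.1), 0, 0), nll)
    c(tau = exp(o$par[1]), delta = o$par[2], beta = o$par[3])
  }))
  ok <- 0; tot <- 0
  for (p in c("tau", "delta", "beta")) {
    gmean <- mean(fit$group[[p]])
    for (i in seq_along(fit$participants)) {
      est <- mean(mat[, sprintf("%s[%d]", p, i)])
      lo <- min(npool[i, p], gmean); hi <- max(npool[i, p], gmean)
      eps <- 0.05 * (hi - lo) + 1e-3
      tot <- tot + 1
      ok <- ok + (est >= lo - eps && est <= hi + eps)
    }
  }
  expect_gte(ok / tot, 0.9)
})

test_that("first-vs-last-block contrast on stationary data straddles zero", {
  cfg <- simulation_config(n_participants = 12, n_main = 4, n_practice = 0,
                           seed = 55)
  st <- simulate_study(cfg)
  first_blk <- st$trials[st$trials$block == 1, ]
  last_blk <- st$trials[st$trials$block == 4, ]
  f1 <- suppressWarnings(fit_hierarchical(first_blk, quick_spec(61, tune = 200, draws = 300)))
  f4 <- suppressWarnings(fit_hierarchical(last_blk, quick_spec(62, tune = 200, draws = 300)))
  ct <- contrast(f4$group$tau, f1$group$tau)
  expect_true(ct$hdi[1] <= 0 && ct$hdi[2] >= 0)
})
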