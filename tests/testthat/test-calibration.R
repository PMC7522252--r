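test_that("kappa estimation is the through-origin least-squares slope", {
  expect_equal(estimate_kappa(data.frame(t0 = 0, t1 = 0.5, t2 = 1.5)), 2)
  ep <- data.frame(t0 = c(0, 1, 2), t1 = c(0.5, 1.8, 2.6),
                   t2 = c(2.0, 4.2, 4.4))
  expect_equal(estimate_kappa(ep), 3)            # exactly proportional
  expect_error(estimate_kappa(data.frame(t0 = 1, t1 = 1, t2 = 2)),
               "episode")
  # noisy synthetic episodes around a known slope
  set.seed(31)
  x <- runif(40, 0.2, 1.5)
  y <- 2.5 * x + rnorm(40, 0, 0.05)
  ep2 <- data.frame(t0 = 0, t1 = x, t2 = x + y)
  expect_equal(estimate_kappa(ep2), 2.5, tolerance = 0.1)
})

test_that("kappa estimated from phase-machine episodes returns the configured value exactly", {
  cs <- new_contact_state(W_oi = 5, kappa = 2.7)
  cs <- update_contact_state(cs, TRUE, 1.0, c(0, -1))
  cs <- update_contact_state(cs, FALSE, 1.6, c(0, -1))
  cs <- update_contact_state(cs, FALSE, 10, c(0, -1))
  cs <- update_contact_state(cs, TRUE, 11, c(0, -1))
  cs <- update_contact_state(cs, FALSE, 11.9, c(0, -1))
  cs <- update_contact_state(cs, FALSE, 20, c(0, -1))
  expect_equal(estimate_kappa(cs$episodes), 2.7, tolerance = 1e-12)
})

test_that("grid search recovers generating parameters from noiseless fixtures", {
  times <- seq(0.5, 6, by = 0.5)
  truth <- list(tip_delay = 2.1, W_g = 0.1, W_r = 0.45, delta = 35)
  target <- fixture_index_series(truth, times)
  grids <- list(tip_delay = c(1.6, 2.1, 2.6),
                W_g = c(0.1, 0.2),
                W_r = c(0.35, 0.45),
                delta = c(25, 35))
  sim_fn <- function(params, seed) fixture_index_series(params, times)
  fit <- grid_search_fit(grids, target, sim_fn)
  expect_equal(fit$best$tip_delay, 2.1)
  expect_equal(fit$best$W_g, 0.1)
  expect_equal(fit$best$W_r, 0.45)
  expect_equal(fit$best$delta, 35)
  expect_equal(fit$error, 0, tolerance = 1e-20)
  expect_equal(nrow(fit$surface), 24L)
  # degenerate one-point grid returns that point
  fit1 <- grid_search_fit(list(tip_delay = 2.1), target,
                          function(p, s) fixture_index_series(
                            utils::modifyList(truth, p), times))
  expect_equal(fit1$best$tip_delay, 2.1)
  expect_error(grid_search_fit(list(), target, sim_fn), "non-empty")
})

test_that("grid search reports ties at the lowest index and surfaces failures", {
  target <- data.frame(time = 1:3, total_length = c(1, 2, 3))
  # constant simulator: every grid point ties
  fit <- grid_search_fit(list(a = c(1, 2, 3)), target,
                         function(p, s)
                           data.frame(time = 1:3,
                                      total_length = c(1, 2, 3)))
  expect_equal(length(fit$ties), 3L)
  expect_equal(fit$best$a, 1)
  expect_error(
    grid_search_fit(list(a = 1), target,
                    function(p, s) stop("boom")),
    "failed")
})

test_that("the error surface is invariant under permutation of replicate seeds", {
  times <- seq(0.5, 4, by = 0.5)
  target <- fixture_index_series(list(tip_delay = 2.1, W_g = 0.1,
                                      W_r = 0.45, delta = 35), times)
  noisy_sim <- function(params, seed) {
    set.seed(seed)
    full <- utils::modifyList(list(tip_delay = 2.1, W_g = 0.1,
                                   W_r = 0.45, delta = 35), params)
    out <- fixture_index_series(full, times)
    out$total_length <- out$total_length * (1 + rnorm(length(times), 0, 0.02))
    out
  }
  grids <- list(tip_delay = c(1.6, 2.1))
  f1 <- grid_search_fit(grids, target, noisy_sim, seeds = c(1, 2, 3))
  f2 <- grid_search_fit(grids, target, noisy_sim, seeds = c(3, 1, 2))
  expect_equal(f1$surface$error, f2$surface$error, tolerance = 1e-12)
})

test_that("index time series over replicates report means and standard deviations", {
  cfg <- default_config()
  cfg$domain$nx <- 10; cfg$domain$nz <- 10
  cfg$time$t_end <- 1
  cfg$water$coupled <- FALSE
  ts1 <- index_timeseries(cfg, times = c(0.5, 1), seeds = c(4, 4))
  # identical seeds: zero spread
  expect_equal(ts1$total_length_sd, c(0, 0))
  # consistency with direct metric calls on a single run
  cfg$seed <- 4L
  sim <- simulate_rsa(cfg)
  direct <- network_indices(sim)
  expect_equal(ts1$total_length[2], direct$total_length, tolerance = 1e-9)
})

test_that("W_oi is recovered from reference growth-angle trajectories", {
  etas <- c(30, 45)
  refs <- lapply(etas, function(e) {
    b <- fixture_beta_trajectory(e, t0 = 1, t1 = 2, kappa = 2, W_oi = 5)
    b[b$time > 2, c("time", "beta")]
  })
  names(refs) <- etas
  sim_fn <- function(eta, W_oi, seed) {
    b <- fixture_beta_trajectory(eta, t0 = 1, t1 = 2, kappa = 2,
                                 W_oi = W_oi)
    b[b$time > 2, c("time", "beta")]
  }
  fit <- fit_w_oi(refs, grid = c(1.5, 2.5, 5, 7.5, 10), sim_fn)
  expect_equal(fit$best, 5)
  expect_equal(unname(fit$per_eta), c(5, 5))
  expect_equal(min(fit$errors["45", ]), 0, tolerance = 1e-18)
  # degenerate grid
  fit1 <- fit_w_oi(refs["45"], grid = 7.5, sim_fn)
  expect_equal(fit1$best, 7.5)
  # length mismatch triggers truncating alignment with a warning
  short_ref <- list("45" = refs[["45"]][1:10, ])
  expect_warning(fit_w_oi(short_ref, grid = 2.5, sim_fn), "truncat")
})
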