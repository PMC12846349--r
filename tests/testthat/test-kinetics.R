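make_curves <- function(times, ctrl, ...) {
  growth_curve_set(times, ctrl, list(...), window_end = max(times))
}

test_that("local virulence responds linearly to area suppression", {
  t <- seq(0, 120, by = 30)
  ctrl <- c(0.05, 0.1, 0.3, 0.6, 0.8)
  cs <- make_curves(t, ctrl, `1` = ctrl, `0.1` = ctrl * 0,
                    `0.01` = ctrl * 0.5)
  expect_equal(local_virulence(cs, 1)$v, 0)
  expect_equal(local_virulence(cs, 0.1)$v, 1)
  expect_equal(local_virulence(cs, 0.01)$v, 0.5)
  expect_error(local_virulence(cs, 7), "not present")
})

test_that("local virulence is monotone in pointwise OD suppression", {
  withr::local_seed(42)
  t <- seq(0, 180, by = 30)
  for (i in 1:20) {
    ctrl <- sort(runif(length(t), 0.05, 1))
    hi <- ctrl * runif(length(t), 0.2, 1)
    lo <- hi * runif(length(t), 0.2, 1)   # pointwise below hi
    cs <- make_curves(t, ctrl, `1` = hi, `0.1` = lo)
    expect_gte(local_virulence(cs, 0.1)$v, local_virulence(cs, 1)$v)
    expect_gte(local_virulence(cs, 0.1)$v, 0)
    expect_lte(local_virulence(cs, 0.1)$v, 1)
  }
})

test_that("virulence index is a normalized log-MOI trapezoid", {
  mois <- 10^seq(-7, 0)
  expect_equal(virulence_index(data.frame(moi = mois, v = rep(1, 8))), 1)
  expect_equal(virulence_index(data.frame(moi = mois, v = rep(0, 8))), 0)
  v <- c(0.17, 0.16, 0.20, 0.25, 0.68, 0.97, 0.92, 0.97)
  vi <- virulence_index(data.frame(moi = mois, v = v))
  # reordering the ladder must not change the integral
  shuf <- c(3, 8, 1, 5, 2, 7, 4, 6)
  expect_equal(virulence_index(data.frame(moi = mois[shuf], v = v[shuf])), vi)
  expect_error(virulence_index(data.frame(moi = c(1, 1), v = c(0, 1))),
               "duplicate")
  expect_error(virulence_index(data.frame(moi = 1, v = 1)), "at least two")
})

test_that("one_step recovers the step fixture by hand computation", {
  s <- titer_series(seq(0, 50, 10),
                    c(1e4, 1e4, 1e4, 6e5, 6e5, 6e5), n0 = 1e4)
  r <- one_step(s)
  expect_equal(r$latent_min, 20)
  expect_equal(r$rise_min, 10)
  expect_equal(r$plateau_titer, 6e5)
  expect_equal(r$burst_size, 60)
})

test_that("one_step rejects flat and burst-free series", {
  flat <- titer_series(seq(0, 50, 10), rep(1e4, 6), n0 = 1e4)
  expect_error(one_step(flat), "no burst")
  p <- infection_params(burst = 1, noise_sd = 0, seed = 4)
  expect_error(one_step(simulate_one_step(p)), "no burst")
})

test_that("one_step recovers simulator truth exactly without noise", {
  withr::local_seed(77)
  for (seed in 1:5) {
    L <- sample(c(10, 20, 30), 1)
    beta <- sample(c(20, 60, 150), 1)
    p <- infection_params(latent_min = L, burst = beta, noise_sd = 0,
                          seed = seed)
    os <- simulate_one_step(p, times = seq(0, 120, 10), n0 = 1e4)
    r <- one_step(os)
    truth <- attr(os, "truth")
    expect_equal(r$latent_min, truth$latent_min)
    expect_lt(abs(r$burst_size - truth$burst) / truth$burst, 0.01)
  }
})

test_that("adsorption reports fractions, percentages and the rate constant", {
  const <- titer_series(c(0, 5, 10, 15), rep(2e6, 4), n0 = 2e6)
  a <- adsorption(const, cell_density = 2e8)
  expect_equal(a$percent_adsorbed, rep(0, 4))
  expect_equal(a$rate_constant, 0)
  # the published 5-min anchor: P/P0 = 0.244 means 75.6% adsorbed
  s <- titer_series(c(0, 5), c(1e6, 0.244e6))
  expect_equal(adsorption(s)$percent_adsorbed[2], 75.6)
  expect_error(adsorption(titer_series(c(0, 5), c(0, 1))), "positive")
})

test_that("adsorption recovers a noiseless exponential rate to 1e-6", {
  for (k in c(1e-10, 3e-10, 2e-9)) {
    s <- simulate_adsorption(p0 = 1e6, k = k, cells = 2e8,
                             times = seq(0, 15), noise_sd = 0, seed = 1)
    a <- adsorption(s, cell_density = 2e8)
    expect_lt(abs(a$rate_constant - k) / k, 1e-6)
  }
})

test_that("biofilm inhibition matches the crystal-violet reduction formula", {
  expect_equal(biofilm_inhibition(c(1, 1), c(1, 1)), 0)
  expect_equal(biofilm_inhibition(rep(1, 3), rep(0.18, 3)), 82)
  expect_equal(biofilm_inhibition(rep(0.5, 3), rep(0.38, 3)), 24)
  # enhancement reported as-is
  expect_equal(biofilm_inhibition(c(1, 1), c(1.5, 1.5)), -50)
  expect_error(biofilm_inhibition(c(0, 0), c(1, 1)), "positive")
})

test_that("log reduction handles magnitudes, identity and censoring", {
  r <- log_reduction(7.0e8, 7.0e6)
  expect_equal(r$value, 2)
  expect_false(r$censored)
  expect_equal(log_reduction(5e5, 5e5)$value, 0)
  cen <- log_reduction(2.0e6, 0, lod = 10)
  expect_equal(cen$value, log10(2e5))
  expect_true(cen$censored)
  # additivity when uncensored
  expect_equal(log_reduction(1e8, 1e6)$value + log_reduction(1e6, 1e3)$value,
               log_reduction(1e8, 1e3)$value)
})

test_that("long-format tables rebuild a replicate-averaged curve set", {
  t <- seq(0, 90, 30)
  df <- expand.grid(time_min = t, condition = c("control", "0.1"),
                    replicate = 1:2, stringsAsFactors = FALSE)
  df$value <- ifelse(df$condition == "control",
                     0.1 + df$time_min / 100, 0.05) +
    0.01 * (df$replicate - 1.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  cs <- curves_from_table(read_assay_table(f), window_end = 90)
  expect_equal(cs$times, t)
  expect_equal(cs$control_od, 0.1 + t / 100)    # replicates averaged
  expect_equal(cs$moi_curves[["0.1"]], rep(0.05, 4))
})

test_that("stationary-phase onset detection finds the slope collapse", {
  t <- seq(0, 300, 30)
  od <- pmin(1, 0.05 * exp(t / 60))
  od <- pmin(od, 0.9)                      # saturates around t = 180
  w <- detect_window_end(t, od)
  expect_true(w >= 180 && w <= 270)
  # growth that never slows returns the final time
  expect_equal(detect_window_end(t, exp(t / 100)), 300)
})
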