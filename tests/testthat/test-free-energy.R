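test_that("equilibration discard keeps exactly the production samples", {
  s <- sample_series(0:499, rnorm(500))
  kept <- discard_equilibration(s, 100)
  expect_equal(nrow(kept), 400)
  expect_true(all(kept$time_ps >= 100))
  expect_identical(discard_equilibration(s, 0), s)
  expect_error(discard_equilibration(s, 1000), "no samples remain")
})

test_that("BAR is zero for identical work distributions and order-invariant", {
  w <- c(1.3, -0.2, 2.5, 0.7, 1.1)
  ws <- work_set(w, w, beta = 1, unit = "reduced")
  expect_equal(bar_estimate(ws)$delta_g, 0, tolerance = 1e-9)

  set.seed(13)
  wf <- rnorm(500, 2, 1)
  wr <- rnorm(400, -1, 1)
  a <- bar_estimate(work_set(wf, wr, beta = 1, unit = "reduced"))
  b <- bar_estimate(work_set(sample(wf), sample(wr), beta = 1,
                             unit = "reduced"))
  expect_equal(a$delta_g, b$delta_g, tolerance = 1e-9)
})

test_that("BAR recovers the Gaussian/Crooks closed form", {
  # forward ~ N(mu, sigma^2) with beta = 1 implies dF = mu - sigma^2/2
  sigma <- 2
  d_f <- 3
  ws <- gaussian_work_samples(d_f, sigma, 2e4, beta = 1, seed = 42)
  est <- bar_estimate(ws)
  se <- gaussian_bar_se(d_f, sigma, 2e4)
  expect_lt(abs(est$delta_g - d_f), 3 * se)
  # the reported asymptotic uncertainty agrees with the analytic one
  expect_equal(est$uncertainty, se, tolerance = 0.2)
})

test_that("BAR agrees with an independent fixed-point route to 1e-6", {
  for (seed in c(1, 7, 19)) {
    ws <- gaussian_work_samples(2, 1.5, 5000, seed = seed)
    est <- bar_estimate(ws)$delta_g
    ref <- bar_fixed_point(ws$forward, ws$backward, beta = 1)
    expect_lt(abs(est - ref), 1e-6)
  }
})

test_that("BAR sits between the EXP estimates on seed average in the
           strongly dissipative regime", {
  seeds <- 1:20
  bar <- expf <- expr <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    ws <- gaussian_work_samples(2, 3, 500, seed = seeds[i])
    bar[i] <- bar_estimate(ws)$delta_g
    expf[i] <- -log(mean(exp(-ws$forward)))
    expr[i] <- log(mean(exp(-ws$backward)))
  }
  expect_lte(mean(expr), mean(bar))
  expect_lte(mean(bar), mean(expf))
})

test_that("non-overlapping work distributions raise a convergence error", {
  ws <- work_set(rnorm(100, 1e5, 0.1), rnorm(100, 1e5, 0.1),
                 beta = 1, unit = "reduced")
  expect_error(bar_estimate(ws), "overlap")
})

test_that("TI trapezoid is exact for affine profiles on any grid", {
  grid <- sort(c(0, runif(20), 1))
  ls_const <- lambda_series(grid, lapply(grid, function(l) rep(3.5, 10)))
  expect_equal(ti_integrate(ls_const)$delta_g, 3.5, tolerance = 1e-12)

  ls_lin <- lambda_series(grid, lapply(grid, function(l) rep(2 * l, 10)))
  expect_equal(ti_integrate(ls_lin)$delta_g, 1, tolerance = 1e-12)

  expect_error(lambda_series(c(0, 0.5, 0.5, 1), as.list(1:4)),
               "strictly increasing")
  expect_error(lambda_series(c(0, 1.5), as.list(1:2)), "\\[0, 1\\]")
  expect_error(ti_integrate(lambda_series(0.5, list(1))), "2 windows")
})

test_that("TI on 85 windows matches dense-grid quadrature for smooth input", {
  co <- c(1, -2, 3, -1.5)
  ls <- synthetic_dhdl("cubic", co)
  est <- ti_integrate(ls)
  dense <- synthetic_dhdl("cubic", co,
                          lambda_grid = seq(0, 1, length.out = 4001),
                          n_samples = 1)
  ref <- ti_integrate(dense)$delta_g
  expect_lt(abs(est$delta_g - ref) / abs(ref), 1e-4)
})

test_that("forward/backward spread is the two-point sample sd", {
  expect_equal(forward_backward_sd(5, 5), 0)
  expect_equal(forward_backward_sd(10, 12), sqrt(2), tolerance = 1e-12)
  expect_equal(forward_backward_sd(12, 10), forward_backward_sd(10, 12))
  e1 <- fe_estimate(10, method = "TI")
  e2 <- fe_estimate(12, method = "TI")
  expect_equal(forward_backward_sd(e1, e2), sqrt(2), tolerance = 1e-12)
})

test_that("time slices agree for stationary input and cover the total", {
  ls <- synthetic_dhdl("linear", c(0, 2), n_samples = 50, spacing_ps = 10,
                       noise_sigma = 0.5, seed = 3)
  sl <- slice_convergence(ls, list(c(0, 490), c(0, 240), c(250, 490)))
  expect_true(all(is.na(sl$error)))
  # full-range slice reproduces the full estimate
  expect_equal(sl$delta_g[1], ti_integrate(ls)$delta_g, tolerance = 1e-12)
  # stationary halves agree within 3 combined analytic standard errors:
  # each window mean over 25 samples has sd 0.5/sqrt(25); trapezoid weights
  # on a uniform 85-point grid give var = sum(w^2) * var(mean)
  w <- diff(ls$lambda)
  wts <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)
  se_half <- sqrt(sum(wts^2) * (0.5^2 / 25))
  expect_lt(abs(sl$delta_g[2] - sl$delta_g[3]), 3 * sqrt(2) * se_half)
})

test_that("planted drift between slices is visible as excess spread", {
  # mean shifts by +1 between the first and second half of every window
  lam <- seq(0, 1, length.out = 11)
  series <- lapply(lam, function(l) {
    sample_series(0:49 * 10, c(rep(l, 25), rep(l + 1, 25)))
  })
  ls <- lambda_series(lam, series)
  sl <- slice_convergence(ls, list(c(0, 240), c(250, 490)))
  expect_equal(sl$delta_g[2] - sl$delta_g[1], 1, tolerance = 1e-9)
  # an empty slice reports its error and leaves others intact
  sl2 <- slice_convergence(ls, list(c(0, 240), c(5000, 6000)))
  expect_true(is.na(sl2$delta_g[2]))
  expect_match(sl2$error[2], "empty slice")
  expect_equal(sl2$delta_g[1], sl$delta_g[1])
})

test_that("snapshot subsampling walks the stride grid", {
  times <- seq(0, 99900, by = 100) # 100 ns at 100 ps spacing
  idx <- subsample_snapshots(times, start_ps = 10000, stride_ps = 100)
  expect_equal(length(idx), 900)
  expect_true(all(diff(idx) > 0))
  expect_true(all(times[idx] >= 10000))

  expect_lte(length(subsample_snapshots(times, 0, 1e9)), 1)
  # off-grid stride keeps times within one frame of the requested grid
  idx2 <- subsample_snapshots(times, 0, 250)
  expect_true(all(diff(times[idx2]) >= 250))
})

test_that("work sets validate input and derive beta from units", {
  expect_error(work_set(numeric(0), 1), "required")
  expect_error(work_set(c(1, NA), c(1, 2)), "finite")
  expect_equal(work_set(1, 1)$beta, 1 / (0.0083144621 * 300),
               tolerance = 1e-9)
  expect_equal(work_set(1, 1, unit = "kcal/mol", temperature_K = 400)$beta,
               4.184 / (0.0083144621 * 400), tolerance = 1e-9)
})
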