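test_that("detrending removes exactly the least-squares line per run", {
  t10 <- 1:10
  vals <- rbind(2 + 3 * t10,            # pure line -> zero residual
                rep(0, 10),             # already centred flat -> unchanged
                t10^2)                  # quadratic -> lm residual oracle
  ts <- ts_from_matrix(vals)
  out <- detrend(ts)
  expect_equal(out$values[1, ], rep(0, 10), tolerance = 1e-10)
  expect_equal(out$values[2, ], rep(0, 10), tolerance = 1e-10)
  oracle <- stats::residuals(stats::lm(I(t10^2) ~ t10))
  expect_equal(out$values[3, ], unname(oracle), tolerance = 1e-8)

  # two runs are detrended independently, each to mean zero
  ts2 <- ts_from_matrix(matrix(rnorm(3 * 20), 3), run_boundaries = c(0, 12))
  out2 <- detrend(ts2)
  expect_lt(max(abs(rowMeans(out2$values[, 1:12]))), 1e-10)
  expect_lt(max(abs(rowMeans(out2$values[, 13:20]))), 1e-10)

  short <- ts_from_matrix(matrix(1, 2, 4), run_boundaries = c(0, 2))
  expect_error(detrend(short), "too short")
})

test_that("low-pass filter has unit DC gain and the Butterworth response", {
  tr <- 2.16
  n <- 400
  tt <- (seq_len(n) - 1) * tr
  const <- ts_from_matrix(matrix(5, 2, n), frame_interval = tr)
  expect_equal(lowpass(const)$values, const$values, tolerance = 1e-8)

  # passband: 0.01 Hz sinusoid survives within 1%
  x <- sin(2 * pi * 0.01 * tt)
  out <- lowpass(ts_from_matrix(rbind(x, x), frame_interval = tr))
  mid <- 80:320
  expect_lt(abs(max(abs(out$values[1, mid])) - 1), 0.01)

  # stopband: 0.2 Hz amplitude matches the squared analytic magnitude
  # response of the 2nd-order Butterworth evaluated at that frequency
  y <- sin(2 * pi * 0.2 * tt)
  outy <- lowpass(ts_from_matrix(rbind(y, y), frame_interval = tr))
  bf <- signal::butter(2, 0.1 / (1 / (2 * tr)), type = "low")
  w <- 2 * pi * 0.2 * tr
  H <- sum(bf$b * exp(-1i * w * (0:2))) / sum(bf$a * exp(-1i * w * (0:2)))
  gain <- Mod(H)^2                       # forward + backward pass
  expect_equal(max(abs(outy$values[1, mid])), gain, tolerance = 0.05)

  expect_error(lowpass(const, cutoff = 0.5), "Nyquist")
})

test_that("nuisance regression matches the least-squares oracle", {
  set.seed(42)
  n <- 50
  R <- cbind(rnorm(n), rnorm(n))
  ts <- ts_from_matrix(rbind(
    R[, 1],                                   # equals a regressor
    rnorm(n),                                 # generic
    3 + 2 * R[, 1] - R[, 2] + rnorm(n)))      # mixed
  out <- regress_nuisance(ts, R)
  expect_lt(max(abs(out$values[1, ])), 1e-8)
  for (i in 2:3) {
    oracle <- stats::residuals(stats::lm(ts$values[i, ] ~ R))
    expect_equal(out$values[i, ], unname(oracle), tolerance = 1e-8)
  }

  # a series orthogonal to intercept and regressors passes through
  v <- rnorm(n)
  v <- stats::residuals(stats::lm(v ~ R))
  out2 <- regress_nuisance(ts_from_matrix(rbind(v, v)), R)
  expect_equal(out2$values[1, ], as.numeric(v), tolerance = 1e-8)

  expect_error(regress_nuisance(ts, cbind(a = R[, 1], b = R[, 1])),
               "rank deficient")
})

test_that("DVARS follows the RMS-difference formula with strict censoring", {
  const <- ts_from_matrix(matrix(1000, 8, 40))
  cen <- compute_dvars(const)
  expect_equal(cen$dvars, rep(0, 40))
  expect_true(all(cen$keep))

  # 20-unit spike on a mode-1000 series: DVARS 2% at the two transitions
  spiked <- inject_spikes(const, 10, 20)
  cen2 <- compute_dvars(spiked)
  expect_equal(cen2$dvars[11], 2.0)          # into the spike (0-based 10)
  expect_equal(cen2$dvars[12], 2.0)          # out of it
  expect_identical(which(!cen2$keep), c(11L, 12L))
  # optionally the frame before the corrupted transition goes too
  cen2b <- compute_dvars(spiked, censor_preceding = TRUE)
  expect_identical(which(!cen2b$keep), c(10L, 11L, 12L))

  # exactly at threshold is kept: "greater than" is strict
  border <- inject_spikes(const, 10, 5)      # DVARS exactly 0.5
  cen3 <- compute_dvars(border)
  expect_equal(cen3$dvars[11], 0.5)
  expect_true(all(cen3$keep))

  # the first frame of each run has DVARS 0 and large cross-run jumps
  # never censor anything
  tworun <- ts_from_matrix(cbind(matrix(1000, 4, 10), matrix(1900, 4, 10)),
                           run_boundaries = c(0, 10))
  cen4 <- compute_dvars(tworun)
  expect_equal(cen4$dvars[11], 0)
  expect_true(all(cen4$keep))
})

test_that("censoring affects which frames enter the correlation", {
  set.seed(1)
  base <- matrix(rnorm(3 * 30), 3)
  ts <- ts_from_matrix(1000 + base)
  spiked <- inject_spikes(ts, 15, 50)
  cen <- compute_dvars(spiked)
  cm <- correlation_map(spiked, cen)
  keep <- cen$keep
  oracle <- pearson_oracle(spiked$values[1, keep], spiked$values[2, keep])
  expect_equal(cm$r[1, 2], oracle, tolerance = 1e-12)
  # dvars of untouched transitions is what it was before the spike
  cen0 <- compute_dvars(ts)
  expect_equal(cen$dvars[-(15:17)], cen0$dvars[-(15:17)])
})

test_that("correlation map is an entrywise Pearson matrix", {
  vals <- rbind(c(1.0, 2.0, 3.0, 4.0, 5.0),
                c(5.5, 4.4, 3.3, 2.2, 1.1),
                c(2.0, 1.0, 4.0, 3.0, 5.0))
  ts <- ts_from_matrix(vals)
  cm <- correlation_map(ts)
  expect_equal(diag(cm$r), rep(1, 3))
  expect_equal(cm$r, t(cm$r))
  for (i in 1:3) for (j in 1:3)
    expect_equal(cm$r[i, j], pearson_oracle(vals[i, ], vals[j, ]),
                 tolerance = 1e-12)

  # an exactly anti-proportional pair gives -1
  anti <- ts_from_matrix(rbind(1:5, -(1:5) + 10))
  expect_equal(correlation_map(anti)$r[1, 2], -1)

  flat <- ts_from_matrix(rbind(1:5, rep(2, 5)))
  expect_error(correlation_map(flat), "zero-variance voxel")
})

test_that("group averaging is the entrywise mean preserving structure", {
  set.seed(9)
  ts <- ts_from_matrix(matrix(rnorm(4 * 20), 4))
  m1 <- correlation_map(ts)
  expect_equal(group_average(list(m1))$r, m1$r)

  neg <- m1$r * -1; diag(neg) <- 1
  avg <- group_average(list(m1, corr_map(neg)))
  expect_equal(avg$r, diag(4))

  ts2 <- ts_from_matrix(matrix(rnorm(4 * 20), 4))
  m2 <- correlation_map(ts2)
  expect_equal(group_average(list(m1, m2))$r, (m1$r + m2$r) / 2)
  expect_error(group_average(list(m1, corr_map(diag(3)))), "size")
})
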