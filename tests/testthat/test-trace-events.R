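test_that("Savitzky-Golay smoothing is exact on polynomials up to order 3", {
  x <- seq(0, 10, length.out = 200)
  expect_equal(smoothTrace(rep(2, 200)), rep(2, 200))
  for (poly in list(function(t) 3 + t,
                    function(t) 1 - 2 * t + 0.5 * t^2 - 0.1 * t^3)) {
    y <- poly(x)
    sm <- smoothTrace(y)
    interior <- 11:190
    expect_lt(max(abs(sm[interior] - y[interior])) / max(abs(y)), 1e-12)
  }
  expect_error(smoothTrace(rnorm(10)), "shorter")
})

test_that("smoothing attenuates white noise by the filter's coefficient norm", {
  # oracle: central SG coefficients from an explicit least-squares
  # polynomial fit; the smoothed variance of unit white noise is their
  # squared sum
  w <- 21; ord <- 3
  X <- outer(-(w %/% 2):(w %/% 2), 0:ord, `^`)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  coef <- H[w %/% 2 + 1, ]
  expectedVar <- sum(coef^2)
  set.seed(42)
  v <- replicate(40, {
    sm <- smoothTrace(rnorm(2000))
    stats::var(sm[50:1950])
  })
  expect_lt(abs(mean(v) - expectedVar) / expectedVar, 0.05)
})

test_that("baseline search finds the quietest window with earliest tie-break", {
  fr <- 10
  expect_equal(detectBaseline(rep(1, 400), fr)$startFrame, 1)
  expect_equal(detectBaseline(rep(1, 400), fr)$sd, 0)
  # planted quiet segment
  set.seed(7)
  x <- rnorm(600, 1, 0.05)
  x[301:400] <- rnorm(100, 1, 0.005)
  bl <- detectBaseline(x, fr)
  expect_gte(bl$startFrame, 290)
  expect_lte(bl$endFrame, 410)
  # restricted to pre-stimulus data
  bl2 <- detectBaseline(x, fr, stimulusOnset = 12)
  expect_lte(bl2$end, 12)
  expect_error(detectBaseline(x, fr, stimulusOnset = 5), "insufficient")
})

test_that("segment detection finds isolated and paired transients", {
  fr <- 10; n <- 1200
  bl <- list(mean = 1, sd = 0.01, startFrame = 1, endFrame = 100)
  expect_equal(nrow(detectEventSegments(rep(1, n), bl, fr)), 0)
  one <- renderEmg(n, fr, mu = 60, sigma = 0.5, tau = 1.5,
                   amplitude = 0.5)
  seg <- detectEventSegments(one, bl, fr)
  expect_equal(nrow(seg), 1)
  two <- one + renderEmg(n, fr, mu = 70, sigma = 0.5, tau = 1.5,
                         amplitude = 0.5) - 1
  expect_equal(nrow(detectEventSegments(two, bl, fr)), 2)
})

test_that("detected peak lands within 0.2 s of the true transient peak", {
  fr <- 10; n <- 600
  set.seed(11)
  noise <- 0.02
  y <- renderEmg(n, fr, mu = 40, sigma = 0.5, tau = 1.5,
                 amplitude = 10 * noise * 5, noiseSd = noise)
  ts <- TraceSet(matrix(y, ncol = 1), fr, stimulusOnset = 20)
  ev <- detectEvents(ts)
  expect_equal(nrow(ev), 1)
  # true peak of the rendered shape
  tg <- (seq_len(n) - 1) / fr
  truePeak <- tg[which.max(renderEmg(n, fr, 40, 0.5, 1.5, 1))]
  expect_lt(abs(ev$peak_time - truePeak), 0.2)
})

test_that("EMG fitting recovers shape parameters on noiseless transients", {
  fr <- 10; n <- 800
  y <- renderEmg(n, fr, mu = 40, sigma = 0.3, tau = 1.0, amplitude = 1)
  ts <- TraceSet(matrix(y, ncol = 1), fr, stimulusOnset = 20)
  ev <- detectEvents(ts)
  expect_equal(nrow(ev), 1)
  expect_true(ev$fit_ok)
  expect_lt(abs(ev$sigma - 0.3) / 0.3, 0.05)
  expect_lt(abs(ev$tau - 1.0) / 1.0, 0.05)
})

test_that("Gaussian-limit FDHM matches the closed form", {
  # as tau -> 0 the EMG tends to a Gaussian whose FDHM is 2 sqrt(2 ln 2) s
  fr <- 20; n <- 1600; sigma <- 0.8
  y <- renderEmg(n, fr, mu = 40, sigma = sigma, tau = 1e-4, amplitude = 1)
  ts <- TraceSet(matrix(y, ncol = 1), fr, stimulusOnset = 20)
  ev <- detectEvents(ts)
  expect_equal(nrow(ev), 1)
  closedForm <- 2 * sqrt(2 * log(2)) * sigma
  expect_lt(abs(ev$fdhm - closedForm) / closedForm, 0.01)
  expect_lt(abs(ev$fit_fdhm - closedForm) / closedForm, 0.01)
})

test_that("a 3-frame blip falls back to empirical metrics", {
  fr <- 10; n <- 400
  x <- rep(1, n)
  x[200:202] <- c(1.3, 1.5, 1.3)
  bl <- list(mean = 1, sd = 0.01, startFrame = 1, endFrame = 100)
  seg <- detectEventSegments(x, bl, fr)
  expect_equal(nrow(seg), 1)
  fit <- fitEvent(seg[1, ], x, bl, fr)
  expect_false(fit$fit_ok)
  expect_gt(fit$amplitude, 0)
})

test_that("cell summaries compute frequencies over the exposure interval", {
  ev <- data.frame(cell_id = c(rep("a", 6), "b"),
                   peak_time = c(seq(70, 170, length.out = 6), 10),
                   amplitude = c(1:6 / 10, 2), fdhm = rep(2, 7),
                   fit_ok = TRUE)
  s <- summarizeCells(ev, c("a", "b"), exposure = c(60, 180))
  expect_equal(s$frequency[s$cell_id == "a"], 3)       # 6 events / 2 min
  expect_equal(s$event_count[s$cell_id == "b"], 0)     # outside interval
  expect_true(is.na(s$mean_amplitude[s$cell_id == "b"]))
})

test_that("event frequency is invariant to amplitude rescaling", {
  cfg <- simulationConfig(nCells = 25, imageSize = 120, duration = 90,
                          rngSeed = 9)
  sim <- simulateTissue(cfg, "ACh", 1e-5)
  ev1 <- detectEvents(sim$traces)
  scaled <- TraceSet(traceMatrix(sim$traces) * 7.3, frameRate(sim$traces),
                     stimulusOnset(sim$traces))
  ev2 <- detectEvents(scaled)
  expect_equal(nrow(ev1), nrow(ev2))
  expect_equal(ev1$peak_time, ev2$peak_time, tolerance = 1e-8)
})
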