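test_that("responsiveness requires five consecutive supra-threshold bins", {
  ## zero background, spikes in exactly 4 consecutive 2 ms bins -> not
  ## responsive; a 5th bin alone does not suffice without the paired test
  tilts <- rep(1:4, each = 5)
  mk <- function(binTimes) {
    times <- lapply(tilts, function(tt)
      if (tt == 1) binTimes else numeric())
    singleNeuronSession(tilts, times)
  }
  fourBins <- mk(c(1, 3, 5, 7))
  expect_false(detectResponsive(fourBins, "n1", 1)$responsive)
  expect_error(peakResponseLatency(fourBins, "n1", 1), "not responsive")
})

test_that("a strong bump is detected with a window covering it", {
  ns <- neuronSpec("n1", "direct", 5, c(50, 0, 0, 0), rep(80, 4), 3, 10)
  hits <- vapply(1:5, function(seed) {
    s <- simulateSession(ns, 0, 400, seed = 400 + seed)
    det <- detectResponsive(s, "n1", 1)
    det$responsive && det$window[1] <= 80 && det$window[2] >= 80
  }, logical(1))
  expect_true(all(hits))
  ## and the non-preferred tilt shows nothing
  s <- simulateSession(ns, 0, 400, seed = 401)
  expect_false(detectResponsive(s, "n1", 2)$responsive)
})

test_that("flat Poisson neurons are rarely called responsive", {
  ns <- neuronSpec("n1", "direct", 8, rep(0, 4), rep(60, 4), 0, 15)
  fp <- vapply(1:150, function(seed) {
    s <- simulateSession(ns, 0, 100, seed = 500 + seed)
    detectResponsive(s, "n1", 1)$responsive
  }, logical(1))
  expect_lte(mean(fp), 0.05)
})

test_that("peak response and latency follow their definitions", {
  ## 1 spike at +11 ms on every trial, zero background
  tilts <- rep(1:4, each = 5)
  s <- singleNeuronSession(tilts, replicate(length(tilts), 11))
  pk <- peakResponseLatency(s, "n1", 1, check = FALSE)
  expect_equal(pk$PR, 1.0)
  expect_equal(pk$PL, 11) # centre of bin [10, 12)
  ## uniform activity everywhere -> PR = 0
  uni <- singleNeuronSession(tilts,
                             replicate(length(tilts),
                                       seq(-199, 199, by = 2),
                                       simplify = FALSE))
  pku <- peakResponseLatency(uni, "n1", 1, check = FALSE)
  expect_equal(pku$PR, 0)
})

test_that("PR is invariant to a uniform added count in response and background", {
  tilts <- rep(1:4, each = 5)
  base <- singleNeuronSession(tilts, replicate(length(tilts), c(11, 11),
                                               simplify = FALSE))
  plus <- singleNeuronSession(tilts,
                              lapply(seq_along(tilts), function(i)
                                c(11, 11, seq(-199, 199, by = 2))))
  p0 <- peakResponseLatency(base, "n1", 1, check = FALSE)
  p1 <- peakResponseLatency(plus, "n1", 1, check = FALSE)
  expect_equal(p0$PR, p1$PR)
  expect_equal(p0$PL, p1$PL)
})

test_that("peak latency is recovered from simulated tuning", {
  ns <- neuronSpec("n1", "direct", 3, c(40, 0, 0, 0), rep(60, 4), 3, 8)
  pls <- vapply(1:20, function(seed) {
    s <- simulateSession(ns, 0, 400, seed = 600 + seed)
    peakResponseLatency(s, "n1", 1, check = FALSE)$PL
  }, numeric(1))
  expect_true(all(abs(pls - 60) <= 10))
})

test_that("most responsive tilt is kept, one observation per neuron", {
  ns <- neuronSpec("n1", "direct", 4, c(50, 25, 0, 0), rep(70, 4), 3, 10)
  s <- simulateSession(ns, 0, 400, seed = 77)
  rp <- responseProfiles(s)
  expect_equal(nrow(rp), 1)
  expect_true(rp$responsive[1])
  expect_equal(rp$tilt_type[1], 1L)
})

test_that("normalized variance matches Poisson, constant and mixture cases", {
  ## Poisson counts -> NV near 1
  ns <- neuronSpec("n1", "direct", 15, rep(0, 4), rep(60, 4), 0, 15)
  s <- simulateSession(ns, 0, 1000, seed = 88)
  nv <- normalizedVariance(s, "n1", 1, firstN = Inf)
  expect_gt(nv$nv, 0.85)
  expect_lt(nv$nv, 1.15)
  ## identical count every trial -> exactly 0
  tilts <- rep(1:4, each = 12)
  cst <- singleNeuronSession(tilts,
                             replicate(length(tilts), c(-150, -50),
                                       simplify = FALSE))
  expect_equal(normalizedVariance(cst, "n1", 1, firstN = Inf)$nv, 0)
  ## 50/50 mixture of rates doubles the count Fano factor:
  ## var = mean_within + var_between = m + (d/2)^2 with means m +/- d/2
  tilts2 <- rep(1L, 400)
  lam <- rep(c(4, 12), 200)
  set.seed(99)
  counts <- rpois(400, lam)
  times <- lapply(counts, function(k) runif(k, -200, 0))
  mix <- singleNeuronSession(c(tilts2, 2L, 2L, 3L, 3L, 4L, 4L),
                             c(times, replicate(6, numeric())))
  nvMix <- normalizedVariance(mix, "n1", 1, firstN = Inf)$nv
  expected <- (8 + 16) / 8 # (mean + between-variance) / mean
  expect_equal(nvMix, expected, tolerance = 0.25)
  expect_error(normalizedVariance(cst, "n1", 1, firstN = 5), ">= 10 trials")
})

test_that("z-scoring against baseline matches hand computation", {
  expect_equal(zscoreToBaseline(3, c(1, 3, 5)), 0)
  expect_equal(zscoreToBaseline(5, c(1, 3, 5)), 1)
  base <- c(2, 4, 6, 8, 10) # mean 6, sd sqrt(10)
  expect_equal(zscoreToBaseline(9, base), 3 / sqrt(10))
  expect_warning(z <- zscoreToBaseline(1, c(2, 2)), "zero baseline SD")
  expect_true(is.na(z))
  expect_error(zscoreToBaseline(1, 2), ">= 2 observations")
})

test_that("per-day hemisphere variance averages four per-tilt z-scores", {
  ns <- defaultNeurons(2, seed = 111)
  sess <- list("0" = simulateSession(ns, 0, 80, seed = 112),
               "1" = simulateSession(ns, 1, 80, seed = 113))
  v <- varianceByDay(sess, "direct", firstN = Inf)
  expect_equal(nrow(v), 8) # 2 days x 4 tilts
  d1 <- v[v$day == 1, ]
  expect_equal(unique(d1$day_mean), mean(d1$z))
})
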