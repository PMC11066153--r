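test_that("mutual information closed forms and oracle agreement", {
  expect_equal(mutualInformation(confusionMatrix(diag(100L, 4))), 2,
               tolerance = 1e-14)
  expect_equal(mutualInformation(confusionMatrix(matrix(25L, 4, 4))), 0,
               tolerance = 1e-14)
  ## 2-class structure padded into the 4x4 matrix
  m <- matrix(0L, 4, 4)
  m[1:2, 1:2] <- c(30L, 10L, 10L, 30L)
  cm <- confusionMatrix(m)
  expect_equal(mutualInformation(cm), 0.75 * log2(1.5) - 0.25) # 0.1887219
  expect_equal(mutualInformation(cm), bfMutualInfo(confusionCounts(cm)))
  expect_error(mutualInformation(matrix(0, 4, 4)), "no counts")
})

test_that("mutual information is bounded and permutation-invariant", {
  set.seed(7)
  for (i in 1:300) {
    m <- matrix(rpois(16, sample(c(1, 5, 40), 1)), 4, 4)
    if (sum(m) == 0) next
    mi <- mutualInformation(m)
    expect_gte(mi, 0)
    expect_lte(mi, 2)
    p <- sample(4)
    expect_equal(mutualInformation(m[p, p]), mi)
    expect_equal(mi, bfMutualInfo(m))
  }
})

test_that("bias estimate is reproducible and positive for separable data", {
  ## perfectly separable one-hot responses
  y <- rep(1:4, times = 10)
  X <- diag(4)[y, ]
  a <- biasCorrectedInformation(X, y, nShuffles = 1, seed = 5)
  b <- biasCorrectedInformation(X, y, nShuffles = 1, seed = 5)
  expect_equal(infoBias(a), infoBias(b))
  full <- biasCorrectedInformation(X, y, nShuffles = 20, seed = 5)
  expect_equal(rawInfo(full), 2)
  expect_gt(infoBias(full), 0)
  expect_equal(correctedInfo(full), 2 - infoBias(full))
  expect_true(isIncluded(full))
  expect_error(biasCorrectedInformation(X[1:5, ], y[1:5]), ">= 2 trials")
})

test_that("label-independent responses give near-zero corrected information", {
  vals <- vapply(1:5, function(seed) {
    ns <- neuronSpec("n1", "direct", 8, rep(0, 4), rep(60, 4), 0, 15)
    s <- simulateSession(ns, 0, 200, seed = 90 + seed)
    tc <- timingAndCountInformation(s, "n1", firstN = Inf, nShuffles = 20,
                                    seed = seed)
    correctedInfo(tc$timing)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("timing and count information dissociate by tuning type", {
  ## rate-only tuning: same latency, different amplitudes
  rateN <- neuronSpec("n1", "direct", 4, c(45, 4, 4, 4), rep(60, 4), 4, 15)
  ## latency-only tuning: equal amplitude, distinct latencies
  latN <- neuronSpec("n1", "direct", 4, rep(35, 4), c(30, 80, 130, 180),
                     4, 12)
  res <- vapply(1:4, function(seed) {
    sr <- simulateSession(rateN, 0, 240, seed = 100 + seed)
    sl <- simulateSession(latN, 0, 240, seed = 200 + seed)
    tr <- timingAndCountInformation(sr, "n1", firstN = Inf,
                                    nShuffles = 20, seed = seed)
    tl <- timingAndCountInformation(sl, "n1", firstN = Inf,
                                    nShuffles = 20, seed = seed)
    c(rateTemporal = tr$temporal,
      latCount = correctedInfo(tl$count),
      latTiming = correctedInfo(tl$timing))
  }, numeric(3))
  expect_lt(abs(mean(res["rateTemporal", ])), 0.1)
  expect_lt(abs(mean(res["latCount", ])), 0.05)
  expect_gt(mean(res["latTiming", ]), 0.5)
})

test_that("single-neuron ensembles have P = 0 exactly", {
  ns <- neuronSpec("n1", "direct", 5, c(40, 0, 0, 0), rep(60, 4), 5, 15)
  s <- simulateSession(ns, 0, 120, seed = 17)
  red <- ensembleRedundancy(s, "direct", firstN = Inf, nShuffles = 10,
                            seed = 3)
  expect_identical(red@P, 0)
  expect_identical(red@redundancy, 0)
  expect_equal(red@nIncluded, 1L)
})

test_that("duplicated neurons are more redundant than complementary ones", {
  specA <- neuronSpec("a", "direct", 5, c(40, 0, 0, 0), rep(60, 4), 5, 15)
  specB <- neuronSpec("b", "direct", 5, c(0, 40, 0, 0), rep(60, 4), 5, 15)
  mkPair <- function(duplicated, seed) {
    if (duplicated) {
      ## identical spike trains: copy neuron a's spikes under a new id
      s <- simulateSession(specA, 0, 160, seed = seed)
      dup <- spikeTable(s)
      dup$neuron_id <- "b"
      sessionRecording("x", 0, trialTable(s),
                       rbind(spikeTable(s), dup),
                       data.frame(neuron_id = c("a", "b"),
                                  hemisphere = "direct"))
    } else {
      ## two neurons tuned to different tilts, one shared trial sequence
      simulateSession(rbind(specA, specB), 0, 160, seed = seed)
    }
  }
  redOf <- function(s, seed) ensembleRedundancy(s, "direct", firstN = Inf,
                                                nShuffles = 10,
                                                seed = seed)@redundancy
  dupRed <- vapply(1:3, function(i) redOf(mkPair(TRUE, 300 + i), i),
                   numeric(1))
  disRed <- vapply(1:3, function(i) redOf(mkPair(FALSE, 300 + i), i),
                   numeric(1))
  expect_true(all(dupRed > 0))
  expect_gt(mean(dupRed), mean(disRed))
})

test_that("information-redundancy correlation behaves like Pearson r", {
  expect_equal(infoRedundancyCorrelation(1:5, 1:5 * 2), 1)
  expect_equal(infoRedundancyCorrelation(1:5, -(1:5)), -1)
  x <- c(0.2, 0.5, 0.3, 0.9, 0.7)
  y <- c(1.1, 0.4, 0.8, 0.2, 0.6)
  byHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(infoRedundancyCorrelation(x, y), byHand)
  expect_warning(r <- infoRedundancyCorrelation(c(1, 1, 1), 1:3),
                 "zero variance")
  expect_true(is.na(r))
  expect_error(infoRedundancyCorrelation(1:2, 1:2), ">= 3 days")
})
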