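test_that("first-n filter keeps a prefix of trials and their spikes", {
  ns <- defaultNeurons(1, seed = 5)
  s <- simulateSession(ns, 0, 400, seed = 6)
  f <- filterFirstN(s, 300)
  expect_equal(nrow(trialTable(f)), 300)
  expect_equal(max(trialTable(f)$trial_id), 300L)
  expect_identical(trialTable(f), trialTable(s)[1:300, ])
  expect_true(all(spikeTable(f)$trial_id <= 300))
  ## shorter sessions pass through whole
  s2 <- simulateSession(ns, 0, 248, seed = 7)
  expect_identical(filterFirstN(s2, 300), s2)
})

test_that("performance normalisation anchors the reference day at zero", {
  srs <- data.frame(day = 1:3, accuracy = c(0.30, 0.40, 0.40))
  out <- normalizePerformance(srs, 1)
  expect_equal(out$normalized, c(0, 0.10, 0.10))
  cst <- normalizePerformance(data.frame(day = 0:2, accuracy = 0.5), 0)
  expect_equal(cst$normalized, rep(0, 3))
  expect_error(normalizePerformance(srs, 9), "not present")
})

test_that("learner rule needs five consecutive days above day one", {
  mk <- function(acc) data.frame(day = seq_along(acc), accuracy = acc)
  ## days 3-7 all above day 1
  expect_equal(classifyLearner(mk(c(.3, .25, .35, .36, .37, .38, .39, .2))),
               "learner")
  ## alternating above/below, max run 4
  alt <- c(.3, .4, .4, .4, .4, .2, .4, .4, .4, .4, .2)
  expect_equal(classifyLearner(mk(alt)), "nonlearner")
  expect_equal(classifyLearner(mk(rep(.3, 10))), "nonlearner")
  expect_error(classifyLearner(mk(c(.3, .4, .5))), "at least 5")
  ## ties are not improvement under the strict comparator
  expect_equal(classifyLearner(mk(c(.3, .3, .3, .3, .3, .3, .3))),
               "nonlearner")
  expect_equal(classifyLearner(mk(c(.3, .3, .3, .3, .3, .3, .3)),
                               strict = FALSE), "learner")
})

test_that("raising any day's performance never turns a learner into a nonlearner", {
  set.seed(13)
  for (i in 1:50) {
    acc <- runif(12, 0.2, 0.8)
    srs <- data.frame(day = 1:12, accuracy = acc)
    before <- classifyLearner(srs)
    j <- sample(2:12, 1)
    srs$accuracy[j] <- srs$accuracy[j] + runif(1, 0, 0.2)
    after <- classifyLearner(srs)
    if (before == "learner") expect_equal(after, "learner")
  }
})

test_that("phases split into the first and last five training days", {
  expect_equal(splitPhases(1:25), list(early = 1:5, late = 21:25))
  expect_equal(splitPhases(1:10), list(early = 1:5, late = 6:10))
  expect_error(splitPhases(1:9), ">= 10 training days")
})

test_that("population tilt-pair distance is a per-neuron mean Euclidean norm", {
  mkP <- function(v) new("PsthMatrix",
                         values = matrix(v, 1, 20,
                                         dimnames = list("n1", NULL)),
                         binEdges = seq(-200, 200, 20), tiltTypes = 1L,
                         nTrials = 10L)
  a <- mkP(c(1, rep(0, 19)))
  b <- mkP(c(0, 1, rep(0, 18)))
  expect_equal(tiltPairDistance(a, a), 0)
  expect_equal(tiltPairDistance(a, b), sqrt(2))
  expect_equal(tiltPairDistance(b, a), tiltPairDistance(a, b))
  bad <- mkP(c(1, rep(0, 19)))
  rownames(bad@values) <- "other"
  expect_error(tiltPairDistance(a, bad), "neuron sets differ")
  ## two-neuron mean
  v2 <- matrix(0, 2, 20, dimnames = list(c("n1", "n2"), NULL))
  v2b <- v2; v2b["n1", 1] <- 3; v2b["n2", 2] <- 4
  A <- new("PsthMatrix", values = v2, binEdges = seq(-200, 200, 20),
           tiltTypes = 1L, nTrials = 5L)
  B <- new("PsthMatrix", values = v2b, binEdges = seq(-200, 200, 20),
           tiltTypes = 2L, nTrials = 5L)
  expect_equal(tiltPairDistance(A, B), (3 + 4) / 2)
})

test_that("learners grow their naive-to-expert grouped-PSTH distances", {
  traj <- trajectorySpec("learner", nDays = 10)
  ns <- defaultNeurons(4, seed = 21)
  naive <- simulateSession(ns, 0, 160, trajectory = traj, seed = 22)
  expert <- simulateSession(ns, 10, 160, trajectory = traj, seed = 23)
  d <- naiveExpertDistances(naive, expert, hemisphere = "direct",
                            firstN = Inf)
  expect_setequal(d$contrast, c("RFS-LFS", "FRL-SRL"))
  expect_true(all(d$expert > 0))
  expect_gt(mean(d$expert), mean(d$naive))
})

test_that("expert day is the best-accuracy day, latest on ties", {
  srs <- data.frame(day = 1:5, accuracy = c(.3, .6, .5, .6, .4))
  expect_equal(expertDay(srs), 4)
})

test_that("cumulative-sum fits capture session-level outcome statistics", {
  allC <- intertrialCumsum(rep(TRUE, 50))
  expect_equal(allC$slope, 1)
  expect_equal(allC$r_squared, 1)
  allW <- intertrialCumsum(rep("incorrect", 50))
  expect_equal(allW$slope, 0)
  expect_equal(allW$r_squared, 0)
  ## slope tracks overall accuracy for exchangeable outcomes
  set.seed(31)
  x <- runif(1000) < 0.7
  fit <- intertrialCumsum(x)
  expect_lt(abs(fit$slope - mean(x)), 0.03)
  expect_gt(fit$r_squared, 0.99)
  expect_error(intertrialCumsum(c(1, 0, 1)), ">= 10 trials")
  expect_error(intertrialCumsum(rep("maybe", 20)), "binary")
})
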