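# fixtures built in code: hand-made sessions and independent brute-force
# oracles the vectorised implementations are checked against

# session with one neuron; times is a list of per-trial spike-time vectors
singleNeuronSession <- function(tilts, times, hemisphere = "direct",
                                day = 0, animal = "toy", id = "n1") {
  trials <- data.frame(trial_id = seq_along(tilts),
                       tilt_type = as.integer(tilts), outcome = "n/a")
  sp <- do.call(rbind, lapply(seq_along(times), function(i) {
    if (length(times[[i]]) == 0) return(NULL)
    data.frame(neuron_id = id, trial_id = i, time_ms = times[[i]])
  }))
  if (is.null(sp))
    sp <- data.frame(neuron_id = character(), trial_id = integer(),
                     time_ms = numeric())
  sessionRecording(animal, day, trials, sp,
                   data.frame(neuron_id = id, hemisphere = hemisphere))
}

# session from an explicit spike table
tableSession <- function(tilts, spikes, neurons, day = 0, animal = "toy") {
  trials <- data.frame(trial_id = seq_along(tilts),
                       tilt_type = as.integer(tilts), outcome = "n/a")
  sessionRecording(animal, day, trials, spikes, neurons)
}

# brute-force nearest template: explicit loops over templates and features
bfNearest <- function(x, Tmat) {
  best <- Inf
  pick <- NA_integer_
  for (j in seq_len(nrow(Tmat))) {
    d <- 0
    for (k in seq_along(x)) d <- d + (x[k] - Tmat[j, k])^2
    if (d < best) {
      best <- d
      pick <- j
    }
  }
  pick
}

# brute-force leave-one-out nearest-class-mean classification
bfLoo <- function(X, y) {
  n <- nrow(X)
  pred <- integer(n)
  for (i in seq_len(n)) {
    Tmat <- matrix(0, 4, ncol(X))
    for (cl in 1:4) {
      rows <- setdiff(which(y == cl), i)
      Tmat[cl, ] <- colMeans(X[rows, , drop = FALSE])
    }
    pred[i] <- bfNearest(X[i, ], Tmat)
  }
  pred
}

# term-by-term mutual information oracle
bfMutualInfo <- function(m) {
  total <- sum(m)
  p <- m / total
  pr <- rowSums(p)
  ps <- colSums(p)
  acc <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (p[i, j] > 0) acc <- acc + p[i, j] * log2(p[i, j] / (pr[i] * ps[j]))
    }
  }
  unname(acc)
}

# neurons where tilt separation can be dialled: each of the four direct
# neurons prefers one tilt type; `sep` scales the amplitude deviation
# from the across-tilt mean (sep = 0 means no tilt information)
separableNeurons <- function(sep, amp = 24, bg = 5, jitter = 5) {
  base <- matrix(amp / 4, 4, 4)
  diag(base) <- amp
  m <- rowMeans(base)
  amps <- m + sep * (base - m)
  amps[amps < 0] <- 0
  do.call(rbind, lapply(1:4, function(i)
    neuronSpec(sprintf("s%d", i), "direct", bg, amps[i, ],
               rep(60, 4), jitter, 15)))
}

# expected bump spike count over the window for given parameters
bumpIntegral <- function(amp, lat, width, window = tiltWindow()) {
  amp / 1000 * width * sqrt(2 * pi) *
    (pnorm((window[2] - lat) / width) - pnorm((window[1] - lat) / width))
}
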