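## Orchestration: simulate -> decode (online + offline) -> response and
## information metrics -> learning analysis, all from one seeded config,
## writing tidy CSVs and a JSON run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults equal to the study
#' conventions: 20 ms decoder bins over the -200..200 ms window, a
#' 0-200 ms information window, 50 bias shuffles, the first 300 trials per
#' session, and a 0.01 normalized-variance offset.
#'
#' @param seed master integer seed.
#' @param cohort cohort settings from [cohortSpec()].
#' @param binWidth decoder template bin width, ms.
#' @param window decoder window, ms.
#' @param firstN leading-trials filter for analyses.
#' @param nShuffles label permutations for bias correction.
#' @param threshSd responsiveness threshold, background SDs.
#' @param alpha responsiveness significance level.
#' @param epsilon normalized-variance divisor offset.
#' @param runInfo compute per-neuron information and redundancy tables
#'   (the slowest stage); disable for quick behavioural runs.
#' @param outDir output directory.
#' @return Named list of validated settings.
#' @export
pipelineConfig <- function(seed = 1, cohort = cohortSpec(),
                           binWidth = 20, window = tiltWindow(),
                           firstN = 300, nShuffles = 50, threshSd = 2,
                           alpha = 0.001, epsilon = 0.01,
                           runInfo = TRUE, outDir = tempfile("tiltbmi_")) {
  .binEdgesFor(window, binWidth)
  list(seed = as.integer(seed), cohort = cohort, binWidth = binWidth,
       window = window, firstN = firstN, nShuffles = as.integer(nShuffles),
       threshSd = threshSd, alpha = alpha, epsilon = epsilon,
       runInfo = isTRUE(runInfo), outDir = outDir)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured cohort, decodes every training day online
#' (previous-day templates; day 1 uses the day-0 baseline) and offline
#' (leave-one-out), writes outcomes back into the sessions, computes
#' performance series, learner labels, intertrial cumulative-sum fits,
#' naive-vs-expert grouped-PSTH distances, response profiles,
#' per-hemisphere normalized variance and (optionally) per-neuron
#' information and redundancy tables, and writes everything as CSV plus a
#' JSON manifest. Deterministic given the seed.
#'
#' @param config list from [pipelineConfig()].
#' @return Invisibly, a list with the output directory, the tables and the
#'   simulated experiment.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log <- function(stage, ...) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(...)))
  }

  log("simulate", "cohort of %d animals, %d training days",
      with(config$cohort, nLearners + nNonlearners + nControls),
      config$cohort$nDays)
  ex <- simulateExperiment(config$cohort, seed = config$seed)
  writeGroundTruth(ex$groundTruth,
                   file.path(config$outDir, "ground_truth.json"))

  infoSeeds <- childSeeds(config$seed + 1L, length(ex$sessions))
  perf <- list(); fits <- list(); dists <- list()
  resp <- list(); nv <- list(); info <- list()
  for (a in seq_along(ex$sessions)) {
    id <- names(ex$sessions)[a]
    sess <- ex$sessions[[a]]
    days <- sort(as.integer(names(sess)))
    tdays <- days[days > 0]

    ## online decoding day d with day d-1 templates, outcomes written back
    onAcc <- rep(NA_real_, length(tdays))
    for (i in seq_along(tdays)) {
      d <- tdays[i]
      res <- decodeOnline(sess[[as.character(d)]],
                          sess[[as.character(d - 1L)]],
                          binWidth = config$binWidth,
                          window = config$window)
      sess[[as.character(d)]] <- res$session
      onAcc[i] <- res$accuracy
      cf <- intertrialCumsum(trialTable(res$session)$outcome)
      fits[[length(fits) + 1L]] <- data.frame(
        animal_id = id, day = d, slope = cf$slope,
        intercept = cf$intercept, r_squared = cf$r_squared)
    }

    offAcc <- vapply(days, function(d)
      decodeOffline(sess[[as.character(d)]], hemisphere = "direct",
                    firstN = config$firstN, binWidth = config$binWidth,
                    window = config$window)$accuracy, numeric(1))
    offline <- data.frame(day = days, accuracy = offAcc)
    online <- data.frame(day = c(0L, tdays),
                         accuracy = c(offAcc[days == 0], onAcc))
    onlineN <- normalizePerformance(online, 0L)
    offlineN <- normalizePerformance(
      offline[offline$day > 0, , drop = FALSE], min(tdays))
    grp <- ex$animals$group[a]
    label <- if (grp == "control") "control" else
      classifyLearner(offlineN)
    perf[[a]] <- rbind(
      data.frame(animal_id = id, group = grp, label = label,
                 series = "online", onlineN),
      data.frame(animal_id = id, group = grp, label = label,
                 series = "offline", offlineN))

    expert <- expertDay(offline[offline$day > 0, , drop = FALSE])
    d <- naiveExpertDistances(sess[["0"]],
                              sess[[as.character(expert)]],
                              hemisphere = "direct",
                              firstN = config$firstN)
    dists[[a]] <- cbind(animal_id = id, expert_day = expert, d)

    ## response metrics and variance on first, expert and last day
    keyDays <- unique(c(0L, min(tdays), expert, max(tdays)))
    for (d0 in keyDays) {
      rp <- responseProfiles(sess[[as.character(d0)]],
                             threshSd = config$threshSd,
                             alpha = config$alpha,
                             firstN = config$firstN)
      resp[[length(resp) + 1L]] <- cbind(animal_id = id, day = d0, rp)
    }
    for (h in c("direct", "indirect")) {
      v <- varianceByDay(sess[as.character(keyDays)], hemisphere = h,
                         firstN = config$firstN,
                         epsilon = config$epsilon)
      nv[[length(nv) + 1L]] <- cbind(animal_id = id, hemisphere = h, v)
    }

    if (config$runInfo) {
      for (d0 in keyDays[keyDays > 0]) {
        s0 <- sess[[as.character(d0)]]
        for (h in c("direct", "indirect")) {
          nr <- neuronRoster(s0)
          ids <- nr$neuron_id[nr$hemisphere == h]
          red <- tryCatch(
            ensembleRedundancy(s0, hemisphere = h,
                               firstN = config$firstN,
                               nShuffles = config$nShuffles,
                               seed = infoSeeds[a]),
            error = function(e) NULL)
          if (is.null(red)) next
          info[[length(info) + 1L]] <- data.frame(
            animal_id = id, day = d0, hemisphere = h,
            mean_info = mean(red@singleInfo),
            ensemble_info = red@ensembleInfo,
            redundancy = red@redundancy,
            n_included = red@nIncluded)
        }
      }
    }
    ex$sessions[[a]] <- sess
    log("animal", "%s done (expert day %d)", id, expert)
  }

  tables <- list(
    performance = do.call(rbind, perf),
    cumsum_fits = do.call(rbind, fits),
    distances = do.call(rbind, dists),
    response_profiles = do.call(rbind, resp),
    normalized_variance = do.call(rbind, nv),
    information = if (length(info)) do.call(rbind, info) else NULL)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    utils::write.csv(tables[[nm]],
                     file.path(config$outDir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }

  cfgPath <- file.path(config$outDir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "outDir")], cfgPath,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfgPath)),
    r_version = as.character(getRversion()),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    rows = lapply(tables, function(t) if (is.null(t)) 0L else nrow(t)))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("done", "outputs in %s", config$outDir)
  invisible(list(outDir = config$outDir, tables = tables,
                 experiment = ex))
}
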