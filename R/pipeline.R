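# End-to-end orchestration: spontaneous-activity analysis (spikes -> bursts
# -> propagation) and the plasticity experiment (three PSTHs -> PRE/POST
# differences -> classification). Reports are plain lists, written as JSON
# with stable formatting so identical inputs give byte-identical files.

pkgVersionString <- function() {
  as.character(utils::packageVersion("modularMEA"))
}

# md5 of the serialized parameter set; stable across runs for identical params
configDigest <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(params, con, version = 3)
  close(con)
  unname(tools::md5sum(f))
}

writeReportJson <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

writeBurstTsv <- function(bursts, path) {
  tb <- burstTable(bursts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("onset\toffset\tpeak_time\tduration_ms\tn_spikes\tn_active\tedge", con)
  if (nrow(tb))
    writeLines(sprintf("%s\t%s\t%s\t%.3f\t%d\t%d\t%d",
                       fmtTime(tb$onset), fmtTime(tb$offset), fmtTime(tb$peak_time),
                       tb$duration_ms, tb$n_spikes, tb$n_active,
                       as.integer(tb$edge)), con)
  invisible(path)
}

#' Spontaneous-activity analysis pipeline
#'
#' Runs spike detection (when given raw traces), network-burst detection in
#' both modules, burst pairing and direction classification, and summarizes
#' burst durations and propagation probabilities. All parameters in force —
#' including reconstructed defaults — are echoed into the report together
#' with the package version and a digest of the parameter set.
#'
#' @param input a [SpikeTable-class], or a [RawSignalSet-class] (spike
#'   detection is then run first with `detection`).
#' @param bursts a [burstParams()] list.
#' @param detection a [detectionParams()] list (raw input only).
#' @param window burst-pairing window, ms.
#' @param includeChannels count module-end microchannel electrodes in the
#'   module rates (see [moduleElectrodes()]).
#' @param outDir optional directory; when given, writes `bursts_source.tsv`,
#'   `bursts_target.tsv` and `report.json` (byte-stable across reruns).
#' @return list with `spikes`, `sourceBursts`, `targetBursts`, `summary`
#'   (a [PropagationSummary-class]) and `report`.
#' @export
runSpontaneousPipeline <- function(input, bursts = burstParams(),
                                   detection = detectionParams(),
                                   window = 200, includeChannels = FALSE,
                                   outDir = NULL) {
  spikes <- if (is(input, "RawSignalSet")) detectSpikes(input, detection) else input
  stopifnot(is(spikes, "SpikeTable"))
  src <- detectBursts(spikes, "source", bursts, includeChannels)
  tgt <- detectBursts(spikes, "target", bursts, includeChannels)
  summary <- propagationSummary(src, tgt, window = window)
  ds <- burstDurationStats(src)
  dt <- burstDurationStats(tgt)
  params <- list(bursts = bursts, pairing_window_ms = window,
                 include_channels = includeChannels,
                 detection = if (is(input, "RawSignalSet")) detection else NULL)
  report <- list(
    version = pkgVersionString(),
    config_digest = configDigest(params),
    parameters = params,
    n_spikes = nrow(spikeEvents(spikes)),
    source = list(n_bursts = summary@nSourceBursts,
                  duration_mean_ms = ds$mean_ms, duration_sd_ms = ds$sd_ms),
    target = list(n_bursts = summary@nTargetBursts,
                  duration_mean_ms = dt$mean_ms, duration_sd_ms = dt$sd_ms),
    propagation = list(n_forward = summary@nForward,
                       n_backward = summary@nBackward,
                       n_zero_delay = summary@nZeroDelay,
                       p_forward = summary@pForward,
                       p_backward = summary@pBackward))
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeBurstTsv(src, file.path(outDir, "bursts_source.tsv"))
    writeBurstTsv(tgt, file.path(outDir, "bursts_target.tsv"))
    writeReportJson(report, file.path(outDir, "report.json"))
  }
  list(spikes = spikes, sourceBursts = src, targetBursts = tgt,
       summary = summary, report = report)
}

#' Plasticity-experiment pipeline
#'
#' Computes the PSTH for the three test stimulations around a tetanus, the
#' per-electrode PRE (test2 - test1) and POST (test3 - test2) mean-PSTH
#' differences in the requested module, and the potentiation/depression
#' classification. Electrodes silent in all three tests are excluded from the
#' test sample (zero-inflation guard) and listed in the result and report.
#'
#' @param test1,test2,test3 lists with elements `spikes` (a
#'   [SpikeTable-class]) and `log` (a [StimulusLog-class]).
#' @param module `"source"` or `"target"`.
#' @param alpha significance level of the rank-sum test.
#' @param includeChannels include the module-end microchannel electrodes in
#'   the module's electrode set (default TRUE).
#' @param window PSTH window, ms; the chip default when NULL.
#' @param outDir optional directory; writes `plasticity.json` with the
#'   per-electrode scatter data (PRE vs POST differences).
#' @return list with `result` (a [PlasticityResult-class]), `psth` (the three
#'   [PSTHMatrix-class] objects) and `report`.
#' @export
runPlasticityPipeline <- function(test1, test2, test3,
                                  module = c("target", "source"),
                                  alpha = 0.05, includeChannels = TRUE,
                                  window = NULL, outDir = NULL) {
  module <- match.arg(module)
  tests <- list(test1, test2, test3)
  for (i in 1:3) {
    if (is.null(tests[[i]]$spikes) || is.null(tests[[i]]$log))
      stop(sprintf("test%d input must provide spikes and log", i), call. = FALSE)
  }
  win <- if (is.null(window)) defaultWindow(chipType(test1$spikes)) else window
  psth <- lapply(tests, function(tt) computePSTH(tt$spikes, tt$log, win))
  electrodes <- moduleElectrodes(electrodeLayout(test1$spikes), module,
                                 includeChannels)
  mp <- lapply(psth, function(m) meanPSTH(m, electrodes)$perElectrode)
  silent <- electrodes[mp[[1]] == 0 & mp[[2]] == 0 & mp[[3]] == 0]
  keep <- setdiff(electrodes, silent)
  stopIfNot(length(keep) > 0L, "all module electrodes are silent in all tests")
  kk <- as.character(keep)
  pre <- mp[[2]][kk] - mp[[1]][kk]
  post <- mp[[3]][kk] - mp[[2]][kk]
  result <- classifyPlasticity(pre, post, alpha, excluded = silent)
  params <- list(module = module, alpha = alpha, window_ms = win,
                 include_channels = includeChannels)
  report <- list(
    version = pkgVersionString(),
    config_digest = configDigest(params),
    parameters = params,
    n_stimuli = vapply(psth, nStimuli, integer(1)),
    excluded_electrodes = silent,
    electrodes = keep,
    pre_diffs = unname(pre),
    post_diffs = unname(post),
    U = result@statistic,
    p_value = result@pValue,
    label = result@label,
    avg_magnitude = result@avgMagnitude)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeReportJson(report, file.path(outDir, "plasticity.json"))
  }
  list(result = result, psth = psth, report = report)
}
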