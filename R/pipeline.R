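#' Pipeline configuration
#'
#' All stage parameters of [runPipeline()] with their conventional
#' defaults: spike detection coefficient 8 over the 300-8000 Hz band with a
#' 1 ms refractory period and 20-200 uV amplitude gate; 5 ms TSR bins with
#' burst coefficient 0.2; 50 s Gaussian kernel, 10 ms step and coefficient
#' 0.4 for superbursts; long superbursts from 21 member small bursts;
#' motif clustering over k = 2..30.
#'
#' @param ns spike detection coefficient.
#' @param bandLow,bandHigh bandpass edges (Hz).
#' @param minIsiMs minimal inter-spike interval (ms).
#' @param ampRange accepted absolute spike amplitude range (uV), or `NULL`.
#' @param binMs TSR bin width (ms).
#' @param burstCoeff burst threshold coefficient.
#' @param kernelWidthS superburst Gaussian effective width (s).
#' @param stepMs superburst correlation step (ms).
#' @param sbCoeff superburst threshold coefficient.
#' @param minSmallLong long-superburst boundary (member small bursts).
#' @param kMax largest cluster number scanned for the DB curve.
#' @param nPcs principal components retained for pattern features.
#' @param clusterMethod `"kmeans"` or `"em"`.
#' @param clusterSpace `"angle"` (major-direction clustering, default) or
#'   `"pc"` (principal-component scores of whole patterns).
#' @param seed integer seed used by every stochastic stage.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(ns = 8, bandLow = 300, bandHigh = 8000,
                           minIsiMs = 1, ampRange = c(20, 200),
                           binMs = 5, burstCoeff = 0.2,
                           kernelWidthS = 50, stepMs = 10, sbCoeff = 0.4,
                           minSmallLong = 21L, kMax = 30L, nPcs = 3L,
                           clusterMethod = c("kmeans", "em"),
                           clusterSpace = c("angle", "pc"),
                           seed = 1L) {
  cfg <- list(ns = ns, bandLow = bandLow, bandHigh = bandHigh,
              minIsiMs = minIsiMs, ampRange = ampRange, binMs = binMs,
              burstCoeff = burstCoeff, kernelWidthS = kernelWidthS,
              stepMs = stepMs, sbCoeff = sbCoeff,
              minSmallLong = as.integer(minSmallLong),
              kMax = as.integer(kMax), nPcs = as.integer(nPcs),
              clusterMethod = match.arg(clusterMethod),
              clusterSpace = match.arg(clusterSpace),
              seed = as.integer(seed))
  stopifnot(cfg$ns > 0, cfg$bandLow > 0, cfg$bandHigh > cfg$bandLow,
            cfg$minIsiMs >= 0, cfg$binMs > 0, cfg$burstCoeff > 0,
            cfg$kernelWidthS > 0, cfg$stepMs > 0, cfg$sbCoeff > 0,
            cfg$minSmallLong >= 1L, cfg$kMax >= 2L, cfg$nPcs >= 1L)
  structure(cfg, class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' Field names mirror the arguments of [pipelineConfig()] exactly; unknown
#' keys are rejected and missing keys take their defaults. Values
#' round-trip losslessly.
#'
#' @param config a `PipelineConfig`.
#' @param path file path.
#' @return `writePipelineConfig()` returns `path` invisibly;
#'   `readPipelineConfig()` a validated `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(pipelineConfig, raw)
}

#' Hash of a pipeline configuration
#'
#' MD5 over the canonical serialized form; any parameter change changes
#' the hash.
#'
#' @param config a `PipelineConfig`.
#' @return Hex digest string.
#' @export
configHash <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  .md5Of(unclass(config))
}

.md5Of <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(object, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

## Run one pipeline stage with structured error reporting.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Binds all stages into one deterministic run: (raw input only) bandpass
#' filtering and spike detection; TSR computation; network-burst detection
#' and initiation/small classification; superburst detection and
#' regular/long classification; interburst frequencies and intra-burst
#' rates; activation patterns and major propagation directions of the small
#' bursts inside long superbursts; motif clustering (major-direction space
#' by default, with a DB curve over k); superburst typing and switching
#' statistics. Stages that need structure the recording lacks (e.g. typing
#' with fewer than 2 long superbursts) are skipped with a log entry rather
#' than failing the run.
#'
#' @param input a [RawRecording-class] or [SpikeTable-class]. Spike-table
#'   input skips spike detection (logged).
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param layout optional [ElectrodeLayout-class]; defaults to the input's
#'   attached layout.
#' @return A list of class `AnalysisBundle` with every stage output, the
#'   configuration and its hash, and a per-stage log. Identical
#'   (input, config) pairs give [bundleHash()]-identical bundles.
#' @export
runPipeline <- function(input, config = pipelineConfig(), layout = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  if (is(input, "RawRecording")) {
    note("spike_detection: raw input, detecting spikes (NS = ", config$ns, ")")
    filt <- .stage("bandpass_filter",
                   bandpassFilter(input, config$bandLow, config$bandHigh))
    st <- .stage("spike_detection",
                 detectSpikes(filt, ns = config$ns,
                              minIsi = config$minIsiMs / 1000,
                              ampRange = config$ampRange))
  } else if (is(input, "SpikeTable")) {
    note("spike_detection: skipped (spike-table input)")
    st <- input
  } else stop("input must be a RawRecording or a SpikeTable")
  if (is.null(layout)) layout <- st@layout

  tsr <- .stage("tsr", computeTSR(st, binWidth = config$binMs / 1000))
  seq0 <- .stage("burst_detection",
                 detectBursts(tsr, st, coeff = config$burstCoeff))
  note("burst_detection: ", nBursts(seq0), " bursts")
  seq <- if (nBursts(seq0) >= 2L)
    .stage("burst_classification", classifyBursts(seq0, seed = config$seed))
  else seq0
  sbs <- .stage("superburst_detection",
                detectSuperbursts(tsr, seq, width = config$kernelWidthS,
                                  step = config$stepMs / 1000,
                                  coeff = config$sbCoeff))
  sbs <- .stage("superburst_length",
                classifySuperburstLength(sbs, seq,
                                         minSmallLong = config$minSmallLong))
  note("superburst_detection: ", nrow(sbs@superbursts), " superbursts (",
       sum(sbs@superbursts$length_class == "long"), " long)")

  ibpi <- computeIBPI(seq, superbursts = sbs, smallOnly = TRUE)
  rates <- if (any(seq@bursts$class == "small"))
    intraBurstRate(seq, st) else NULL

  patterns <- NULL; angles <- NULL
  dirModel <- NULL; motifModel <- NULL; typeSeq <- NULL; stats <- NULL
  longIds <- which(sbs@superbursts$length_class == "long")
  memberIds <- unlist(sbs@members[longIds])
  smallIds <- seq@bursts$burst_id[seq@bursts$class == "small" &
                                    seq@bursts$burst_id %in% memberIds]
  if (length(smallIds) >= 3L && !is.null(layout)) {
    patterns <- .stage("activation_patterns",
                       activationPatterns(seq, st, which = smallIds,
                                          layout = layout))
    angles <- .stage("dynamic_patterns", majorDirections(patterns, layout))
    nAng <- sum(!is.na(angles))
    kR <- 2:min(config$kMax, nAng - 1L)
    if (nAng >= 4L) {
      if (config$clusterSpace == "angle") {
        dirModel <- .stage("motif_clustering",
                           selectKDirections(angles, kRange = kR,
                                             seed = config$seed))
        motifModel <- .stage("motif_clustering",
                             clusterMajorDirections(angles, k = 2L,
                                                    seed = config$seed))
        labIdx <- motifModel@metadata$angle_index
      } else {
        feats <- .stage("motif_features",
                        prepareFeatures(patterns, nPcs = config$nPcs))
        dirModel <- .stage("motif_clustering",
                           selectK(feats, method = config$clusterMethod,
                                   kRange = kR, seed = config$seed))
        motifModel <- .stage("motif_clustering",
                             clusterPatterns(feats,
                                             method = config$clusterMethod,
                                             k = 2L, seed = config$seed))
        labIdx <- seq_len(nrow(feats))
      }
      motifs <- data.frame(
        burst_id = as.integer(rownames(patterns))[labIdx],
        motif = motifModel@labels)
      nLong <- length(longIds)
      if (nLong >= 2L) {
        typeSeq <- tryCatch(
          typeSuperbursts(sbs, seq, motifs, seed = config$seed),
          error = function(e) { note("typing: skipped (",
                                     conditionMessage(e), ")"); NULL })
        if (!is.null(typeSeq))
          stats <- .stage("switch_statistics", switchStats(typeSeq))
      } else note("typing: skipped (fewer than 2 long superbursts)")
    } else note("motif_clustering: skipped (too few defined directions)")
  } else note("pattern_analysis: skipped (too few long-superburst small ",
              "bursts or no layout)")

  bundle <- list(config = config, config_hash = configHash(config),
                 input_type = class(input), spikes = st, tsr = tsr,
                 bursts = seq, superbursts = sbs, ibpi = ibpi,
                 intra_burst_rates = rates, patterns = patterns,
                 major_directions = angles, db_model = dirModel,
                 motif_model = motifModel, type_sequence = typeSeq,
                 stats = stats, log = log,
                 version = as.character(utils::packageVersion("meaburst")))
  class(bundle) <- "AnalysisBundle"
  bundle
}

#' Hash of an analysis bundle
#'
#' MD5 over the serialized stage outputs (configuration, tables, labels,
#' statistics and log). Two runs of [runPipeline()] on identical input and
#' configuration produce identical hashes.
#'
#' @param bundle an `AnalysisBundle`.
#' @return Hex digest string.
#' @export
bundleHash <- function(bundle) {
  stopifnot(inherits(bundle, "AnalysisBundle"))
  .md5Of(unclass(bundle))
}

#' @export
print.AnalysisBundle <- function(x, ...) {
  cat("AnalysisBundle (config ", substr(x$config_hash, 1, 8), ")\n",
      sep = "")
  cat(" ", nSpikes(x$spikes), "spikes;", nBursts(x$bursts), "bursts;",
      nrow(x$superbursts@superbursts), "superbursts\n")
  if (!is.null(x$stats))
    cat("  fidelity ", round(x$stats$motif_fidelity$value, 3),
        ", superburst switch ",
        round(x$stats$superburst_switch_probability$value, 3),
        ", burst motif switch ",
        round(x$stats$burst_motif_switch_probability$value, 3), "\n",
        sep = "")
  for (l in x$log) cat("  - ", l, "\n", sep = "")
  invisible(x)
}
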