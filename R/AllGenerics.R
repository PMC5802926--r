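#' @include AllClasses.R
NULL

#' Accessors for meaburst containers
#'
#' Small accessor generics used across the package: `spikes()` returns the
#' spike data.frame of a [SpikeTable-class]; `arrayLayout()` the attached
#' [ElectrodeLayout-class]; `bursts()` / `superbursts()` the underlying
#' tables; `nSpikes()` / `nBursts()` the row counts; `recordingDuration()`
#' the recording length in seconds; `motifLabels()` the per-burst motif ids
#' of a [MotifModel-class]; `dbCurve()` its Davies-Bouldin curve.
#'
#' @param x a meaburst object.
#' @return The underlying slot value (data.frame, layout, integer or
#'   numeric), never a reference into private state.
#' @name accessors
#' @aliases spikes arrayLayout bursts superbursts nSpikes nBursts
#'   recordingDuration motifLabels dbCurve
#' @examples
#' st <- generateDataset(generatorConfig(nSuperbursts = 1,
#'   smallBurstsPerSuperburst = c(5, 5), seed = 1))$spikes
#' nSpikes(st)
#' head(spikes(st))
NULL

#' @rdname accessors
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))
#' @rdname accessors
#' @export
setGeneric("arrayLayout", function(x) standardGeneric("arrayLayout"))
#' @rdname accessors
#' @export
setGeneric("bursts", function(x) standardGeneric("bursts"))
#' @rdname accessors
#' @export
setGeneric("superbursts", function(x) standardGeneric("superbursts"))
#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setGeneric("nBursts", function(x) standardGeneric("nBursts"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("motifLabels", function(x) standardGeneric("motifLabels"))
#' @rdname accessors
#' @export
setGeneric("dbCurve", function(x) standardGeneric("dbCurve"))

#' @rdname accessors
setMethod("spikes", "SpikeTable", function(x) x@spikes)
#' @rdname accessors
setMethod("arrayLayout", "SpikeTable", function(x) x@layout)
#' @rdname accessors
setMethod("arrayLayout", "RawRecording", function(x) x@layout)
#' @rdname accessors
setMethod("bursts", "BurstSequence", function(x) x@bursts)
#' @rdname accessors
setMethod("superbursts", "SuperburstSet", function(x) x@superbursts)
#' @rdname accessors
setMethod("nSpikes", "SpikeTable", function(x) nrow(x@spikes))
#' @rdname accessors
setMethod("nBursts", "BurstSequence", function(x) nrow(x@bursts))
#' @rdname accessors
setMethod("recordingDuration", "SpikeTable", function(x) x@duration)
#' @rdname accessors
setMethod("recordingDuration", "RawRecording",
  function(x) nrow(x@channels) / x@samplingRate)
#' @rdname accessors
setMethod("motifLabels", "MotifModel", function(x) x@labels)
#' @rdname accessors
setMethod("dbCurve", "MotifModel", function(x) x@dbCurve)

setMethod("show", "ElectrodeLayout", function(object) {
  cat("ElectrodeLayout with", length(object@ids), "electrodes\n")
  cat("  pitch:", format(nearestNeighbourDistance(object)), "um;",
      "bounding box:",
      paste(apply(object@positions, 2, function(p) diff(range(p))),
            collapse = " x "), "um\n")
})

setMethod("show", "SpikeTable", function(object) {
  cat("SpikeTable:", nrow(object@spikes), "spikes on",
      length(unique(object@spikes$electrode)), "electrodes,",
      format(object@duration, digits = 4), "s\n")
})

setMethod("show", "RawRecording", function(object) {
  cat("RawRecording:", ncol(object@channels), "channels x",
      nrow(object@channels), "samples @", object@samplingRate, "Hz\n")
})

setMethod("show", "TSRSeries", function(object) {
  cat("TSRSeries:", length(object@counts), "bins of",
      object@binWidth * 1000, "ms; total", sum(object@counts), "spikes\n")
})

setMethod("show", "BurstSequence", function(object) {
  cl <- table(object@bursts$class)
  cat("BurstSequence with", nrow(object@bursts), "bursts (",
      paste(names(cl), cl, sep = ": ", collapse = ", "), ")\n")
})

setMethod("show", "SuperburstSet", function(object) {
  df <- object@superbursts
  cat("SuperburstSet with", nrow(df), "superbursts")
  if (nrow(df)) {
    lc <- table(df$length_class)
    cat(" (", paste(names(lc), lc, sep = ": ", collapse = ", "), ")")
  }
  cat("\n")
})

setMethod("show", "DynamicPattern", function(object) {
  cat("DynamicPattern on", nrow(object@vectors), "electrodes; major direction",
      ifelse(is.na(object@majorDirection), "undefined",
             paste0(format(object@majorDirection, digits = 4), " deg")),
      "\n")
})

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel:", object@method, "in", object@featureSpace,
      "space, k =", object@k, "; DB =", format(object@db, digits = 3), "\n")
  if (!is.na(object@kOpt))
    cat("  DB-selected k_opt =", object@kOpt, "over k =",
        paste(range(object@dbCurve$k), collapse = ".."), "\n")
  if (!all(is.na(object@motifAngles)))
    cat("  motif circular means:",
        paste(format(object@motifAngles, digits = 4), collapse = ", "),
        "deg\n")
})

setMethod("show", "GeneratorConfig", function(object) {
  p <- object@params
  cat("GeneratorConfig:", p$nSuperbursts, "superbursts,",
      paste(p$smallBurstsPerSuperburst, collapse = "-"),
      "small bursts each; motif directions",
      paste(p$motifDirections, collapse = "/"), "deg; fidelity",
      p$motifFidelity, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@superbursts), "superbursts,",
      nrow(object@bursts), "bursts planted\n")
})

setMethod("show", "TypeSequence", function(object) {
  cat("TypeSequence:", nrow(object@table), "typed superbursts (types:",
      paste(table(object@table$type), collapse = "/"), "),",
      nrow(object@burstMotifs), "labelled small bursts\n")
})
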