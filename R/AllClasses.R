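#' @import methods
NULL

#' ElectrodeLayout: planar electrode geometry of an MEA
#'
#' Positions of the recording sites of a planar multielectrode array, in
#' micrometres. The canonical layout used throughout the package is the
#' 59-site 8 x 8 grid with 200 um pitch returned by [standardLayout()].
#'
#' @slot ids integer electrode identifiers (0-based by convention).
#' @slot positions numeric matrix with one row per electrode and columns
#'   `x`, `y` (um).
#' @seealso [standardLayout()], [nearestNeighbourDistance()]
#' @export
setClass("ElectrodeLayout",
  representation(ids = "integer", positions = "matrix"),
  validity = function(object) {
    p <- object@positions
    if (!is.numeric(p) || ncol(p) != 2L)
      return("positions must be a numeric matrix with columns x, y")
    if (nrow(p) != length(object@ids))
      return("one position per electrode id required")
    if (anyDuplicated(object@ids))
      return("electrode ids must be unique")
    if (any(!is.finite(p)))
      return("positions must be finite")
    if (anyDuplicated(p, MARGIN = 1))
      return("electrode positions must be unique")
    TRUE
  })

#' SpikeTable: per-electrode spike times and amplitudes
#'
#' The pipeline's central exchange format: one detected (or simulated) spike
#' per row, sorted by time, with the electrode geometry attached. Provenance
#' from spike detection (per-channel noise sigma, threshold, detection
#' coefficient) is carried in `metadata$detection` when available.
#'
#' @slot spikes data.frame with columns `electrode` (integer),
#'   `time_s` (numeric, seconds from recording start) and
#'   `amplitude_uV` (numeric, signed peak amplitude).
#' @slot layout an [ElectrodeLayout-class] or `NULL`.
#' @slot duration numeric, recording duration in seconds.
#' @slot metadata list of provenance entries.
#' @seealso [readSpikeTable()], [generateDataset()], [detectSpikes()]
#' @export
setClass("SpikeTable",
  representation(spikes = "data.frame", layout = "ANY",
                 duration = "numeric", metadata = "list"),
  validity = function(object) {
    df <- object@spikes
    need <- c("electrode", "time_s", "amplitude_uV")
    if (!all(need %in% names(df)))
      return(paste("spikes needs columns", paste(need, collapse = ", ")))
    if (nrow(df) && any(df$time_s < 0))
      return("spike times must be non-negative")
    if (nrow(df) && is.unsorted(df$time_s))
      return("spikes must be sorted by time")
    if (length(object@duration) != 1L || object@duration < 0)
      return("duration must be a single non-negative number")
    if (nrow(df) && max(df$time_s) > object@duration)
      return("spike times must lie within [0, duration]")
    if (!is.null(object@layout) && !is(object@layout, "ElectrodeLayout"))
      return("layout must be an ElectrodeLayout or NULL")
    TRUE
  })

#' RawRecording: multichannel sampled extracellular voltage
#'
#' @slot channels numeric matrix, samples x channels, in microvolts.
#' @slot samplingRate numeric, Hz.
#' @slot layout an [ElectrodeLayout-class] or `NULL`; when present, column
#'   `i` of `channels` is the electrode with `ids[i]`.
#' @seealso [renderRawSignal()], [bandpassFilter()], [detectSpikes()]
#' @export
setClass("RawRecording",
  representation(channels = "matrix", samplingRate = "numeric",
                 layout = "ANY"),
  validity = function(object) {
    if (!is.numeric(object@channels))
      return("channels must be a numeric matrix (samples x channels)")
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
      return("samplingRate must be a single positive number")
    if (!is.null(object@layout)) {
      if (!is(object@layout, "ElectrodeLayout"))
        return("layout must be an ElectrodeLayout or NULL")
      if (ncol(object@channels) != length(object@layout@ids))
        return("one channel per layout electrode required")
    }
    TRUE
  })

#' TSRSeries: binned total spiking rate
#'
#' Total spiking rate TSR(t): the number of spikes summed over all electrodes
#' within each time bin (5 ms by default). Thresholds for burst detection are
#' expressed as multiples of `sd(counts)`.
#'
#' @slot binWidth numeric, bin width in seconds.
#' @slot counts numeric vector of per-bin spike counts; bin `i` covers the
#'   half-open interval `[(i-1)*binWidth, i*binWidth)`.
#' @seealso [computeTSR()], [detectBursts()], [detectSuperbursts()]
#' @export
setClass("TSRSeries",
  representation(binWidth = "numeric", counts = "numeric"),
  validity = function(object) {
    if (length(object@binWidth) != 1L || object@binWidth <= 0)
      return("binWidth must be a single positive number")
    if (any(object@counts < 0))
      return("counts must be non-negative")
    TRUE
  })

#' BurstSequence: detected network bursts
#'
#' Time-ordered network bursts detected from the total spiking rate. Each
#' burst records its boundaries (half-open `[start, end)`), spike count, the
#' time of the TSR peak inside the burst, and a class label (`initiation`,
#' `small` or `unclassified`).
#'
#' @slot bursts data.frame with columns `burst_id`, `start_s`, `end_s`,
#'   `peak_s`, `n_spikes`, `class`.
#' @slot metadata list (detection threshold, TSR sd, classification
#'   threshold, ...).
#' @seealso [detectBursts()], [classifyBursts()], [computeIBPI()]
#' @export
setClass("BurstSequence",
  representation(bursts = "data.frame", metadata = "list"),
  validity = function(object) {
    df <- object@bursts
    need <- c("burst_id", "start_s", "end_s", "peak_s", "n_spikes", "class")
    if (!all(need %in% names(df)))
      return(paste("bursts needs columns", paste(need, collapse = ", ")))
    if (!nrow(df)) return(TRUE)
    if (any(df$start_s >= df$end_s))
      return("burst start must precede burst end")
    if (any(df$n_spikes < 1))
      return("every burst must contain at least one spike")
    if (any(df$peak_s < df$start_s | df$peak_s >= df$end_s))
      return("peak_s must lie in [start_s, end_s)")
    if (is.unsorted(df$start_s, strictly = TRUE) && nrow(df) > 1L)
      return("bursts must be strictly time-ordered")
    if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)]))
      return("bursts must not overlap")
    if (!all(df$class %in% c("initiation", "small", "unclassified")))
      return("class must be initiation, small or unclassified")
    TRUE
  })

#' SuperburstSet: detected superbursts
#'
#' Superbursts detected by thresholding the correlation of the TSR with a
#' wide Gaussian kernel. Member bursts are indices into the associated
#' [BurstSequence-class]; `length_class` separates regular superbursts
#' (a handful of small bursts) from long superbursts (tens of seconds,
#' up to hundreds of small bursts); `type` is the motif-based type label
#' assigned by [typeSuperbursts()].
#'
#' @slot superbursts data.frame with columns `sb_id`, `start_s`, `end_s`,
#'   `n_bursts`, `length_class`, `type`.
#' @slot members list of integer vectors of member burst ids, one per
#'   superburst.
#' @slot metadata list (kernel width, threshold, ...).
#' @seealso [detectSuperbursts()], [classifySuperburstLength()]
#' @export
setClass("SuperburstSet",
  representation(superbursts = "data.frame", members = "list",
                 metadata = "list"),
  validity = function(object) {
    df <- object@superbursts
    need <- c("sb_id", "start_s", "end_s", "n_bursts", "length_class", "type")
    if (!all(need %in% names(df)))
      return(paste("superbursts needs columns", paste(need, collapse = ", ")))
    if (nrow(df) != length(object@members))
      return("one member vector per superburst required")
    if (nrow(df) && any(df$start_s >= df$end_s))
      return("superburst start must precede end")
    if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)]))
      return("superbursts must not overlap")
    TRUE
  })

#' DynamicPattern: activation-timing gradient vector field
#'
#' Spatial representation of one activation pattern: for each electrode, a
#' 2-D vector (units s/um) giving the local gradient of first-spike latency
#' fitted over the electrode and its grid neighbours; the vector points in
#' the direction of spike propagation (increasing latency). The major
#' direction is the angle of the arithmetic (magnitude-weighted) mean of all
#' defined vectors, in degrees counter-clockwise from +x.
#'
#' @slot vectors numeric matrix, electrodes x 2 (`vx`, `vy`), `NA` rows where
#'   no local fit was possible.
#' @slot majorDirection numeric, degrees in `[0, 360)`, `NA` when the mean
#'   vector length falls below the floor.
#' @slot meanVectorLength numeric, length of the mean vector (s/um).
#' @slot layout the [ElectrodeLayout-class] the field is defined on.
#' @seealso [dynamicPattern()], [meanDynamicPattern()]
#' @export
setClass("DynamicPattern",
  representation(vectors = "matrix", majorDirection = "numeric",
                 meanVectorLength = "numeric", layout = "ANY"),
  validity = function(object) {
    if (ncol(object@vectors) != 2L)
      return("vectors must have two columns (vx, vy)")
    if (length(object@majorDirection) != 1L)
      return("majorDirection must be a single number (possibly NA)")
    TRUE
  })

#' MotifModel: clustering of burst patterns into motifs
#'
#' Result of clustering burst activation patterns (principal-component
#' scores) or major-direction angles into recurring motifs, with the
#' Davies-Bouldin (DB) index used for cluster-number selection. Lower DB
#' means more compact, better separated clusters; values below 1 are taken
#' as robust clustering.
#'
#' @slot featureSpace character: `"pc"` (principal-component scores) or
#'   `"angle"` (unit-circle embedding of major directions).
#' @slot method character: `"kmeans"` or `"em"`.
#' @slot k integer, number of clusters of the reported labelling.
#' @slot labels integer vector of per-burst motif ids in `1..k`.
#' @slot centers numeric matrix of cluster centers in feature space.
#' @slot db numeric, DB index of the reported labelling.
#' @slot dbCurve data.frame with columns `k`, `db` (empty unless produced by
#'   [selectK()]).
#' @slot kOpt integer, argmin of the DB curve (`NA` unless produced by
#'   [selectK()]).
#' @slot motifAngles numeric, per-motif circular mean direction in degrees
#'   (`NA` for non-angle feature spaces).
#' @slot metadata list.
#' @seealso [clusterPatterns()], [selectK()], [clusterMajorDirections()]
#' @export
setClass("MotifModel",
  representation(featureSpace = "character", method = "character",
                 k = "integer", labels = "integer", centers = "matrix",
                 db = "numeric", dbCurve = "data.frame", kOpt = "integer",
                 motifAngles = "numeric", metadata = "list"),
  validity = function(object) {
    if (!object@featureSpace %in% c("pc", "angle"))
      return("featureSpace must be 'pc' or 'angle'")
    if (!object@method %in% c("kmeans", "em"))
      return("method must be 'kmeans' or 'em'")
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > object@k))
      return("labels must lie in 1..k")
    if (length(object@db) == 1L && !is.na(object@db) && object@db < 0)
      return("DB index must be non-negative")
    TRUE
  })

#' GeneratorConfig: parameters of the synthetic MEA generator
#'
#' Created by [generatorConfig()]; see that constructor for the meaning,
#' units and defaults of every field.
#'
#' @slot params named list of generator parameters.
#' @seealso [generatorConfig()], [generateDataset()]
#' @export
setClass("GeneratorConfig", representation(params = "list"))

#' GroundTruth: planted structure of a synthetic dataset
#'
#' @slot bursts data.frame of planted burst windows: `burst_id`, `sb_id`,
#'   `start_s`, `end_s`, `peak_s`, `n_spikes`, `class`, `motif` (`NA` for
#'   initiation bursts), `direction_deg`.
#' @slot superbursts data.frame of planted superburst windows: `sb_id`,
#'   `start_s`, `end_s`, `type`, `n_small`.
#' @slot latencies list of per-burst planted first-spike latency vectors
#'   (seconds, one entry per electrode).
#' @slot config the [GeneratorConfig-class] used.
#' @seealso [generateDataset()]
#' @export
setClass("GroundTruth",
  representation(bursts = "data.frame", superbursts = "data.frame",
                 latencies = "list", config = "ANY"))

#' TypeSequence: motif-typed superburst sequence
#'
#' Long superbursts typed by their motif content (2-component mixture over
#' per-superburst motif fractions), together with the time-ordered motif
#' labels of all small bursts. Input to the switching statistics.
#'
#' @slot table data.frame, one row per typed superburst: `sb_id`, `start_s`,
#'   `type` (1 or 2), `dominant_motif`.
#' @slot counts matrix of per-superburst motif counts (superbursts x motifs).
#' @slot burstMotifs data.frame of all labelled small bursts in time order:
#'   `burst_id`, `sb_id` (`NA` if not inside a typed superburst), `peak_s`,
#'   `motif`.
#' @slot dominantMotif named integer: modal motif of each type.
#' @seealso [typeSuperbursts()], [switchStats()]
#' @export
setClass("TypeSequence",
  representation(table = "data.frame", counts = "matrix",
                 burstMotifs = "data.frame", dominantMotif = "integer"),
  validity = function(object) {
    if (nrow(object@table) && !all(object@table$type %in% c(1L, 2L)))
      return("superburst types must be 1 or 2")
    TRUE
  })
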