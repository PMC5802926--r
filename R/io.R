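#' Read and write spike tables as CSV
#'
#' The on-disk spike-table format is a CSV with header
#' `electrode,time_s,amplitude_uV`. Values round-trip losslessly at full
#' double precision.
#'
#' @param spikes a [SpikeTable-class].
#' @param path file path.
#' @return `writeSpikeTable()` returns `path` invisibly.
#' @export
writeSpikeTable <- function(spikes, path) {
  stopifnot(is(spikes, "SpikeTable"))
  df <- spikes@spikes
  df$time_s <- format(df$time_s, digits = 17, trim = TRUE,
                      scientific = FALSE)
  df$amplitude_uV <- format(df$amplitude_uV, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpikeTable
#' @param layout optional [ElectrodeLayout-class] to attach.
#' @param duration optional recording duration (s); defaults to the last
#'   spike time.
#' @return `readSpikeTable()` returns a [SpikeTable-class]. Malformed
#'   headers and negative times are parse errors; out-of-order rows are
#'   sorted with a warning.
#' @export
readSpikeTable <- function(path, layout = NULL, duration = NULL) {
  df <- utils::read.csv(path)
  need <- c("electrode", "time_s", "amplitude_uV")
  if (!identical(names(df)[seq_along(need)], need))
    stop("malformed spike-table header in ", path,
         ": expected columns ", paste(need, collapse = ","))
  if (any(!is.finite(df$time_s)) || any(df$time_s < 0))
    stop("invalid spike time in ", path,
         " (row ", which(!is.finite(df$time_s) | df$time_s < 0)[1], ")")
  if (is.unsorted(df$time_s))
    warning("spike rows out of time order in ", path, ": sorting")
  SpikeTable(df$electrode, df$time_s, df$amplitude_uV,
             layout = layout, duration = duration)
}

#' Read and write burst tables as CSV
#'
#' Format: `burst_id,start_s,end_s,peak_s,n_spikes,class`.
#'
#' @param seq a [BurstSequence-class].
#' @param path file path.
#' @return `writeBursts()` returns `path` invisibly; `readBursts()` a
#'   [BurstSequence-class].
#' @export
writeBursts <- function(seq, path) {
  stopifnot(is(seq, "BurstSequence"))
  utils::write.csv(format(seq@bursts, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBursts
#' @export
readBursts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("burst_id", "start_s", "end_s", "peak_s", "n_spikes", "class")
  if (!identical(names(df)[seq_along(need)], need))
    stop("malformed burst-table header in ", path)
  df$burst_id <- as.integer(df$burst_id)
  df$n_spikes <- as.integer(df$n_spikes)
  df$class <- trimws(df$class)
  new("BurstSequence", bursts = df, metadata = list(source = path))
}

#' Write a superburst table as CSV
#'
#' Format: `sb_id,start_s,end_s,n_bursts,length_class,type`.
#'
#' @param sbs a [SuperburstSet-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeSuperbursts <- function(sbs, path) {
  stopifnot(is(sbs, "SuperburstSet"))
  utils::write.csv(format(sbs@superbursts, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a TSR series as CSV
#'
#' Format: `bin_start_s,count`.
#'
#' @param tsr a [TSRSeries-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeTSR <- function(tsr, path) {
  stopifnot(is(tsr, "TSRSeries"))
  df <- data.frame(
    bin_start_s = (seq_along(tsr@counts) - 1L) * tsr@binWidth,
    count = tsr@counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write switching statistics as JSON
#'
#' @param stats a list as returned by [switchStats()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
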