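#' Render a synthetic raw voltage recording from a spike table
#'
#' Produces per-channel sampled traces consisting of Gaussian noise plus a
#' fixed biphasic template (~1 ms, negative-leading) inserted at each spike
#' time, scaled so the template extremum equals `spikeAmplitude` exactly.
#' Intended for exercising the spike detector against planted ground truth.
#'
#' @param spikes a [SpikeTable-class]; spike times must allow at least 1 ms
#'   between templates on the same channel (the detector's refractory
#'   contract), otherwise an error is raised.
#' @param noiseSd Gaussian noise sd in uV (0 gives noise-free traces).
#' @param spikeAmplitude template extremum magnitude in uV; must lie in the
#'   detector's accepted 20-200 uV range.
#' @param samplingRate sampling rate in Hz (>= 10 kHz).
#' @param seed integer seed for the noise draw.
#' @param duration trace duration in seconds; defaults to the spike table's
#'   duration. Spike times beyond it are an error.
#' @return A [RawRecording-class]. When the table has a layout, channels
#'   follow the layout's electrode order; otherwise the sorted set of
#'   electrode ids present in the table.
#' @export
renderRawSignal <- function(spikes, noiseSd = 5, spikeAmplitude = 60,
                            samplingRate = 20000, seed = 1L,
                            duration = NULL) {
  stopifnot(is(spikes, "SpikeTable"))
  if (samplingRate < 10000)
    stop("samplingRate must be at least 10 kHz")
  if (spikeAmplitude < 20 || spikeAmplitude > 200)
    stop("spikeAmplitude must lie in the 20-200 uV range")
  df <- spikes@spikes
  if (is.null(duration)) duration <- max(spikes@duration, 0.01)
  if (nrow(df) && any(df$time_s > duration))
    stop("spike times beyond the requested trace duration")

  lay <- spikes@layout
  chIds <- if (!is.null(lay)) lay@ids else sort(unique(df$electrode))
  if (!length(chIds)) chIds <- 0L
  nSamp <- ceiling(duration * samplingRate)

  ## biphasic template, ~1 ms, negative-dominant as in extracellular
  ## recordings, normalized so the extremum equals -spikeAmplitude exactly
  nT <- max(round(samplingRate * 0.001), 8L)
  tt <- seq(0, 1, length.out = nT)
  w <- -sin(2 * pi * tt)
  w[w > 0] <- 0.4 * w[w > 0]
  w <- w / max(abs(w)) * spikeAmplitude

  set.seed(seed)
  ch <- if (noiseSd > 0)
    matrix(stats::rnorm(nSamp * length(chIds), 0, noiseSd), nSamp, length(chIds))
  else matrix(0, nSamp, length(chIds))

  for (j in seq_along(chIds)) {
    tj <- sort(df$time_s[df$electrode == chIds[j]])
    if (!length(tj)) next
    if (length(tj) > 1L && any(diff(tj) < 0.001))
      stop("spike templates would overlap within 1 ms on channel ", chIds[j])
    i0 <- floor(tj * samplingRate) + 1L
    for (s in i0) {
      idx <- s:min(s + nT - 1L, nSamp)
      ch[idx, j] <- ch[idx, j] + w[seq_along(idx)]
    }
  }
  new("RawRecording", channels = ch, samplingRate = samplingRate,
      layout = lay)
}
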