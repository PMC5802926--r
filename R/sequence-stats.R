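#' Type superbursts by their motif content
#'
#' Each eligible (by default long) superburst is summarized by the vector of
#' motif fractions of its member small bursts; a 2-component Gaussian
#' mixture (EM) over those fractions assigns each superburst to one of two
#' types. Each type's dominant motif is the modal motif over all small
#' bursts of that type's superbursts (ties broken by earliest occurrence).
#'
#' @param sbs a [SuperburstSet-class] with `length_class` assigned.
#' @param seq the classified [BurstSequence-class].
#' @param motifs data.frame with columns `burst_id`, `motif`: motif labels
#'   of small bursts (e.g. from [clusterMajorDirections()] applied to their
#'   major directions).
#' @param lengthClass which superbursts to type (default `"long"`).
#' @param seed integer seed (EM is deterministic; kept for interface
#'   stability).
#' @return A [TypeSequence-class]. Errors when fewer than 2 eligible
#'   superbursts exist or all motif-fraction vectors are identical.
#' @export
typeSuperbursts <- function(sbs, seq, motifs, lengthClass = "long",
                            seed = 1L) {
  stopifnot(is(sbs, "SuperburstSet"), is(seq, "BurstSequence"),
            all(c("burst_id", "motif") %in% names(motifs)))
  df <- sbs@superbursts
  elig <- which(df$length_class %in% lengthClass)
  if (length(elig) < 2L)
    stop("need at least 2 superbursts of class ",
         paste(lengthClass, collapse = "/"), " to type")
  bdf <- seq@bursts
  motifOf <- motifs$motif[match(bdf$burst_id, motifs$burst_id)]
  levs <- sort(unique(motifs$motif))

  cnt <- matrix(0L, length(elig), length(levs),
                dimnames = list(df$sb_id[elig], levs))
  sbOf <- rep(NA_integer_, nrow(bdf))
  for (j in seq_along(elig)) {
    i <- elig[j]
    m <- bdf$burst_id %in% sbs@members[[i]] & bdf$class == "small" &
      !is.na(motifOf)
    sbOf[m] <- df$sb_id[i]
    cnt[j, ] <- as.integer(table(factor(motifOf[m], levels = levs)))
  }
  if (any(rowSums(cnt) == 0))
    stop("superburst without labelled small bursts cannot be typed")
  frac <- cnt / rowSums(cnt)
  feat <- frac[, -ncol(frac), drop = FALSE]   # fractions sum to 1
  if (nrow(unique(round(feat, 12))) < 2L)
    stop("all superbursts have identical motif fractions: typing degenerate")
  set.seed(seed)
  fit <- .emCluster(feat, 2L)
  type <- as.integer(fit$classification)

  smallOK <- bdf$class == "small" & !is.na(motifOf)
  ord <- order(bdf$peak_s)
  dominant <- vapply(1:2, function(tt) {
    m <- smallOK & sbOf %in% df$sb_id[elig][type == tt]
    tab <- table(motifOf[m])
    cand <- as.integer(names(tab)[tab == max(tab)])
    if (length(cand) == 1L) return(cand)
    ## tie: the motif occurring earliest in time wins
    firstSeen <- vapply(cand, function(mm)
      min(which(motifOf[ord] == mm & m[ord])), numeric(1))
    cand[which.min(firstSeen)]
  }, integer(1))

  burstMotifs <- data.frame(burst_id = bdf$burst_id[smallOK],
                            sb_id = sbOf[smallOK],
                            peak_s = bdf$peak_s[smallOK],
                            motif = motifOf[smallOK])
  burstMotifs <- burstMotifs[order(burstMotifs$peak_s), , drop = FALSE]
  rownames(burstMotifs) <- NULL
  tab <- data.frame(sb_id = df$sb_id[elig], start_s = df$start_s[elig],
                    type = type, dominant_motif = dominant[type])
  tab <- tab[order(tab$start_s), , drop = FALSE]
  rownames(tab) <- NULL
  new("TypeSequence", table = tab, counts = cnt,
      burstMotifs = burstMotifs,
      dominantMotif = stats::setNames(dominant, c("1", "2")))
}

#' Motif fidelity of typed superbursts
#'
#' Fraction of small bursts (inside typed superbursts) whose motif equals
#' the dominant motif of their superburst's type.
#'
#' @param ts a [TypeSequence-class].
#' @return List with `value`, `numerator`, `denominator`.
#' @export
motifFidelity <- function(ts) {
  stopifnot(is(ts, "TypeSequence"))
  if (!nrow(ts@table)) stop("no typed superbursts")
  bm <- ts@burstMotifs[!is.na(ts@burstMotifs$sb_id), , drop = FALSE]
  typeOf <- ts@table$type[match(bm$sb_id, ts@table$sb_id)]
  match_ <- bm$motif == ts@dominantMotif[typeOf]
  list(value = mean(match_), numerator = sum(match_),
       denominator = length(match_))
}

#' Switch probability between consecutive superburst types
#'
#' Fraction of consecutive (time-ordered) typed superburst pairs whose
#' types differ.
#'
#' @param ts a [TypeSequence-class] with at least 2 typed superbursts.
#' @return List with `value`, `numerator`, `denominator`.
#' @export
superburstSwitchProbability <- function(ts) {
  stopifnot(is(ts, "TypeSequence"))
  ty <- ts@table$type
  if (length(ty) < 2L) stop("need at least 2 typed superbursts")
  sw <- diff(ty) != 0
  list(value = mean(sw), numerator = sum(sw), denominator = length(sw))
}

#' Switch probability between consecutive small-burst motifs
#'
#' Fraction of consecutive pairs in the whole recording's time-ordered
#' small-burst motif sequence whose motifs differ. Pairs spanning the gap
#' between superbursts are included (superburst indexing is ignored).
#'
#' @param x a [TypeSequence-class], or a vector of motif labels in time
#'   order.
#' @return List with `value`, `numerator`, `denominator`.
#' @export
burstMotifSwitchProbability <- function(x) {
  labels <- if (is(x, "TypeSequence")) x@burstMotifs$motif else x
  labels <- labels[!is.na(labels)]
  if (length(labels) < 2L) stop("need at least 2 labelled small bursts")
  sw <- labels[-1L] != labels[-length(labels)]
  list(value = mean(sw), numerator = sum(sw), denominator = length(sw))
}

#' All switching statistics of a typed sequence
#'
#' @param ts a [TypeSequence-class].
#' @return List with elements `motif_fidelity`,
#'   `superburst_switch_probability` and `burst_motif_switch_probability`,
#'   each a list of `value`, `numerator`, `denominator`.
#' @export
switchStats <- function(ts) {
  list(motif_fidelity = motifFidelity(ts),
       superburst_switch_probability = superburstSwitchProbability(ts),
       burst_motif_switch_probability = burstMotifSwitchProbability(ts))
}
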