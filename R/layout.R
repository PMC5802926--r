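#' Canonical 59-electrode MEA layout
#'
#' The standard planar MEA geometry used throughout: an 8 x 8 square lattice
#' with 200 um pitch in which the four corner sites do not exist and one
#' further site is the unconnected reference electrode, leaving 59 active
#' recording sites. Which site serves as reference varies between array
#' models and is configurable; the default follows the common convention of
#' placing it in the first column, fifth row.
#'
#' @param pitch electrode spacing in um (default 200).
#' @param nSide lattice side length (default 8).
#' @param referenceSite integer vector of length 2, the (column, row) grid
#'   coordinates (1-based) of the absent reference site.
#' @return An [ElectrodeLayout-class] with 59 sites for the defaults.
#' @examples
#' lay <- standardLayout()
#' length(lay@ids)                  # 59
#' nearestNeighbourDistance(lay)    # 200
#' @export
standardLayout <- function(pitch = 200, nSide = 8L,
                           referenceSite = c(1L, 5L)) {
  stopifnot(pitch > 0, nSide >= 3L)
  grid <- expand.grid(col = seq_len(nSide), row = seq_len(nSide))
  corner <- (grid$col %in% c(1L, nSide)) & (grid$row %in% c(1L, nSide))
  ref <- grid$col == referenceSite[1L] & grid$row == referenceSite[2L]
  if (any(ref & corner))
    stop("referenceSite must not be a corner (corners are already absent)")
  grid <- grid[!corner & !ref, , drop = FALSE]
  pos <- cbind(x = (grid$col - 1L) * pitch, y = (grid$row - 1L) * pitch)
  rownames(pos) <- NULL
  new("ElectrodeLayout", ids = seq_len(nrow(pos)) - 1L, positions = pos)
}

#' Nearest-neighbour electrode spacing
#'
#' @param layout an [ElectrodeLayout-class].
#' @return The smallest pairwise distance between electrodes (um); for grid
#'   layouts this is the pitch.
#' @export
nearestNeighbourDistance <- function(layout) {
  stopifnot(is(layout, "ElectrodeLayout"))
  min(stats::dist(layout@positions))
}

## Index into layout rows for a vector of electrode ids.
.layoutIndex <- function(layout, electrode) {
  idx <- match(electrode, layout@ids)
  if (anyNA(idx))
    stop("electrode ids not present in layout: ",
         paste(unique(electrode[is.na(idx)]), collapse = ", "))
  idx
}
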