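## wrap into [0, 360): floating %% 360 of a tiny negative yields exactly 360
.wrap360 <- function(a) {
  a <- a %% 360
  a[a == 360] <- 0
  a
}

#' Circular difference between two angles
#'
#' Smallest rotation between two directions: `min(|a-b| mod 360,
#' 360 - |a-b| mod 360)`, in `[0, 180]` degrees. Vectorized.
#'
#' @param a,b angles in degrees.
#' @return Absolute circular difference(s) in degrees.
#' @examples
#' circularAngleDifference(29, 302)  # 87
#' circularAngleDifference(10, 350)  # 20
#' @export
circularAngleDifference <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Circular mean of angles
#'
#' Direction of the resultant vector of the unit-circle embedding.
#'
#' @param angles angles in degrees.
#' @return Mean direction in `[0, 360)` degrees; `NA` when the resultant
#'   vector is (numerically) zero.
#' @export
circularMean <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) return(NA_real_)
  th <- angles * pi / 180
  s <- mean(sin(th)); c <- mean(cos(th))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  .wrap360(atan2(s, c) * 180 / pi)
}
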