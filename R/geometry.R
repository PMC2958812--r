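#' Angular coordinate of a position relative to oriC
#'
#' On a circular chromosome of length `L`, a position is `d = (position -
#' oriC) mod L` bp downstream of the origin; its angle is `360 d / L`
#' reduced to `(-180, 180]`. Positive angles run in the direction of
#' increasing sequence coordinate. Vectorized over `position`.
#'
#' @param position Position(s) in bp, `[0, L)`.
#' @param oriC Origin position in bp.
#' @param L Genome length in bp.
#' @return Signed degrees in `(-180, 180]`.
#' @export
angle_from_origin <- function(position, oriC, L) {
  if (length(L) != 1L || L <= 0) stop("L must be a positive scalar")
  d <- (position - oriC) %% L
  ang <- 360 * d / L
  ifelse(ang > 180, ang - 360, ang)
}

#' Genome quarter of an origin-relative angle
#'
#' Quarter 1 covers `[0, 90)` degrees, quarter 2 `[90, 180]`, quarter 3
#' `(-180, -90]`, quarter 4 `(-90, 0)`.
#'
#' @param angle Signed degrees in `(-180, 180]`.
#' @return Integer 1..4.
#' @export
genome_quarter <- function(angle) {
  stopifnot(all(angle > -180 & angle <= 180))
  ifelse(angle >= 0 & angle < 90, 1L,
         ifelse(angle >= 90, 2L,
                ifelse(angle <= -90, 3L, 4L)))
}

#' Position at a given angle from oriC
#'
#' Inverse of [angle_from_origin()] (up to bp rounding).
#'
#' @param oriC Origin position (bp).
#' @param angle Signed degrees.
#' @param L Genome length (bp).
#' @return Position in `[0, L)`.
#' @export
position_at_angle <- function(oriC, angle, L) {
  as.integer(round(oriC + angle / 360 * L)) %% as.integer(L)
}

#' Origin-relative localization report
#'
#' @param genome A `Genome` with `oriC` set.
#' @param positions Positions in bp.
#' @param labels Optional feature labels.
#' @return `data.frame` with `genome_id`, `label`, `position`, `angle_deg`,
#'   `quarter`.
#' @export
angle_report <- function(genome, positions, labels = NULL) {
  if (is.null(genome$oriC)) stop("genome has no oriC set")
  ang <- angle_from_origin(positions, genome$oriC, genome$length)
  data.frame(genome_id = genome$id,
             label = labels %||% sprintf("site_%d", seq_along(positions)),
             position = positions, angle_deg = ang,
             quarter = genome_quarter(ang),
             stringsAsFactors = FALSE)
}
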