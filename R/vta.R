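# Spherical volume-of-tissue-activated (VTA) overlap under positional shift.
# Equal spheres only: the intersection is a symmetric lens with closed form
# V_int(r, d) = pi * (4r + d) * (2r - d)^2 / 12   for 0 <= d < 2r, else 0,
# and Dice = V_int / V for equal volumes.

#' Radius of a sphere from its volume
#'
#' @param volume sphere volume in mm^3 (> 0).
#' @return radius in mm: `(3 V / (4 pi))^(1/3)`.
#' @export
sphere_radius_from_volume <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Intersection volume of two equal spheres
#'
#' @param radius common sphere radius, mm (> 0).
#' @param shift center separation, mm (>= 0).
#' @return lens volume in mm^3; 0 when the spheres are disjoint
#'   (`shift >= 2 radius`); continuous at the boundary.
#' @export
sphere_intersection_volume <- function(radius, shift) {
  if (any(radius <= 0)) stop("radius must be positive")
  if (any(shift < 0)) stop("shift must be nonnegative")
  ifelse(shift >= 2 * radius, 0,
         pi * (4 * radius + shift) * (2 * radius - shift)^2 / 12)
}

#' Dice overlap of a spherical VTA after a positional shift
#'
#' For two equal spheres Dice = 2 V_int / (V + V) = V_int / V.
#'
#' @param volume VTA volume in mm^3 (> 0).
#' @param shift center shift in mm (>= 0).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_after_shift <- function(volume, shift) {
  r <- sphere_radius_from_volume(volume)
  sphere_intersection_volume(r, shift) / volume
}

# round half away from zero (presentation convention; R's round() is
# round-half-even)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' VTA shift report
#'
#' @param volume VTA volume, mm^3.
#' @param shift center shift, mm.
#' @param digits decimals for the rounded presentation values
#'   (half-away-from-zero); raw doubles are always included.
#' @return list with `radius_mm`, `intersection_mm3`, `dice` and a `rounded`
#'   sub-list.
#' @export
vta_dice_report <- function(volume, shift, digits = 2) {
  r <- sphere_radius_from_volume(volume)
  vi <- sphere_intersection_volume(r, shift)
  d <- vi / volume
  list(radius_mm = r, intersection_mm3 = vi, dice = d,
       rounded = list(radius_mm = round_half_away(r, digits),
                      intersection_mm3 = round_half_away(vi, digits),
                      dice = round_half_away(d, digits)))
}
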