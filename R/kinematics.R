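#' Sagittal posture angles at one instant
#'
#' Inclination-from-vertical angles (radians, sagittal plane) of the four
#' segments that enter the hand-location equations.  Positive = forward
#' (anterior) inclination; for the thigh, positive means the knee is
#' forward of the hip, which is why the thigh term is subtracted in the H
#' equation.  The calf is assumed vertical and carries no angle.
#'
#' @param forearm,upper_arm,back,thigh angles in radians, each in
#'   `[-pi, pi]`.
#' @return Named numeric vector of class `"posture_angles"`.
#' @export
posture_angles <- function(forearm, upper_arm, back, thigh) {
  x <- c(forearm = forearm, upper_arm = upper_arm, back = back,
         thigh = thigh)
  if (any(!is.finite(x)))
    stop_invalid("posture angles must be finite")
  if (any(abs(x) > pi + 1e-12))
    stop_invalid("posture angles must lie in [-pi, pi]")
  structure(x, class = "posture_angles")
}

#' Vertical hand height from the planar chain
#'
#' Height of the hand centre above the ground for a standing lifter,
#' stacking the chain from the ankle up and hanging the arm down from the
#' shoulder:
#' \deqn{V = L_{back}\cos\theta_{back} + L_{thigh}\cos\theta_{thigh}
#'       + L_{calf} - L_{UA}\cos\theta_{UA} - L_{FA}\cos\theta_{FA}}
#' The calf contributes its full length (vertical-shank assumption, no
#' calf angle).  The arm terms are subtracted because the arm hangs
#' downward; hands above the shoulder need arm angles beyond pi/2, which
#' are allowed, not clamped.
#'
#' @param angles a [posture_angles()] object.
#' @param lengths a [segment_lengths()] object.
#' @return Vertical height V in metres.
#' @examples
#' l <- segment_lengths(0.25, 0.30, 0.50, 0.45, 0.43)
#' estimate_v(posture_angles(0, 0, 0, 0), l)  # 0.83
#' @export
estimate_v <- function(angles, lengths) {
  check_kin_args(angles, lengths)
  unname(lengths[["back"]] * cos(angles[["back"]]) +
         lengths[["thigh"]] * cos(angles[["thigh"]]) +
         lengths[["calf"]] -
         lengths[["upper_arm"]] * cos(angles[["upper_arm"]]) -
         lengths[["forearm"]] * cos(angles[["forearm"]]))
}

#' Horizontal hand distance from the planar chain
#'
#' Horizontal distance from the ankle centre to the hand centre:
#' \deqn{H = L_{UA}\sin\theta_{UA} + L_{FA}\sin\theta_{FA}
#'       + L_{back}\sin\theta_{back} - L_{thigh}\sin\theta_{thigh}}
#'
#' @inheritParams estimate_v
#' @return Horizontal distance H in metres (signed; negative means hands
#'   behind the ankles).
#' @export
estimate_h <- function(angles, lengths) {
  check_kin_args(angles, lengths)
  unname(lengths[["upper_arm"]] * sin(angles[["upper_arm"]]) +
         lengths[["forearm"]] * sin(angles[["forearm"]]) +
         lengths[["back"]] * sin(angles[["back"]]) -
         lengths[["thigh"]] * sin(angles[["thigh"]]))
}

#' Hand location (V, H) from posture angles and segment lengths
#'
#' Bundles [estimate_v()] and [estimate_h()]; bit-identical to calling
#' them separately.
#'
#' @inheritParams estimate_v
#' @return Named numeric vector `c(V =, H =)` of class `"hand_location"`,
#'   metres.
#' @export
hand_location <- function(angles, lengths) {
  structure(c(V = estimate_v(angles, lengths),
              H = estimate_h(angles, lengths)),
            class = "hand_location")
}

check_kin_args <- function(angles, lengths) {
  if (!inherits(angles, "posture_angles"))
    stop_invalid("angles must be a posture_angles object")
  if (!inherits(lengths, "segment_lengths"))
    stop_invalid("lengths must be a segment_lengths object")
  invisible(TRUE)
}
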