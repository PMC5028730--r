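#' Kinect-v2 joint vocabulary
#'
#' The Kinect v2 skeleton tracker reports 25 named joints per frame. A fixed
#' 14-joint subset (trunk and limb landmarks, in the spirit of point-light
#' walker marker sets) is used for gait analysis; its order is a package
#' constant so that every motion matrix, segment and feature vector shares
#' one documented column layout.
#'
#' @return `kinect_joints()` returns the 25 joint names in canonical order;
#'   `analysis_joints()` returns the ordered 14-joint analysis subset.
#' @examples
#' length(kinect_joints())   # 25
#' length(analysis_joints()) # 14
#' @export
kinect_joints <- function() {
  c("Head", "Neck", "SpineShoulder", "SpineMid", "SpineBase",
    "ShoulderL", "ShoulderR", "ElbowL", "ElbowR", "WristL", "WristR",
    "HandL", "HandR", "HandTipL", "HandTipR", "ThumbL", "ThumbR",
    "HipL", "HipR", "KneeL", "KneeR", "AnkleL", "AnkleR", "FootL", "FootR")
}

#' @rdname kinect_joints
#' @export
analysis_joints <- function() {
  c("SpineBase", "Neck", "ShoulderL", "ShoulderR", "ElbowL", "ElbowR",
    "WristL", "WristR", "HipL", "HipR", "KneeL", "KneeR", "AnkleL", "AnkleR")
}

# x/y/z column names for a set of joints, joint-major: J1_x, J1_y, J1_z, J2_x...
coord_columns <- function(joints) {
  as.vector(t(outer(joints, c("x", "y", "z"), paste, sep = "_")))
}

#' Column labels of the 42-dimensional analysis frame vector
#'
#' One frame of the selected-joint representation is a 42-vector: the 14
#' analysis joints by x, y, z in fixed joint-major order.
#'
#' @return Character vector of 42 column labels (`SpineBase_x`, ...).
#' @export
motion_columns <- function() {
  coord_columns(analysis_joints())
}
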