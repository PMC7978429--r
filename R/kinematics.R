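#' Build a joint pose
#'
#' Angles are in degrees; any joint degree of freedom not given explicitly
#' takes the model's locked default (hip held at -15 degrees of abduction and
#' 0 of long-axis rotation, all other angles 0, metatarsophalangeal joint
#' fixed at 0). Angles outside the range of motion raise a warning, not an
#' error.
#'
#' @param model A `limb_model`.
#' @param ... Named joint angle sets, e.g. `hip = c(FLEXEX = 30, ABAD = -15)`.
#' @param warn_rom Warn on out-of-range angles.
#' @return A named list of named numeric vectors (degrees), one per joint.
#' @export
pose <- function(model, ..., warn_rom = TRUE) {
  user <- list(...)
  out <- lapply(model$joints, function(j) {
    ang <- setNames(j$rom$locked_default, j$rom$dof)
    u <- user[[j$name]]
    if (!is.null(u)) {
      bad <- setdiff(names(u), j$rom$dof)
      if (length(bad)) abort(paste0("joint ", j$name, " has no DoF ", bad[1]),
                             class = "archolimb_config_error")
      ang[names(u)] <- u
      if (warn_rom) {
        lo <- setNames(j$rom$rom_lo, j$rom$dof)[names(u)]
        hi <- setNames(j$rom$rom_hi, j$rom$dof)[names(u)]
        if (any(u < lo - 1e-9 | u > hi + 1e-9)) {
          warn(paste0("pose angle outside RoM at joint ", j$name))
        }
      }
    }
    ang
  })
  names(out) <- names(model$joints)
  out
}

# Rotation for one joint at the given angles (degrees): the FLEXEX, ABAD and
# LAR axis-angle rotations composed in that stated order.
joint_rotation <- function(angles_deg) {
  R <- diag(3)
  for (dof in c("FLEXEX", "ABAD", "LAR")) {
    if (!is.na(angles_deg[dof]) && dof %in% names(angles_deg)) {
      R <- R %*% rot_axis_angle(DOF_AXES[[dof]], deg2rad(unname(angles_deg[dof])))
    }
  }
  R
}

#' Forward kinematics of a limb model
#'
#' Composes rigid transforms from the pelvis (the world frame) down the chain.
#' Each child frame sits at the parent-frame joint center translated distally
#' by the joint's cartilage gap, and rotates by the FLEXEX-ABAD-LAR sequence;
#' there are no translational degrees of freedom.
#'
#' @param model A `limb_model`.
#' @param pose A pose from [pose()] (or a compatible named list).
#' @return A named list per segment of `list(R, t)` such that a local point
#'   `p` maps to world coordinates `t + R %*% p`.
#' @export
forward_kinematics <- function(model, pose) {
  fk <- list(pelvis = list(R = diag(3), t = c(0, 0, 0)))
  for (jn in names(model$joints)) {
    j <- model$joints[[jn]]
    parent <- unname(JOINT_PARENT[jn])
    child <- unname(JOINT_CHILD[jn])
    if (!child %in% names(model$segments)) next
    ang <- pose[[jn]]
    Rj <- joint_rotation(ang)
    origin_parent <- j$center + c(0, 0, -j$gap_mm)
    Rp <- fk[[parent]]$R
    tp <- fk[[parent]]$t
    fk[[child]] <- list(R = Rp %*% Rj, t = tp + as.numeric(Rp %*% origin_parent))
  }
  fk
}

# World coordinates of a local point on a segment.
to_world <- function(fk, segment, point) {
  f <- fk[[segment]]
  if (is.null(f)) abort(paste0("segment not posed: ", segment))
  f$t + as.numeric(f$R %*% point)
}

# World position of a joint center (on the parent side, including gap).
joint_center_world <- function(model, fk, joint) {
  j <- model$joints[[joint]]
  to_world(fk, unname(JOINT_PARENT[joint]), j$center + c(0, 0, -j$gap_mm))
}

# World FLEXEX/ABAD/LAR axis of a joint at the current pose. The FLEXEX axis
# is fixed in the parent frame; ABAD follows the FLEXEX rotation and LAR both.
joint_axis_world <- function(model, fk, joint, dof, pose) {
  parent <- unname(JOINT_PARENT[joint])
  Rp <- fk[[parent]]$R
  ang <- pose[[joint]]
  a <- DOF_AXES[[dof]]
  if (dof == "ABAD") {
    a <- as.numeric(rot_axis_angle(DOF_AXES$FLEXEX, deg2rad(unname(ang["FLEXEX"]))) %*% a)
  } else if (dof == "LAR") {
    R <- rot_axis_angle(DOF_AXES$FLEXEX, deg2rad(unname(ang["FLEXEX"]))) %*%
      rot_axis_angle(DOF_AXES$ABAD, deg2rad(unname(ang["ABAD"])))
    a <- as.numeric(R %*% a)
  }
  as.numeric(Rp %*% a)
}
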