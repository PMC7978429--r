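# A limb model is a single kinematic chain rooted at the pelvis:
# pelvis -> (hip) -> femur -> (knee) -> tibiotarsus -> (ankle) ->
# tarsometatarsus -> (mtp) -> pes.  All attachment and joint coordinates are
# expressed in local segment frames (mm); the reference pose (all joint
# angles zero) stacks the joint centers vertically with the limb fully
# extended ventrally.

SEGMENT_ORDER <- c("pelvis", "femur", "tibiotarsus", "tarsometatarsus", "pes")
JOINT_ORDER <- c("hip", "knee", "ankle", "mtp")
JOINT_PARENT <- c(hip = "pelvis", knee = "femur", ankle = "tibiotarsus", mtp = "tarsometatarsus")
JOINT_CHILD <- c(hip = "femur", knee = "tibiotarsus", ankle = "tarsometatarsus", mtp = "pes")

# Cartilage spacing: child segments are translated distally along the
# proximal segment's long axis by these fractions of its reference length.
CARTILAGE_FRACTION <- c(hip = 0, knee = 0.05, ankle = 0.075, mtp = 0)

# Joint DoF axes in the parent frame at the reference pose (x cranial, y
# left-medial, z dorsal for a right limb): flexion-extension about the
# right-lateral axis, ab/adduction about the cranial axis, long-axis rotation
# about the vertical. Positive senses: hip flexion, hip adduction, hip medial
# rotation, knee extension, ankle dorsiflexion.
DOF_AXES <- list(FLEXEX = c(0, -1, 0), ABAD = c(1, 0, 0), LAR = c(0, 0, 1))

#' Default joint ranges of motion and locked poses
#'
#' The moment-arm sweeps sample these ranges: hip flexion-extension -45 to 65
#' degrees, hip ab/adduction -45 to 0, hip long-axis rotation -30 to 30, knee
#' -90 (flexion) to 10 (extension), ankle 0 to 90 (dorsiflexion); the
#' metatarsophalangeal joint is fixed at 0. While one degree of freedom is
#' swept the others sit at the locked defaults (hip at -15 degrees of
#' abduction for abdominal clearance, 0 elsewhere, keeping the femur
#' vertical).
#'
#' @return A tibble with columns `joint`, `dof`, `rom_lo`, `rom_hi`,
#'   `locked_default` (degrees).
#' @export
default_rom <- function() {
  tibble::tribble(
    ~joint, ~dof,     ~rom_lo, ~rom_hi, ~locked_default,
    "hip",   "FLEXEX",  -45,     65,      0,
    "hip",   "ABAD",    -45,      0,    -15,
    "hip",   "LAR",     -30,     30,      0,
    "knee",  "FLEXEX",  -90,     10,      0,
    "ankle", "FLEXEX",    0,     90,      0,
    "mtp",   "FLEXEX",    0,      0,      0
  )
}

#' Construct a limb segment
#'
#' @param name One of `"pelvis"`, `"femur"`, `"tibiotarsus"`,
#'   `"tarsometatarsus"`, `"pes"`.
#' @param reference_length Segment reference length in mm, used for cartilage
#'   offsets and for normalizing moment arms (femur for hip, tibiotarsus for
#'   knee, tarsometatarsus for ankle muscles).
#' @return A `segment` object.
#' @export
segment <- function(name, reference_length) {
  name <- match.arg(name, SEGMENT_ORDER)
  if (!is.numeric(reference_length) || reference_length <= 0) {
    abort("segment reference_length must be > 0", class = "archolimb_config_error")
  }
  structure(list(name = name, reference_length = as.numeric(reference_length)),
            class = "limb_segment")
}

#' Construct a joint specification
#'
#' @param name Joint name (`"hip"`, `"knee"`, `"ankle"`, `"mtp"`).
#' @param center Joint center, length-3, in the parent segment's frame (mm).
#' @param rom Optional tibble overriding rows of [default_rom()] for this
#'   joint.
#' @param gap_mm Cartilage gap (mm) translating the child segment distally;
#'   normally computed by [place_joint()].
#' @return A `joint_spec` object.
#' @export
joint_spec <- function(name, center, rom = NULL, gap_mm = 0) {
  name <- match.arg(name, JOINT_ORDER)
  center <- vec3(center)
  rom_tbl <- default_rom()[default_rom()$joint == name, ]
  if (!is.null(rom)) {
    rom <- tibble::as_tibble(rom)
    for (i in seq_len(nrow(rom))) {
      k <- which(rom_tbl$dof == rom$dof[i])
      if (length(k) == 0) abort(paste0("joint ", name, " has no DoF ", rom$dof[i]),
                                class = "archolimb_config_error")
      rom_tbl[k, c("rom_lo", "rom_hi", "locked_default")] <-
        rom[i, c("rom_lo", "rom_hi", "locked_default")]
    }
  }
  bad <- rom_tbl$rom_lo > rom_tbl$rom_hi
  if (any(bad)) abort("joint RoM lower bound must not exceed upper bound",
                      class = "archolimb_config_error")
  off <- rom_tbl$locked_default < rom_tbl$rom_lo | rom_tbl$locked_default > rom_tbl$rom_hi
  if (any(off)) abort("locked default angles must lie within the RoM bounds",
                      class = "archolimb_config_error")
  structure(list(name = name, center = center, rom = rom_tbl,
                 cartilage_fraction = unname(CARTILAGE_FRACTION[name]),
                 gap_mm = as.numeric(gap_mm)),
            class = "joint_spec")
}

#' Place a joint center from fitted primitives and apply cartilage spacing
#'
#' The hip center is the superposition (mean) of the femoral-head and
#' acetabular sphere centers, with zero gap; when the two fitted centers
#' disagree their discrepancy is recorded in the returned joint. Knee and
#' ankle centers sit at the long-axis midpoint of the fitted cylinder and the
#' child segment is translated distally by 5% (knee) or 7.5% (ankle) of the
#' proximal segment's reference length to represent articular cartilage.
#'
#' @param joint A `joint_spec` (its `center` is overwritten).
#' @param proximal The proximal (parent) `segment`.
#' @param primitives For the hip, a list of two `sphere_primitive`s; for the
#'   knee/ankle, a single `cylinder_primitive`. `NULL` keeps the declared
#'   center (manual placement) but still applies the cartilage gap.
#' @return The updated `joint_spec` with `center` and `gap_mm` set.
#' @export
place_joint <- function(joint, proximal, primitives = NULL) {
  stopifnot(inherits(joint, "joint_spec"), inherits(proximal, "limb_segment"))
  if (unname(JOINT_PARENT[joint$name]) != proximal$name) {
    abort(paste0("segment ", proximal$name, " is not the parent of joint ", joint$name),
          class = "archolimb_config_error")
  }
  if (!is.null(primitives)) {
    if (joint$name == "hip") {
      sp <- if (inherits(primitives, "sphere_primitive")) list(primitives) else primitives
      if (!all(vapply(sp, inherits, logical(1), "sphere_primitive"))) {
        abort("hip placement needs sphere primitives", class = "archolimb_config_error")
      }
      centers <- do.call(rbind, lapply(sp, `[[`, "center"))
      joint$center <- colMeans(centers)
      joint$center_discrepancy_mm <- if (nrow(centers) == 2L) norm3(centers[1, ] - centers[2, ]) else 0
    } else {
      if (!inherits(primitives, "cylinder_primitive")) {
        abort(paste0(joint$name, " placement needs a cylinder primitive"),
              class = "archolimb_config_error")
      }
      joint$center <- primitives$axis_point
    }
  }
  joint$gap_mm <- joint$cartilage_fraction * proximal$reference_length
  joint
}

#' Attachment point on a segment
#'
#' @param segment Segment name.
#' @param point Length-3 coordinates in that segment's frame (mm).
#' @export
attachment <- function(segment, point) {
  list(segment = match.arg(segment, SEGMENT_ORDER), point = vec3(point))
}

#' Construct a wrapping surface
#'
#' Wrapping surfaces deflect muscle-tendon paths on contact, standing in for
#' underlying bone and muscle bulk. Cylinders use the exact unrolled-plane
#' tangent-arc-tangent construction, spheres the tangent-great-circle
#' construction, and ellipsoids an iterative taut-path relaxation over the
#' surface.
#'
#' @param name Surface name (unique within a model).
#' @param shape `"cylinder"`, `"sphere"` or `"ellipsoid"`.
#' @param segment Segment whose frame the surface is fixed in.
#' @param center Surface center in the segment frame (mm).
#' @param axis Cylinder axis direction (segment frame); ignored for spheres.
#' @param radius Radius in mm (cylinder/sphere), or length-3 semi-axes for an
#'   ellipsoid.
#' @param half_length Cylinder half length (mm), used only for reporting.
#' @param wrap_side For cylinders, `+1` or `-1`: the sense (counterclockwise
#'   or clockwise, viewed down the axis) in which an engaged path traverses
#'   the contact arc, which fixes the side of the surface the path passes.
#' @param mtus Character vector of MTU names the surface is assigned to.
#' @export
wrap_surface <- function(name, shape = c("cylinder", "sphere", "ellipsoid"),
                         segment, center, axis = c(0, -1, 0), radius,
                         half_length = NULL, wrap_side = 1, mtus = character()) {
  shape <- match.arg(shape)
  if (any(radius <= 0)) abort("wrap surface dimensions must be > 0",
                              class = "archolimb_config_error")
  if (shape == "ellipsoid" && length(radius) != 3L) {
    abort("ellipsoid wrap surfaces need three semi-axes", class = "archolimb_config_error")
  }
  structure(list(name = name, shape = shape,
                 segment = match.arg(segment, SEGMENT_ORDER),
                 center = vec3(center), axis = unit3(vec3(axis)),
                 radius = radius, half_length = half_length,
                 wrap_side = sign(wrap_side), mtus = mtus),
            class = "wrap_surface")
}

#' Construct a muscle-tendon unit path
#'
#' @param name MTU acronym (normally from the archosaur hindlimb roster, see
#'   [muscle_roster()]).
#' @param origin,insertion [attachment()]s; the origin segment must be
#'   proximal to the insertion segment in the chain.
#' @param via Ordered (proximal to distal) list of [attachment()] via points.
#' @param wraps Character vector of wrap surface names assigned to this MTU.
#' @param present Logical; muscles lost in a taxon are flagged absent and
#'   excluded at assembly.
#' @export
mtu_path <- function(name, origin, insertion, via = list(), wraps = character(),
                     present = TRUE) {
  ro <- match(origin$segment, SEGMENT_ORDER)
  ri <- match(insertion$segment, SEGMENT_ORDER)
  if (ro >= ri) abort(paste0("MTU ", name, ": origin must be proximal to insertion"),
                      class = "archolimb_config_error")
  structure(list(name = name, origin = origin, via = via, insertion = insertion,
                 wraps = wraps, present = isTRUE(present)),
            class = "mtu_path")
}

#' Assemble and validate a limb model
#'
#' Checks that segments form the pelvis-rooted chain, that every joint,
#' attachment and wrap surface references an existing segment, that MTU
#' acronyms are known, and drops muscles flagged absent for the taxon.
#'
#' @param taxon Taxon name.
#' @param segments List of [segment()]s (pelvis through pes subchain).
#' @param joints List of [joint_spec()]s connecting consecutive segments.
#' @param mtus List of [mtu_path()]s.
#' @param wraps List of [wrap_surface()]s.
#' @param metadata Optional list (specimen, body mass, ...).
#' @param roster_check Validate MTU acronyms against [muscle_roster()].
#' @return A validated `limb_model`.
#' @export
assemble_model <- function(taxon, segments, joints, mtus = list(),
                           wraps = list(), metadata = list(),
                           roster_check = TRUE) {
  seg_names <- vapply(segments, `[[`, character(1), "name")
  if (anyDuplicated(seg_names)) abort("duplicate segment names", class = "archolimb_config_error")
  ord <- match(seg_names, SEGMENT_ORDER)
  if (anyNA(ord)) abort("unknown segment name", class = "archolimb_config_error")
  ord_sorted <- sort(ord)
  if (!identical(ord_sorted, seq(min(ord_sorted), max(ord_sorted))) || min(ord_sorted) != 1L) {
    abort("segments must form a single chain rooted at the pelvis",
          class = "archolimb_config_error")
  }
  segments <- segments[order(ord)]
  seg_names <- seg_names[order(ord)]
  names(segments) <- seg_names

  joint_names <- vapply(joints, `[[`, character(1), "name")
  names(joints) <- joint_names
  needed <- JOINT_ORDER[seq_len(length(segments) - 1L)]
  if (!setequal(joint_names, needed)) {
    abort(paste0("model with segments {", paste(seg_names, collapse = ", "),
                 "} needs joints {", paste(needed, collapse = ", "), "}"),
          class = "archolimb_config_error")
  }
  joints <- joints[needed]

  wrap_names <- vapply(wraps, `[[`, character(1), "name")
  names(wraps) <- wrap_names
  for (w in wraps) {
    if (!w$segment %in% seg_names) {
      abort(paste0("wrap surface ", w$name, " sits on missing segment ", w$segment),
            class = "archolimb_config_error")
    }
  }

  keep <- list()
  dropped <- character()
  roster <- if (roster_check) muscle_roster()$abbrev else NULL
  for (m in mtus) {
    if (!is.null(roster) && !m$name %in% roster) {
      abort(paste0("unknown MTU acronym: ", m$name), class = "archolimb_config_error")
    }
    for (att in c(list(m$origin), m$via, list(m$insertion))) {
      if (!att$segment %in% seg_names) {
        abort(paste0("MTU ", m$name, " attaches to missing segment ", att$segment),
              class = "archolimb_config_error")
      }
    }
    for (wn in m$wraps) {
      if (!wn %in% wrap_names) {
        abort(paste0("MTU ", m$name, " references missing wrap surface ", wn),
              class = "archolimb_config_error")
      }
    }
    if (m$present) keep[[m$name]] <- m else dropped <- c(dropped, m$name)
  }

  structure(list(taxon = taxon, segments = segments, joints = joints,
                 mtus = keep, wraps = wraps,
                 metadata = c(metadata, list(absent_mtus = dropped))),
            class = "limb_model")
}

#' @export
print.limb_model <- function(x, ...) {
  cat(sprintf("<limb_model> %s: %d segments, %d joints, %d MTUs (%d absent), %d wrap surfaces\n",
              x$taxon, length(x$segments), length(x$joints), length(x$mtus),
              length(x$metadata$absent_mtus), length(x$wraps)))
  invisible(x)
}

# Joints crossed by an MTU: every joint between the origin and insertion
# segments in the chain.
mtu_joints <- function(model, mtu) {
  ro <- match(mtu$origin$segment, SEGMENT_ORDER)
  ri <- match(mtu$insertion$segment, SEGMENT_ORDER)
  js <- JOINT_ORDER[seq(ro, ri - 1L)]
  intersect(js, names(model$joints))
}

# Segment whose reference length normalizes a joint's moment arms.
NORMALIZING_SEGMENT <- c(hip = "femur", knee = "tibiotarsus", ankle = "tarsometatarsus",
                         mtp = "pes")
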