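# Moment arms by the virtual-work method: the signed moment arm of an MTU
# about a joint degree of freedom is r = -dL/dtheta (theta in radians), so a
# positive moment arm means muscle tension drives positive rotation of that
# DoF (hip flexion, hip adduction, hip medial long-axis rotation, knee
# extension, ankle dorsiflexion).

#' Moment arm of an MTU about one joint DoF at a pose
#'
#' Differentiates the routed path length with respect to the joint angle with
#' a fourth-order central finite-difference stencil of step `h` degrees.
#'
#' @param model A `limb_model`.
#' @param mtu MTU name or `mtu_path`.
#' @param joint Joint name.
#' @param dof `"FLEXEX"`, `"ABAD"` or `"LAR"`.
#' @param pose A [pose()]; defaults to the locked reference pose.
#' @param h Finite-difference step in degrees.
#' @return Signed moment arm in mm.
#' @export
moment_arm <- function(model, mtu, joint, dof = "FLEXEX", pose = NULL, h = 0.25) {
  if (is.character(mtu)) {
    mtu <- model$mtus[[mtu]] %||%
      abort(paste0("no MTU named ", mtu, " in model"), class = "archolimb_config_error")
  }
  if (!joint %in% mtu_joints(model, mtu)) {
    abort(paste0("MTU ", mtu$name, " does not cross joint ", joint),
          class = "archolimb_config_error")
  }
  if (is.null(pose)) pose <- pose(model)
  theta0 <- unname(pose[[joint]][dof])
  L <- function(th) {
    p <- pose
    p[[joint]][dof] <- th
    withCallingHandlers(
      route_path(model, p, mtu)$length,
      error = function(e) {
        abort(paste0("path routing failed for ", mtu$name, " at ", joint, " ",
                     dof, " = ", signif(th, 6), " deg: ", conditionMessage(e)),
              class = "archolimb_wrap_failure")
      })
  }
  h_rad <- deg2rad(h)
  dL <- (L(theta0 - 2 * h) - 8 * L(theta0 - h) + 8 * L(theta0 + h) - L(theta0 + 2 * h)) /
    (12 * h_rad)
  -dL
}

#' Sweep a joint range of motion and return a moment-arm curve
#'
#' Samples the signed moment arm on a 1-degree grid across the joint's stated
#' range of motion while all other DoFs sit at their locked defaults.
#'
#' @inheritParams moment_arm
#' @param step Grid step in degrees.
#' @param h Finite-difference step in degrees.
#' @return A tibble of class `moment_arm_curve` with columns `mtu`, `joint`,
#'   `dof`, `theta_deg`, `moment_arm_mm`.
#' @export
sweep_rom <- function(model, mtu, joint, dof = "FLEXEX", step = 1, h = 0.25) {
  if (is.character(mtu)) mtu <- model$mtus[[mtu]] %||%
      abort(paste0("no MTU named ", mtu, " in model"), class = "archolimb_config_error")
  j <- model$joints[[joint]] %||%
    abort(paste0("no joint named ", joint), class = "archolimb_config_error")
  rom <- j$rom[j$rom$dof == dof, ]
  if (nrow(rom) == 0) abort(paste0("joint ", joint, " has no DoF ", dof),
                            class = "archolimb_config_error")
  grid <- seq(rom$rom_lo, rom$rom_hi, by = step)
  base <- pose(model)
  r <- vapply(grid, function(th) {
    p <- base
    p[[joint]][dof] <- th
    moment_arm(model, mtu, joint, dof, pose = p, h = h)
  }, numeric(1))
  out <- tibble::tibble(mtu = mtu$name, joint = joint, dof = dof,
                        theta_deg = grid, moment_arm_mm = r)
  class(out) <- c("moment_arm_curve", class(out))
  out
}

#' Reduce a moment-arm curve to its mean, normalized by segment length
#'
#' The curve is averaged (unweighted arithmetic mean over the angle grid) and
#' divided by the reference length of the joint's normalizing segment (femur
#' for the hip, tibiotarsus for the knee, tarsometatarsus for the ankle).
#'
#' @param curve A `moment_arm_curve` from [sweep_rom()].
#' @param segment The normalizing [segment()] (or a `limb_model`, from which
#'   it is looked up).
#' @return A one-row tibble with `mtu`, `joint`, `dof`, `mean_mm`,
#'   `segment_length_mm`, `mean_normalized`.
#' @export
mean_normalized <- function(curve, segment) {
  if (nrow(curve) == 0) abort("empty moment-arm curve", class = "archolimb_config_error")
  joint <- curve$joint[1]
  if (inherits(segment, "limb_model")) {
    segment <- segment$segments[[unname(NORMALIZING_SEGMENT[joint])]]
  }
  m <- mean(curve$moment_arm_mm)
  tibble::tibble(mtu = curve$mtu[1], joint = joint, dof = curve$dof[1],
                 mean_mm = m, segment_length_mm = segment$reference_length,
                 mean_normalized = m / segment$reference_length)
}

#' Average the mean moment arms of a muscle's sub-heads
#'
#' Muscles modeled as two sub-heads (e.g. IT2 in general, ITC in dinosaurs)
#' contribute a single averaged value to the trait table.
#'
#' @param values Numeric vector of per-head means (at least one).
#' @return Their arithmetic mean.
#' @export
average_subheads <- function(values) {
  if (length(values) == 0) abort("no sub-head values to average",
                                 class = "archolimb_config_error")
  mean(values)
}

#' Sweep all MTUs and DoFs of a model into a mean moment-arm table
#'
#' For each present MTU, sweeps every DoF of every joint it crosses, reduces
#' each curve to a segment-length normalized mean, and averages sub-heads
#' (MTU names ending in `.1`/`.2` are treated as sub-heads of the stem name).
#' Muscles flagged absent for the taxon are carried as zero with a `lost`
#' flag so that trait vectors stay complete across taxa.
#'
#' @param model A `limb_model`.
#' @param joints Restrict to these joints (default: all in the model except
#'   the fixed metatarsophalangeal joint).
#' @param step,h Grid and finite-difference steps in degrees.
#' @param keep_curves Also return per-angle curves.
#' @return A tibble (class `mean_moment_arm_table`) with columns `taxon`,
#'   `mtu`, `joint`, `dof`, `mean_mm`, `segment_length_mm`,
#'   `mean_normalized`, `lost`; with attribute `curves` when requested.
#' @export
sweep_model <- function(model, joints = NULL, step = 1, h = 0.25,
                        keep_curves = FALSE) {
  joints <- joints %||% setdiff(names(model$joints), "mtp")
  rows <- list()
  curves <- list()
  for (m in model$mtus) {
    for (jn in intersect(mtu_joints(model, m), joints)) {
      for (dof in model$joints[[jn]]$rom$dof) {
        if (model$joints[[jn]]$rom$rom_lo[model$joints[[jn]]$rom$dof == dof] ==
            model$joints[[jn]]$rom$rom_hi[model$joints[[jn]]$rom$dof == dof]) next
        cv <- sweep_rom(model, m, jn, dof, step = step, h = h)
        if (keep_curves) curves[[length(curves) + 1L]] <- cv
        rows[[length(rows) + 1L]] <- mean_normalized(cv, model)
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab)) {
    tab <- tab |>
      dplyr::mutate(stem = sub("\\.[12]$", "", .data$mtu)) |>
      dplyr::group_by(.data$stem, .data$joint, .data$dof) |>
      dplyr::summarise(
        mean_mm = average_subheads(.data$mean_mm),
        segment_length_mm = .data$segment_length_mm[1],
        mean_normalized = average_subheads(.data$mean_normalized),
        .groups = "drop") |>
      dplyr::rename(mtu = "stem") |>
      dplyr::mutate(lost = FALSE)
  }
  lost <- model$metadata$absent_mtus
  if (length(lost)) {
    tab <- dplyr::bind_rows(tab, tidyr::expand_grid(
      mtu = lost, joint = NA_character_, dof = NA_character_) |>
        dplyr::mutate(mean_mm = 0, segment_length_mm = NA_real_,
                      mean_normalized = 0, lost = TRUE))
  }
  tab <- dplyr::mutate(tab, taxon = model$taxon, .before = 1)
  class(tab) <- c("mean_moment_arm_table", class(tab))
  if (keep_curves) attr(tab, "curves") <- dplyr::bind_rows(curves)
  tab
}
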