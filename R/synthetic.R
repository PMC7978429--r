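# Synthetic inputs: parametric limb models whose moment arms are known in
# closed form (pulley and straight-line muscles), clade series with a
# programmed leverage trend across the study tree, and Brownian-motion trait
# simulation. Everything is deterministic given its parameters and seed.

#' Parameters for the parametric limb generator
#'
#' Segment proportions loosely follow theropod hindlimb ratios
#' (femur : tibiotarsus : tarsometatarsus = 1 : 1.1 : 0.6); they are cosmetic
#' in that ground-truth moment arms come from the muscle recipes, not from
#' anatomical realism. The default wrap radius is 0.1421 of femur length,
#' the proportion that condylar wrapping surfaces hold across the 13 study
#' models.
#'
#' @param femur_mm Femur reference length (mm).
#' @param wrap_radius_fraction Knee wrap cylinder radius as a fraction of
#'   femur length.
#' @param muscles Named list of muscle recipes; see Details. The default
#'   roster is a knee-extensor pulley (AMB), two straight-line hip muscles
#'   (CFL extensor, IT1 flexor) and a straight-line knee flexor (GL).
#' @param leverage_scale Named numeric: per-muscle scale factor applied to
#'   the recipe's leverage-determining dimension (wrap radius for pulleys,
#'   attachment offsets for straight muscles).
#' @param absent Character vector of muscles flagged lost for the taxon.
#' @param seed Integer seed (reserved for stochastic recipe variants; the
#'   default recipes are fully deterministic).
#' @return A `limb_gen_params` list.
#' @details A recipe is `list(type = "pulley_knee")` or
#'   `list(type = "straight", joint, origin, insertion)` with attachments as
#'   `attachment()`s. Straight recipes keep all points in the sagittal plane
#'   so their moment arms follow the planar perpendicular-distance formula.
#' @export
limb_gen_params <- function(femur_mm = 300, wrap_radius_fraction = 0.1421,
                            muscles = NULL, leverage_scale = numeric(),
                            absent = character(), seed = 1L) {
  if (wrap_radius_fraction <= 0 || wrap_radius_fraction > 1) {
    abort("wrap_radius_fraction must be in (0, 1]", class = "archolimb_config_error")
  }
  L <- c(pelvis = femur_mm * 0.85, femur = femur_mm, tibiotarsus = femur_mm * 1.1,
         tarsometatarsus = femur_mm * 0.6, pes = femur_mm * 0.35)
  if (is.null(muscles)) {
    muscles <- list(
      AMB = list(type = "pulley_knee"),
      CFL = list(type = "straight", joint = "hip",
                 origin = attachment("pelvis", c(-0.20, 0, 0.07) * femur_mm),
                 insertion = attachment("femur", c(-0.027, 0, -0.30) * femur_mm)),
      IT1 = list(type = "straight", joint = "hip",
                 origin = attachment("pelvis", c(0.23, 0, 0.10) * femur_mm),
                 insertion = attachment("femur", c(0.033, 0, -0.27) * femur_mm)),
      GL = list(type = "straight", joint = "knee",
                origin = attachment("femur", c(-0.13, 0, -0.80) * femur_mm),
                insertion = attachment("tibiotarsus", c(-0.10, 0, -0.15) * femur_mm))
    )
  }
  structure(list(segment_lengths = L, wrap_radius_fraction = wrap_radius_fraction,
                 muscles = muscles, leverage_scale = leverage_scale,
                 absent = absent, seed = as.integer(seed)),
            class = "limb_gen_params")
}

#' Generate a parametric limb model with known moment arms
#'
#' Builds a five-segment limb whose muscle recipes have closed-form moment
#' arms: the knee pulley muscle wraps a cylinder coaxial with the knee
#' flexion axis (moment arm = wrap radius at every angle, positive =
#' extensor), and straight-line muscles obey the perpendicular-distance
#' formula. The ground truth is recorded in a sidecar table computed from
#' the recipes, independent of the path-routing engine.
#'
#' @param params A [limb_gen_params()].
#' @param taxon Taxon name for the model.
#' @return A `limb_model` with attribute `ground_truth`: a tibble `mtu`,
#'   `joint`, `dof`, `true_mean_mm`, `true_mean_normalized` (NA for recipes
#'   without a closed form over the sweep).
#' @export
generate_limb <- function(params = limb_gen_params(), taxon = "synthetic") {
  L <- params$segment_lengths
  segs <- lapply(names(L), function(nm) segment(nm, L[[nm]]))
  names(segs) <- names(L)
  joints <- list(
    joint_spec("hip", c(0, 0, 0)),
    joint_spec("knee", c(0, 0, -L[["femur"]])),
    joint_spec("ankle", c(0, 0, -L[["tibiotarsus"]])),
    joint_spec("mtp", c(0, 0, -L[["tarsometatarsus"]]))
  )
  joints <- lapply(joints, function(j) place_joint(j, segs[[unname(JOINT_PARENT[j$name])]]))
  wraps <- list()
  mtus <- list()
  gt <- list()
  for (nm in names(params$muscles)) {
    rc <- params$muscles[[nm]]
    sc <- unname(params$leverage_scale[nm])
    if (is.na(sc)) sc <- 1
    present <- !nm %in% params$absent
    if (rc$type == "pulley_knee") {
      R <- params$wrap_radius_fraction * L[["femur"]] * sc
      # coaxial with the actual knee rotation axis, i.e. at the fitted
      # center displaced distally by the cartilage gap
      knee_rot <- c(0, 0, -(1 + CARTILAGE_FRACTION[["knee"]]) * L[["femur"]])
      wname <- paste0("knee_cyl_", nm)
      wraps[[wname]] <- wrap_surface(wname, "cylinder", "femur",
                                     center = knee_rot,
                                     axis = DOF_AXES$FLEXEX, radius = R,
                                     half_length = 0.2 * L[["femur"]],
                                     wrap_side = -1, mtus = nm)
      mtus[[nm]] <- mtu_path(nm,
        origin = attachment("femur", knee_rot + c(0, 0, R)),
        insertion = attachment("tibiotarsus", c(0, 0, -0.2 * L[["tibiotarsus"]])),
        wraps = wname, present = present)
      gt[[nm]] <- tibble::tibble(
        mtu = nm, joint = "knee", dof = "FLEXEX", true_mean_mm = R,
        true_mean_normalized = R / L[["tibiotarsus"]])
    } else if (rc$type == "straight") {
      o <- rc$origin; i <- rc$insertion
      if (sc != 1) {
        o <- attachment(o$segment, o$point * c(sc, 1, 1))
        i <- attachment(i$segment, i$point * c(sc, 1, 1))
      }
      mtus[[nm]] <- mtu_path(nm, origin = o, insertion = i, present = present)
      gt[[nm]] <- tibble::tibble(mtu = nm, joint = rc$joint, dof = "FLEXEX",
                                 true_mean_mm = NA_real_,
                                 true_mean_normalized = NA_real_)
    } else {
      abort(paste0("unknown muscle recipe type: ", rc$type),
            class = "archolimb_config_error")
    }
  }
  model <- assemble_model(taxon, segs, joints, mtus, wraps,
                          metadata = list(generator = "parametric",
                                          wrap_radius_fraction = params$wrap_radius_fraction))
  # Straight-line ground truth: mean of the closed-form perpendicular-distance
  # moment arm over the sweep grid, computed from rotation matrices only.
  gt <- dplyr::bind_rows(gt)
  for (k in seq_len(nrow(gt))) {
    if (!is.na(gt$true_mean_mm[k])) next
    nm <- gt$mtu[k]
    if (!nm %in% names(model$mtus)) next
    jn <- gt$joint[k]
    rom <- model$joints[[jn]]$rom
    rr <- rom[rom$dof == "FLEXEX", ]
    grid <- seq(rr$rom_lo, rr$rom_hi, by = 1)
    vals <- vapply(grid, function(th) {
      p <- pose(model)
      p[[jn]]["FLEXEX"] <- th
      straight_line_moment_arm(model, model$mtus[[nm]], jn, "FLEXEX", p)
    }, numeric(1))
    gt$true_mean_mm[k] <- mean(vals)
    gt$true_mean_normalized[k] <- mean(vals) /
      L[[unname(NORMALIZING_SEGMENT[jn])]]
  }
  attr(model, "ground_truth") <- gt
  model
}

#' Closed-form moment arm of a straight-line muscle
#'
#' Geometric oracle, independent of path routing and finite differences: the
#' signed moment arm of a straight origin-to-insertion muscle about a joint
#' axis is `a . ((P - c) x u)` where `a` is the world joint axis, `c` the
#' joint center, `P` the insertion and `u` the unit vector from insertion
#' toward origin.
#'
#' @inheritParams moment_arm
#' @export
straight_line_moment_arm <- function(model, mtu, joint, dof = "FLEXEX",
                                     pose = NULL) {
  if (is.character(mtu)) mtu <- model$mtus[[mtu]]
  if (length(mtu$via) || length(mtu$wraps)) {
    abort("closed form applies to straight origin-insertion muscles only",
          class = "archolimb_config_error")
  }
  if (is.null(pose)) pose <- pose(model)
  fk <- forward_kinematics(model, pose)
  O <- to_world(fk, mtu$origin$segment, mtu$origin$point)
  P <- to_world(fk, mtu$insertion$segment, mtu$insertion$point)
  c0 <- joint_center_world(model, fk, joint)
  a <- joint_axis_world(model, fk, joint, dof, pose)
  u <- unit3(O - P)
  sum(a * cross3(P - c0, u))
}

#' Generate a clade series of limb models with a programmed leverage trend
#'
#' Builds one parametric limb model per tip of the tree, scaling the target
#' muscle's leverage by a schedule that declines linearly with the tip's
#' main-line attachment position: the tips splitting at Archosauria carry
#' scale 1 and the Phasianidae tips carry `1 - decline`. For the pulley
#' target the true mean normalized moment arm scales exactly with the wrap
#' radius, so the programmed node-wise truth is the schedule itself.
#'
#' @param tree The phylogeny (default [study_tree()]).
#' @param params Base [limb_gen_params()] shared by all tips.
#' @param target Muscle whose leverage follows the schedule.
#' @param decline Total fractional decline across the main line (0.5 = -50%).
#' @param sign_flip_tip Optional tip name whose target-muscle leverage is
#'   negated (for switch-detection checks) by mirroring the pulley to the
#'   flexor side.
#' @return A list with `models` (named list of `limb_model`s), `schedule`
#'   (tibble `taxon`, `scale`, `true_value`) and `target`.
#' @export
generate_clade_series <- function(tree = study_tree(), params = limb_gen_params(),
                                  target = "AMB", decline = 0.5,
                                  sign_flip_tip = NULL) {
  main <- main_line_nodes()
  idx <- setNames(seq_along(main) - 1L, main)
  anc <- main_line_attachment(tree)
  scale <- 1 - decline * idx[anc] / (length(main) - 1L)
  names(scale) <- names(anc)
  base_gt <- attr(generate_limb(params), "ground_truth")
  base_val <- base_gt$true_mean_normalized[base_gt$mtu == target]
  models <- list()
  for (tp in tree$tip.label) {
    p <- params
    p$leverage_scale[target] <- unname(scale[tp])
    m <- generate_limb(p, taxon = tp)
    if (!is.null(sign_flip_tip) && tp %in% sign_flip_tip) {
      m <- mirror_pulley(m, target)
    }
    models[[tp]] <- m
  }
  flip <- as.integer(!tree$tip.label %in% (sign_flip_tip %||% character())) * 2L - 1L
  sched <- tibble::tibble(taxon = tree$tip.label,
                          scale = unname(scale[tree$tip.label]),
                          true_value = flip * unname(scale[tree$tip.label]) * base_val)
  list(models = models, schedule = sched, target = target)
}

# Flip a pulley muscle to the caudal side of its wrap cylinder, negating its
# moment arm (extensor -> flexor).
mirror_pulley <- function(model, target) {
  m <- model$mtus[[target]]
  wname <- m$wraps[1]
  w <- model$wraps[[wname]]
  w$wrap_side <- -w$wrap_side
  model$wraps[[wname]] <- w
  R <- w$radius[1]
  model$mtus[[target]]$origin$point <- w$center + c(0, 0, R)
  gt <- attr(model, "ground_truth")
  k <- gt$mtu == target
  gt[k, c("true_mean_mm", "true_mean_normalized")] <-
    -gt[k, c("true_mean_mm", "true_mean_normalized")]
  attr(model, "ground_truth") <- gt
  model
}

# For each tip, the main-line clade at (or nearest above) its attachment.
main_line_attachment <- function(tree) {
  main <- main_line_nodes()
  n <- ape::Ntip(tree)
  labs <- c(tree$tip.label, tree$node.label)
  out <- character(n)
  for (i in seq_len(n)) {
    nd <- i
    repeat {
      nd <- tree$edge[tree$edge[, 2] == nd, 1]
      if (length(nd) == 0) abort("tip not connected to root", class = "archolimb_data_error")
      if (labs[nd] %in% main) break
    }
    out[i] <- labs[nd]
  }
  setNames(out, tree$tip.label)
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Root-to-tip recursion with Gaussian increments of variance
#' `sig2 x branch length`; the true internal-node states are retained so
#' that ancestral-state estimators can be scored against them.
#'
#' @param tree A `phylo` object with positive branch lengths.
#' @param sig2 Brownian rate (trait variance per Ma), `>= 0`.
#' @param root_state Trait value at the root.
#' @param n_rep Number of independent replicates.
#' @param seed Integer seed.
#' @return A list with `tips` (`n_rep` x tips matrix) and `nodes`
#'   (`n_rep` x internal-node matrix, labeled, root included).
#' @export
simulate_bm <- function(tree, sig2 = 1, root_state = 0, n_rep = 1, seed = 1L) {
  if (sig2 < 0) abort("sig2 must be >= 0", class = "archolimb_config_error")
  if (any(tree$edge.length <= 0)) abort("branch lengths must be positive",
                                        class = "archolimb_data_error")
  set.seed(as.integer(seed))
  n <- ape::Ntip(tree)
  n_nodes <- tree$Nnode
  labs_nodes <- tree$node.label %||% as.character((n + 1L):(n + n_nodes))
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  el <- ape::reorder.phylo(tree, "cladewise")$edge.length
  states <- matrix(NA_real_, n_rep, n + n_nodes)
  states[, n + 1L] <- root_state
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    states[, ch] <- states[, par] + rnorm(n_rep, 0, sqrt(sig2 * el[k]))
  }
  tips <- states[, seq_len(n), drop = FALSE]
  colnames(tips) <- tree$tip.label
  nodes <- states[, (n + 1L):(n + n_nodes), drop = FALSE]
  colnames(nodes) <- labs_nodes
  list(tips = tips, nodes = nodes)
}

# family tag <-> joint/dof mapping for the archival ACE CSV dialect
ACE_FAMILIES <- tibble::tribble(
  ~family,    ~joint,  ~dof,
  "hip_Ex",   "hip",   "FLEXEX",
  "hip_Ab",   "hip",   "ABAD",
  "hip_Ro",   "hip",   "LAR",
  "knee_Ex",  "knee",  "FLEXEX",
  "ankle_Ex", "ankle", "FLEXEX"
)

#' Write ancestral-state tables in the archival CSV dialect
#'
#' One file per joint/DoF family (`hip_Ex`, `hip_Ab`, `hip_Ro`, `knee_Ex`,
#' `ankle_Ex`): rows are MTUs, columns ancestral nodes, first column header
#' `MTU`; companion `_CI_lower` / `_CI_upper` files carry the interval
#' bounds.
#'
#' @param ace_table Long `ace_table` from [ace_all()] (one tree variant).
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix inserted after the family tag.
#' @return Character vector of the estimate-file paths, invisibly.
#' @export
write_ace_csvs <- function(ace_table, dir, prefix = "ACE_data") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if ("tree" %in% names(ace_table) && length(unique(ace_table$tree)) > 1) {
    abort("write one tree variant at a time", class = "archolimb_data_error")
  }
  paths <- character()
  for (k in seq_len(nrow(ACE_FAMILIES))) {
    fam <- ACE_FAMILIES[k, ]
    sub <- ace_table[ace_table$joint == fam$joint & ace_table$dof == fam$dof, ]
    if (nrow(sub) == 0) next
    for (what in c("estimate", "ci95_lo", "ci95_hi")) {
      wide <- sub |>
        dplyr::select("mtu", "node", dplyr::all_of(what)) |>
        tidyr::pivot_wider(names_from = "node", values_from = dplyr::all_of(what)) |>
        dplyr::rename(MTU = "mtu")
      suffix <- switch(what, estimate = "", ci95_lo = "_CI_lower", ci95_hi = "_CI_upper")
      path <- file.path(dir, paste0(fam$family, "_", prefix, suffix, ".csv"))
      readr::write_csv(wide, path)
      if (what == "estimate") paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Read an ancestral-state table in the archival CSV dialect
#'
#' @param path Path to one family file (rows = MTUs, columns = nodes, first
#'   header `MTU`); the joint/DoF family is auto-detected from the filename.
#' @return A long tibble `joint`, `dof`, `mtu`, `node`, `estimate`.
#' @export
read_ace_csv <- function(path) {
  fam <- ACE_FAMILIES[vapply(ACE_FAMILIES$family, grepl, logical(1), x = basename(path)), ]
  if (nrow(fam) != 1) {
    abort(paste0("cannot infer joint/DoF family from filename: ", basename(path)),
          class = "archolimb_data_error")
  }
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (length(hdr) < 2 || hdr[1] != "MTU") {
    abort(paste0("malformed ACE table header in ", basename(path),
                 ": first column must be 'MTU'"),
          class = "archolimb_data_error")
  }
  readr::read_csv(path, show_col_types = FALSE) |>
    tidyr::pivot_longer(-"MTU", names_to = "node", values_to = "estimate") |>
    dplyr::transmute(joint = fam$joint, dof = fam$dof, mtu = .data$MTU,
                     node = .data$node, estimate = .data$estimate)
}
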