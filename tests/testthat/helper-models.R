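# Shared builders for geometric test fixtures. The "toy wrap model" places a
# hip joint 1 m below the region of interest so that pelvis- and femur-fixed
# attachments are effectively static world points at the reference pose,
# letting closed-form planar constructions be compared directly.

toy_wrap_model <- function(origin_xyz, insertion_xyz, surface = NULL,
                           wraps = character(), via = list()) {
  segs <- list(segment("pelvis", 100), segment("femur", 100))
  js <- list(place_joint(joint_spec("hip", c(0, 0, -1000)), segs[[1]]))
  mt <- mtu_path("CFL", attachment("pelvis", origin_xyz),
                 attachment("femur", insertion_xyz + c(0, 0, 1000)),
                 via = via, wraps = wraps)
  assemble_model("toy", segs, js, list(mt),
                 if (is.null(surface)) list() else list(surface))
}

toy_pose <- function(model) pose(model, hip = c(ABAD = 0))

# Independent planar 2D oracle: signed moment arm about the hip FLEXEX axis
# for a straight muscle with all points in the x-z plane equals
# cross2(P - c, u) in (x, z) coordinates, with u the unit vector from the
# insertion toward the origin.
planar_moment_arm_oracle <- function(origin_xz, insertion_xz_local, center_xz,
                                     theta_deg) {
  th <- theta_deg * pi / 180
  # positive FLEXEX about the right-lateral axis maps (x, z) -> rotated
  R2 <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  P <- center_xz + as.numeric(R2 %*% insertion_xz_local)
  u <- origin_xz - P
  u <- u / sqrt(sum(u^2))
  v <- P - center_xz
  v[1] * u[2] - v[2] * u[1]
}

# A minimal straight-muscle hip model in the sagittal plane: origin on the
# pelvis, insertion on the femur, no wraps.
planar_hip_model <- function(origin_xz, insertion_xz) {
  segs <- list(segment("pelvis", 250), segment("femur", 300))
  js <- list(place_joint(joint_spec("hip", c(0, 0, 0)), segs[[1]]))
  mt <- mtu_path("CFL", attachment("pelvis", c(origin_xz[1], 0, origin_xz[2])),
                 attachment("femur", c(insertion_xz[1], 0, insertion_xz[2])))
  assemble_model("planar", segs, js, list(mt))
}

sample_sphere_points <- function(n, center, radius, sd = 0, seed = 1) {
  set.seed(seed)
  th <- runif(n) * 2 * pi
  ph <- acos(runif(n) * 2 - 1)
  pts <- cbind(center[1] + radius * sin(ph) * cos(th),
               center[2] + radius * sin(ph) * sin(th),
               center[3] + radius * cos(ph))
  pts + matrix(rnorm(3 * n, 0, sd), n)
}

ring_points <- function(z, radius = 2, n = 8) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(radius * cos(a), radius * sin(a), z)
}

random_positive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.3
  tr
}

# Brute-force GLS oracle for the root state: builds the BM tip covariance
# matrix V from shared root-to-ancestor path lengths (independent of
# ape::vcv) and solves the closed form (1'V^-1 1)^-1 1'V^-1 x.
brute_force_root_gls <- function(tree, x) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- if (i == j) i else ape::getMRCA(tree, c(i, j))
      V[i, j] <- depth[a]
    }
  }
  Vi <- solve(V)
  sum(Vi %*% x[tree$tip.label]) / sum(Vi)
}

to_local_world <- function(fk, segment, point) archolimb:::to_world(fk, segment, point)
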