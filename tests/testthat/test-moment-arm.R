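test_that("a line of action through the joint center has zero moment arm", {
  m <- planar_hip_model(origin_xz = c(100, 100), insertion_xz = c(-60, -60))
  p <- pose(m, hip = c(ABAD = 0))
  expect_lt(abs(moment_arm(m, "CFL", "hip", "FLEXEX", pose = p)), 1e-9)
})

test_that("a tendon fully wrapped on a joint-coaxial cylinder is a pulley", {
  m <- generate_limb()
  R <- m$wraps$knee_cyl_AMB$radius
  cv <- sweep_rom(m, "AMB", "knee", "FLEXEX")
  expect_equal(nrow(cv), 101)  # -90..10 inclusive
  expect_lt(max(abs(abs(cv$moment_arm_mm) - R) / R), 1e-6)
  expect_true(all(cv$moment_arm_mm > 0))  # extensor side
})

test_that("finite differences match the planar perpendicular-distance oracle", {
  set.seed(1234)
  worst <- 0
  for (k in 1:60) {
    o <- c(runif(1, -150, 150), runif(1, -60, 120))
    i <- c(runif(1, -80, 80), runif(1, -260, -120))
    m <- planar_hip_model(o, i)
    th <- runif(1, -45, 65)
    p <- pose(m, hip = c(FLEXEX = th, ABAD = 0), warn_rom = FALSE)
    fd <- moment_arm(m, "CFL", "hip", "FLEXEX", pose = p)
    ex <- planar_moment_arm_oracle(o, i, c(0, 0), th)
    if (abs(ex) > 1) worst <- max(worst, abs(fd - ex) / abs(ex))
  }
  expect_lt(worst, 1e-6)
})

test_that("sweep grids cover the stated ranges of motion", {
  m <- generate_limb()
  expect_equal(nrow(sweep_rom(m, "CFL", "hip", "FLEXEX")), 111)  # -45..65
  expect_equal(nrow(sweep_rom(m, "CFL", "hip", "ABAD")), 46)     # -45..0
  expect_equal(nrow(sweep_rom(m, "CFL", "hip", "LAR")), 61)      # -30..30
  expect_equal(nrow(sweep_rom(m, "GL", "knee", "FLEXEX")), 101)  # -90..10
})

test_that("means normalize by segment length and scale out of the model", {
  const <- tibble::tibble(mtu = "CFL", joint = "hip", dof = "FLEXEX",
                          theta_deg = 0:100, moment_arm_mm = 30)
  row <- mean_normalized(const, segment("femur", 300))
  expect_equal(row$mean_normalized, 0.1)
  lin <- tibble::tibble(mtu = "CFL", joint = "hip", dof = "FLEXEX",
                        theta_deg = 0:100, moment_arm_mm = seq(10, 20, length.out = 101))
  expect_equal(mean_normalized(lin, segment("femur", 300))$mean_mm, 15)

  t1 <- sweep_model(generate_limb(limb_gen_params(femur_mm = 300)))
  t2 <- sweep_model(generate_limb(limb_gen_params(femur_mm = 600)))
  j <- dplyr::inner_join(t1, t2, by = c("mtu", "joint", "dof"))
  expect_equal(j$mean_normalized.x, j$mean_normalized.y, tolerance = 1e-9)
  expect_equal(2 * j$mean_mm.x, j$mean_mm.y, tolerance = 1e-9)
})

test_that("sub-head averaging is the arithmetic mean", {
  expect_equal(average_subheads(c(0.08, 0.10)), 0.09)
  expect_equal(average_subheads(c(0.3, 0.3)), 0.3)
  expect_equal(average_subheads(0.42), 0.42)
  expect_error(average_subheads(numeric()), class = "archolimb_config_error")
})

test_that("mirroring across the sagittal plane flips ABAD/LAR and keeps FLEXEX", {
  mk <- function(sgn) {
    segs <- list(segment("pelvis", 250), segment("femur", 300))
    js <- list(place_joint(joint_spec("hip", c(0, 0, 0)), segs[[1]]))
    mt <- mtu_path("CFL", attachment("pelvis", c(-60, sgn * 35, 20)),
                   attachment("femur", c(-10, sgn * 20, -90)))
    assemble_model("m", segs, js, list(mt))
  }
  m <- mk(1); mm <- mk(-1)
  p <- function(model) pose(model, hip = c(FLEXEX = 20, ABAD = 0, LAR = 0),
                            warn_rom = FALSE)
  # mirrored pose: ABAD/LAR angles negate along with the y coordinates
  for (dof in c("FLEXEX", "ABAD", "LAR")) {
    r <- moment_arm(m, "CFL", "hip", dof, pose = p(m))
    rm <- moment_arm(mm, "CFL", "hip", dof, pose = p(mm))
    if (dof == "FLEXEX") expect_equal(rm, r, tolerance = 1e-9)
    else expect_equal(rm, -r, tolerance = 1e-9)
  }
})
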