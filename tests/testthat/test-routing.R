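test_that("via-point paths without contact are polylines of straight segments", {
  m <- toy_wrap_model(c(-5, 3, 0), c(5, 3, 0),
                      via = list(attachment("pelvis", c(0, 10, 0))))
  pl <- route_path(m, toy_pose(m), "CFL")
  expect_equal(pl$length, sqrt(25 + 49) + sqrt(25 + 49))
  expect_length(pl$wrapped, 0)
})

test_that("obligatory cylinder wrap matches the planar tangent-arc-tangent closed form", {
  w <- wrap_surface("cyl", "cylinder", "pelvis", center = c(0, 0, 0),
                    axis = c(0, 0, 1), radius = 1, wrap_side = 1, mtus = "CFL")
  m <- toy_wrap_model(c(-5, 3, 0), c(5, 3, 0), surface = w, wraps = "cyl")
  pl <- route_path(m, toy_pose(m), "CFL")
  alpha <- acos(1 / sqrt(34))
  delta <- ((atan2(3, 5) - alpha) - (atan2(3, -5) + alpha)) %% (2 * pi)
  expect_equal(pl$length, 2 * sqrt(33) + delta, tolerance = 1e-12)
  expect_identical(pl$wrapped, "cyl")
  # every arc point lies on the surface
  r2 <- sqrt(rowSums(pl$points[, 1:2]^2))
  on_surf <- abs(r2 - 1) < 1e-6
  expect_gte(sum(on_surf), 10)
  # and the arc passes on the required side (y < 0)
  expect_lt(min(pl$points[, 2]), -0.9)
})

test_that("a segment clear of the cylinder on the free side stays straight", {
  w <- wrap_surface("cyl", "cylinder", "pelvis", center = c(0, 0, 0),
                    axis = c(0, 0, 1), radius = 1, wrap_side = 1, mtus = "CFL")
  m <- toy_wrap_model(c(-5, -3, 0), c(5, -3, 0), surface = w, wraps = "cyl")
  pl <- route_path(m, toy_pose(m), "CFL")
  expect_equal(pl$length, 10)
  expect_length(pl$wrapped, 0)
})

test_that("sphere wrap takes the shorter in-plane tangent-arc-tangent path", {
  w <- wrap_surface("sph", "sphere", "pelvis", center = c(0, 0, 0),
                    radius = 1, mtus = "CFL")
  m <- toy_wrap_model(c(-5, 0.3, 0), c(5, 0.3, 0), surface = w, wraps = "sph")
  pl <- route_path(m, toy_pose(m), "CFL")
  d <- sqrt(25.09)
  alpha <- acos(1 / d)
  d1 <- ((atan2(0.3, 5) - alpha) - (atan2(0.3, -5) + alpha)) %% (2 * pi)
  d2 <- ((atan2(0.3, -5) - alpha) - (atan2(0.3, 5) + alpha)) %% (2 * pi)
  expect_equal(pl$length, 2 * sqrt(d^2 - 1) + min(d1, d2), tolerance = 1e-12)
})

test_that("an ellipsoid with equal semi-axes reproduces the sphere geodesic", {
  wsph <- wrap_surface("sph", "sphere", "pelvis", center = c(0, 0, 0),
                       radius = 2, mtus = "CFL")
  well <- wrap_surface("ell", "ellipsoid", "pelvis", center = c(0, 0, 0),
                       radius = c(2, 2, 2), mtus = "CFL")
  msph <- toy_wrap_model(c(-6, 0.5, 0.4), c(6, 0.5, -0.4), surface = wsph, wraps = "sph")
  mell <- toy_wrap_model(c(-6, 0.5, 0.4), c(6, 0.5, -0.4), surface = well, wraps = "ell")
  Ls <- route_path(msph, toy_pose(msph), "CFL")$length
  Le <- route_path(mell, toy_pose(mell), "CFL")$length
  expect_equal(Le, Ls, tolerance = 2e-3)
})

test_that("attachments inside a wrap surface raise a geometry error", {
  w <- wrap_surface("cyl", "cylinder", "pelvis", center = c(0, 0, 0),
                    axis = c(0, 0, 1), radius = 2, wrap_side = 1, mtus = "CFL")
  m <- toy_wrap_model(c(0.5, 0.5, 0), c(5, 3, 0), surface = w, wraps = "cyl")
  expect_error(route_path(m, toy_pose(m), "CFL"),
               class = "archolimb_geometry_error")
})

test_that("path length is continuous through wrap engagement", {
  # insertion swings about the hip; the straight line grazes the cylinder at
  # tangency, where wrapped and unwrapped lengths must meet
  w <- wrap_surface("cyl", "cylinder", "pelvis", center = c(0, 0, -300),
                    axis = c(0, -1, 0), radius = 30, wrap_side = -1, mtus = "CFL")
  segs <- list(segment("pelvis", 100), segment("femur", 400))
  js <- list(place_joint(joint_spec("hip", c(0, 0, 0)), segs[[1]]))
  mt <- mtu_path("CFL", attachment("pelvis", c(150, 0, -100)),
                 attachment("femur", c(0, 0, -380)), wraps = "cyl")
  m <- assemble_model("cont", segs, js, list(mt), list(w))
  grid <- seq(-45, 65, by = 0.5)
  L <- vapply(grid, function(th) {
    route_path(m, pose(m, hip = c(FLEXEX = th, ABAD = 0)), "CFL")$length
  }, numeric(1))
  wrapped_any <- any(vapply(c(-45, 0, 65), function(th) {
    length(route_path(m, pose(m, hip = c(FLEXEX = th, ABAD = 0)), "CFL")$wrapped) > 0
  }, logical(1)))
  expect_true(wrapped_any)
  # maximum path speed is bounded by the insertion lever (~380 mm/rad)
  expect_lt(max(abs(diff(L))), 400 * 0.5 * pi / 180 * 1.2)
})
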