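test_that("cartilage gaps follow the stated fractions of proximal length", {
  femur <- segment("femur", 400)
  knee <- place_joint(joint_spec("knee", c(0, 0, -400)), femur)
  expect_equal(knee$gap_mm, 20)  # 5% of 400

  tt <- segment("tibiotarsus", 300)
  ankle <- place_joint(joint_spec("ankle", c(0, 0, -300)), tt)
  expect_equal(ankle$gap_mm, 22.5)  # 7.5% of 300
})

test_that("hip center superimposes the two fitted sphere centers with zero gap", {
  pelvis <- segment("pelvis", 250)
  s1 <- fit_sphere(sample_sphere_points(60, c(0, 0, 0), 30, seed = 1))
  s2 <- fit_sphere(sample_sphere_points(60, c(1, 0, 0), 30, seed = 2))
  hip <- place_joint(joint_spec("hip", c(9, 9, 9)), pelvis, list(s1, s2))
  expect_equal(hip$gap_mm, 0)
  expect_equal(hip$center, (s1$center + s2$center) / 2, tolerance = 1e-6)
  expect_equal(hip$center_discrepancy_mm, 1, tolerance = 1e-6)
})

test_that("assembly validates acronyms, segments and absence flags", {
  m <- generate_limb()
  expect_s3_class(m, "limb_model")
  expect_setequal(names(m$mtus), c("AMB", "CFL", "IT1", "GL"))

  p <- limb_gen_params(absent = "CFL")
  m2 <- generate_limb(p, taxon = "phasianid_grade")
  expect_false("CFL" %in% names(m2$mtus))
  expect_identical(m2$metadata$absent_mtus, "CFL")

  segs <- list(segment("pelvis", 100), segment("femur", 100))
  js <- list(place_joint(joint_spec("hip", c(0, 0, 0)), segs[[1]]))
  bad_name <- mtu_path("CFL", attachment("pelvis", c(0, 0, 0)),
                       attachment("femur", c(0, 0, -10)))
  bad_name$name <- "NOTAMUSCLE"
  expect_error(assemble_model("t", segs, js, list(bad_name)),
               class = "archolimb_config_error")
  expect_error(
    mtu_path("CFL", attachment("pelvis", c(0, 0, 0)),
             attachment("tibiotarsus", c(0, 0, 0))) |>
      list() |> (\(mt) assemble_model("t", segs, js, mt))(),
    class = "archolimb_config_error")
})

test_that("model specs round-trip through the YAML format", {
  m <- generate_limb(taxon = "roundtrip")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(m, path)
  m2 <- read_model_spec(path)
  expect_identical(m2$taxon, "roundtrip")
  expect_setequal(names(m2$mtus), names(m$mtus))
  expect_equal(m2$joints$knee$gap_mm, m$joints$knee$gap_mm)
  expect_equal(m2$wraps[[1]]$radius, m$wraps[[1]]$radius, tolerance = 1e-9)
  r1 <- moment_arm(m, "AMB", "knee")
  r2 <- moment_arm(m2, "AMB", "knee")
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("point clouds load from xyz and ascii STL", {
  pts <- sample_sphere_points(30, c(0, 0, 0), 5, seed = 9)
  xyz <- withr::local_tempfile(fileext = ".asc")
  utils::write.table(pts, xyz, row.names = FALSE, col.names = FALSE)
  rd <- read_point_cloud(xyz)
  expect_equal(dim(rd), c(30, 3))
  expect_equal(sort(rd[, 1]), sort(unname(pts[, 1])), tolerance = 1e-6)

  stl <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid toy",
               "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 1 0 0", "vertex 0 1 0",
               "endloop", "endfacet", "endsolid toy"), stl)
  tri <- read_point_cloud(stl)
  expect_equal(nrow(tri), 3)
  expect_equal(tri[2, ], c(1, 0, 0))
})
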