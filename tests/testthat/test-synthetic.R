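test_that("the pulley recipe records the wrap-proportion ground truth", {
  m <- generate_limb(limb_gen_params(femur_mm = 300))
  gt <- attr(m, "ground_truth")
  expect_equal(gt$true_mean_mm[gt$mtu == "AMB"], 0.1421 * 300)  # 42.63 mm
  expect_equal(m$wraps$knee_cyl_AMB$radius, 42.63)
  # engine agrees with the recorded truth
  tab <- sweep_model(m, joints = "knee")
  expect_equal(tab$mean_mm[tab$mtu == "AMB"], 42.63, tolerance = 1e-6)
})

test_that("straight-line ground truth comes from the geometric formula", {
  m <- generate_limb()
  gt <- attr(m, "ground_truth")
  tab <- sweep_model(m, joints = c("hip", "knee"))
  j <- dplyr::inner_join(gt, tab, by = c("mtu", "joint", "dof"))
  expect_gt(nrow(j), 2)
  expect_equal(j$true_mean_normalized, j$mean_normalized, tolerance = 1e-6)
})

test_that("generation is deterministic for identical parameters", {
  p <- limb_gen_params(seed = 7)
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(generate_limb(p), f1)
  write_model_spec(generate_limb(p), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("clade series program the leverage schedule onto the tips", {
  sr <- generate_clade_series(decline = 0.5)
  expect_equal(nrow(sr$schedule), 13)
  expect_equal(sr$schedule$scale[sr$schedule$taxon == "Crocodylus"], 1)
  expect_equal(sr$schedule$scale[sr$schedule$taxon == "Gallus"], 0.5)
  r_croc <- sr$models$Crocodylus$wraps$knee_cyl_AMB$radius
  r_gal <- sr$models$Gallus$wraps$knee_cyl_AMB$radius
  expect_equal(r_gal / r_croc, 0.5)

  sr0 <- generate_clade_series(decline = 0)
  expect_true(all(sr0$schedule$scale == 1))
  expect_equal(sr0$models$Gallus$wraps$knee_cyl_AMB$radius,
               sr0$models$Crocodylus$wraps$knee_cyl_AMB$radius)
})

test_that("Brownian simulation honors rate, root and seed", {
  st <- study_tree()
  s0 <- simulate_bm(st, sig2 = 0, root_state = 0.4, n_rep = 3, seed = 1)
  expect_true(all(s0$tips == 0.4))
  expect_true(all(s0$nodes == 0.4))

  tr2 <- read_timetree("(A:4,B:4)R;")
  sim <- simulate_bm(tr2, sig2 = 2.5, root_state = 0, n_rep = 10000, seed = 5)
  expect_equal(var(sim$tips[, "A"]), 2.5 * 4, tolerance = 0.05 * 10)
  expect_equal(mean(sim$tips[, "A"]), 0, tolerance = 0.1)

  a <- simulate_bm(st, 1, 0, n_rep = 4, seed = 99)
  b <- simulate_bm(st, 1, 0, n_rep = 4, seed = 99)
  expect_identical(a, b)
})

test_that("archival-dialect ACE CSVs round-trip and validate their header", {
  st <- study_tree()
  set.seed(31)
  traits <- tidyr::expand_grid(taxon = st$tip.label, mtu = paste0("M", 1:20)) |>
    dplyr::mutate(joint = "hip", dof = "FLEXEX",
                  mean_normalized = rnorm(dplyr::n(), 0, 0.1))
  tab <- ace_all(st, traits)
  dir <- withr::local_tempdir()
  paths <- write_ace_csvs(tab, dir)
  expect_length(paths, 1)  # one family present
  wide <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(dim(wide), c(20, 13))  # 20 MTUs x (MTU + 12 nodes)
  back <- read_ace_csv(paths[1])
  j <- dplyr::inner_join(back, tab, by = c("joint", "dof", "mtu", "node"))
  expect_equal(j$estimate.x, j$estimate.y, tolerance = 1e-12)

  bad <- file.path(dir, "hip_Ex_broken.csv")
  writeLines(c("muscle,n1,n2", "CFL,1,2"), bad)
  err <- tryCatch(read_ace_csv(bad), error = identity)
  expect_s3_class(err, "archolimb_data_error")
  expect_match(conditionMessage(err), "hip_Ex_broken.csv")
})
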