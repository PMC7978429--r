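test_that("Newick round-trips preserve topology, labels and lengths", {
  tr <- read_timetree("((A:1,B:1)N1:1,C:2)R;")
  expect_equal(ape::Ntip(tr), 3)
  expect_setequal(tr$node.label, c("N1", "R"))
  rt <- read_timetree(write_timetree(tr))
  expect_equal(rt$edge.length, tr$edge.length, tolerance = 1e-9)
  expect_identical(rt$tip.label, tr$tip.label)

  st <- study_tree()
  st2 <- read_timetree(write_timetree(st))
  expect_identical(ape::write.tree(st2), ape::write.tree(st))
  expect_error(read_timetree("((A:1,B:-1):1,C:1);"), class = "archolimb_data_error")
})

test_that("the study tree has the expected shape and calibration structure", {
  st <- study_tree()
  expect_equal(ape::Ntip(st), 13)
  expect_equal(nrow(st$edge), 24)
  expect_setequal(st$node.label, c(main_line_nodes(), "Dromaeosauridae"))
  expect_true(all(st$edge.length > 0))
})

test_that("punctuated branch lengths are all one and idempotent", {
  st <- study_tree()
  p1 <- punctuated_tree(st)
  expect_true(all(p1$edge.length == 1))
  expect_equal(length(p1$edge.length), 24)
  expect_identical(punctuated_tree(p1), p1)
})

test_that("two equal branches average and constant traits collapse", {
  tr <- read_timetree("(A:1,B:1)R;")
  fit <- ace_brownian(tr, c(A = 0, B = 1))
  expect_equal(fit$root_estimate, 0.5)

  st <- study_tree()
  x <- setNames(rep(0.37, 13), st$tip.label)
  fit <- ace_brownian(st, x)
  expect_equal(fit$nodes$estimate, rep(0.37, 12))
  expect_equal(fit$sig2, 0)
  expect_equal(fit$nodes$ci95_hi - fit$nodes$ci95_lo, rep(0, 12))
})

test_that("estimates agree with the brute-force GLS matrix oracle", {
  for (seed in 1:4) {
    n <- 3 + seed %% 4  # 3..6 tips
    tr <- random_positive_tree(n, seed)
    x <- setNames(rnorm(n, sd = 2), tr$tip.label)
    fit <- ace_brownian(tr, x)
    expect_equal(fit$root_estimate, brute_force_root_gls(tr, x), tolerance = 1e-8)
    fa <- phytools::fastAnc(tr, x, CI = TRUE)
    expect_equal(fit$nodes$estimate, as.numeric(fa$ace), tolerance = 1e-8)
    expect_equal(fit$nodes$ci95_lo, unname(fa$CI95[, 1]), tolerance = 1e-4)
    expect_true(all(fit$nodes$estimate >= min(x) - 1e-12 &
                      fit$nodes$estimate <= max(x) + 1e-12))
  }
})

test_that("ancestral estimation is affine-equivariant", {
  st <- study_tree()
  set.seed(21)
  x <- setNames(rnorm(13), st$tip.label)
  f0 <- ace_brownian(st, x)
  f1 <- ace_brownian(st, 3.5 * x - 2)
  expect_equal(f1$nodes$estimate, 3.5 * f0$nodes$estimate - 2, tolerance = 1e-10)
  w0 <- f0$nodes$ci95_hi - f0$nodes$ci95_lo
  w1 <- f1$nodes$ci95_hi - f1$nodes$ci95_lo
  expect_equal(w1, 3.5 * w0, tolerance = 1e-10)
})

test_that("ace_all matches per-trait fits cell by cell and validates taxa", {
  st <- study_tree()
  set.seed(8)
  traits <- tidyr::expand_grid(taxon = st$tip.label,
                               mtu = c("CFL", "IT1", "GL"),
                               joint = "hip", dof = "FLEXEX") |>
    dplyr::mutate(mean_normalized = rnorm(dplyr::n(), 0, 0.1))
  tab <- ace_all(st, traits, punctuated = TRUE)
  expect_setequal(unique(tab$tree), c("time", "punctuated"))
  expect_equal(nrow(tab), 2 * 3 * 12)
  for (mt in c("CFL", "GL")) {
    x <- traits |> dplyr::filter(.data$mtu == mt)
    fit <- ace_brownian(st, setNames(x$mean_normalized, x$taxon))
    sub <- tab[tab$tree == "time" & tab$mtu == mt, ]
    expect_equal(setNames(sub$estimate, sub$node)[fit$nodes$node],
                 setNames(fit$nodes$estimate, fit$nodes$node), tolerance = 1e-12)
  }
  bad <- dplyr::mutate(traits, taxon = ifelse(taxon == "Gallus", "Turkey", taxon))
  expect_error(ace_all(st, bad), class = "archolimb_data_error")
})

test_that("tidy and glance expose the fit in broom style", {
  st <- study_tree()
  fit <- ace_brownian(st, setNames(seq(0, 1, length.out = 13), st$tip.label))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("node", "estimate", "variance", "ci95_lo", "ci95_hi"))
  g <- glance(fit)
  expect_equal(g$n_tips, 13)
  expect_gte(g$sig2, 0)
})
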