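mk_ace <- function(df) {
  # df: tibble(mtu, node, estimate); fills hip FLEXEX family
  dplyr::mutate(df, joint = "hip", dof = "FLEXEX", .before = 1)
}

test_that("action sums split by per-node sign and conserve total magnitude", {
  tab <- mk_ace(tibble::tibble(mtu = c("A1", "A2", "A3"), node = "N",
                               estimate = c(0.1, -0.2, -0.3)))
  tab$mtu <- c("CFL", "CFB", "IT1")
  s <- sum_by_action(tab)
  expect_equal(s$sum_abs[s$action == "flexion"], 0.1)
  expect_equal(s$sum_abs[s$action == "extension"], 0.5)

  z <- mk_ace(tibble::tibble(mtu = c("CFL", "CFB"), node = "N", estimate = 0))
  sz <- sum_by_action(z)
  expect_equal(sz$sum_abs, c(0, 0))

  set.seed(99)
  big <- tidyr::expand_grid(mtu = paste0("M", 1:20), node = paste0("N", 1:12)) |>
    dplyr::mutate(joint = "knee", dof = "FLEXEX", estimate = rnorm(240))
  sb <- sum_by_action(big)
  for (nd in paste0("N", 1:12)) {
    e <- big$estimate[big$node == nd]
    pos <- sum(abs(e[e > 0])); neg <- sum(abs(e[e < 0]))  # naive loop oracle
    expect_equal(sb$sum_abs[sb$node == nd & sb$action == "extension"], pos)
    expect_equal(sb$sum_abs[sb$node == nd & sb$action == "flexion"], neg)
    expect_equal(pos + neg, sum(abs(e)), tolerance = 1e-12)
  }
})

test_that("hypothesis ratios divide the stated action sums", {
  sums <- tibble::tibble(joint = "hip", dof = "FLEXEX", node = c("N", "N"),
                         action = c("extension", "flexion"), sum_abs = c(2, 1))
  rs <- ratio_series(sums, "H1")
  expect_equal(rs$ratio, 2)
  sums$sum_abs <- c(1.3, 1.3)
  expect_equal(ratio_series(sums, "H1")$ratio, 1)
  sums$sum_abs <- c(2, 0)
  rs0 <- ratio_series(sums, "H1")
  expect_true(rs0$undefined)
  expect_true(is.na(rs0$ratio))
})

test_that("internodal changes flag the 20/10 thresholds exactly at >=", {
  nodes <- main_line_nodes()
  flat <- tibble::tibble(node = nodes, ratio = 2)
  cf <- internodal_changes(flat)
  expect_true(all(cf$pct_change == 0))
  expect_false(any(cf$reliable | cf$notable))

  two <- tibble::tibble(node = nodes[1:2], ratio = c(2, 1.5))
  ct <- internodal_changes(two, main_line = nodes[1:2])
  expect_equal(ct$pct_change[ct$segment == "main"], -25)
  expect_true(ct$reliable[ct$segment == "main"])

  vals <- rep(1, 11)
  vals[6:11] <- 0.78  # one engineered -22% step
  ser <- tibble::tibble(node = nodes, ratio = vals)
  cr <- internodal_changes(ser)
  main <- cr[cr$segment == "main", ]
  expect_equal(sum(main$reliable), 1)
  expect_equal(main$to[main$reliable], nodes[6])

  exact <- internodal_changes(tibble::tibble(node = nodes[1:2], ratio = c(1, 0.8)),
                              main_line = nodes[1:2])
  expect_true(exact$reliable[1])   # -20% is >= the threshold
  expect_true(all(cr$notable[cr$reliable]))  # reliable implies notable
})

test_that("sign switches count transitions with zeros taking neighbor signs", {
  nodes <- main_line_nodes()[1:3]
  none <- mk_ace(tibble::tibble(mtu = "CFL", node = nodes, estimate = c(-1, -2, -0.5)))
  expect_equal(nrow(detect_switches(none, nodes)), 0)

  two <- mk_ace(tibble::tibble(mtu = "CFL", node = nodes, estimate = c(1, -1, 2)))
  ev <- detect_switches(two, nodes)
  expect_equal(nrow(ev), 2)

  zer <- mk_ace(tibble::tibble(mtu = "CFL", node = nodes, estimate = c(1, 0, -1)))
  expect_equal(nrow(detect_switches(zer, nodes)), 1)  # zero joins nearer (+) side
  allz <- mk_ace(tibble::tibble(mtu = "CFL", node = nodes, estimate = c(0, 0, 0)))
  expect_equal(nrow(detect_switches(allz, nodes)), 0)
})

test_that("extrema locate argmax/argmin with earlier-node tie-breaks", {
  nodes <- main_line_nodes()
  mono <- mk_ace(tibble::tibble(mtu = "CFL", node = nodes,
                                estimate = -seq(0.1, 1.1, length.out = 11)))
  ex <- detect_extrema(mono, nodes)
  expect_equal(ex$node[ex$kind == "peak"], nodes[11])
  expect_equal(ex$node[ex$kind == "minimum"], nodes[1])

  const <- mk_ace(tibble::tibble(mtu = "CFL", node = nodes, estimate = 0.2))
  exc <- detect_extrema(const, nodes)
  expect_equal(exc$node, rep(nodes[1], 2))
  expect_true(all(exc$tie))

  set.seed(4)
  rnd <- mk_ace(tibble::tibble(mtu = "CFL", node = nodes, estimate = rnorm(11)))
  exr <- detect_extrema(rnd, nodes)
  x <- rnd$estimate
  s <- sign(x)
  if (length(unique(s[s != 0])) == 1) {
    expect_equal(exr$node[exr$kind == "peak"], nodes[which.max(abs(x))])
    expect_equal(exr$node[exr$kind == "minimum"], nodes[which.min(abs(x))])
  } else {
    for (sg in unique(s[s != 0])) {
      k <- which(s == sg)[which.max(abs(x)[s == sg])]
      expect_true(nodes[k] %in% exr$node[exr$kind == "peak" & exr$sign == sg])
    }
  }
})

test_that("all ratio statistics are invariant to positive rescaling", {
  set.seed(12)
  nodes <- main_line_nodes()
  tab <- tidyr::expand_grid(mtu = paste0("M", 1:6), node = nodes) |>
    dplyr::mutate(joint = "knee", dof = "FLEXEX", estimate = rnorm(66))
  run <- function(t) {
    rs <- ratio_series(sum_by_action(t), "H2", node_order = nodes)
    internodal_changes(rs)
  }
  tab_k <- dplyr::mutate(tab, estimate = estimate * 7.3)
  expect_equal(run(tab)$pct_change, run(tab_k)$pct_change, tolerance = 1e-10)
  expect_identical(detect_switches(tab, nodes), detect_switches(tab_k, nodes))
  e1 <- detect_extrema(tab, nodes)
  e2 <- detect_extrema(tab_k, nodes)
  expect_identical(e1$node, e2$node)
})

test_that("verdict logic follows the threshold rule", {
  nodes <- main_line_nodes()
  flat <- internodal_changes(tibble::tibble(node = nodes, ratio = 1.5))
  halve <- internodal_changes(tibble::tibble(node = nodes,
                                             ratio = c(rep(2, 5), rep(1, 6))))
  rise <- internodal_changes(tibble::tibble(node = nodes,
                                            ratio = c(rep(0.2, 4), rep(0.5, 7))))
  rep1 <- hypothesis_report(list(time = list(H1 = flat, H2 = halve, H3 = rise)))
  expect_equal(rep1$verdict, c("constant", "supported", "supported"))
  rep2 <- hypothesis_report(list(time = list(H1 = halve, H2 = rise, H3 = halve)))
  expect_equal(rep2$verdict, c("rejected", "not supported", "not supported"))
})
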