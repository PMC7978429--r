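# Ratio/threshold trend analysis of ancestral moment-arm estimates: classify
# each estimate by action direction from its sign at each node, sum absolute
# values per action, form the hypothesis ratios, and flag internodal changes
# against the a-priori >=20% (reliable) and >=10% (notable) thresholds.

#' Sign conventions mapping moment-arm signs to muscle actions
#'
#' Positive and negative action labels per joint and degree of freedom:
#' hip flexion(+)/extension(-), hip adduction(+)/abduction(-), hip medial(+)/
#' lateral(-) long-axis rotation, knee extension(+)/flexion(-), ankle
#' dorsiflexion(+)/plantarflexion(-).
#'
#' @return A tibble with columns `joint`, `dof`, `positive`, `negative`.
#' @export
action_sign_convention <- function() {
  tibble::tribble(
    ~joint,  ~dof,     ~positive,      ~negative,
    "hip",   "FLEXEX", "flexion",      "extension",
    "hip",   "ABAD",   "adduction",    "abduction",
    "hip",   "LAR",    "medial_rotation", "lateral_rotation",
    "knee",  "FLEXEX", "extension",    "flexion",
    "ankle", "FLEXEX", "dorsiflexion", "plantarflexion"
  )
}

#' Sum absolute ancestral estimates by action direction
#'
#' For each node and joint/DoF family, sums the absolute values of all MTU
#' estimates whose sign at that node matches the action; membership is
#' decided per node, so a muscle that switches sign migrates between the two
#' sums. Zero estimates contribute to neither direction.
#'
#' @param ace_table An `ace_table` (long) from [ace_all()], or any tibble
#'   with columns `joint`, `dof`, `mtu`, `node`, `estimate` (and optionally
#'   `tree`).
#' @param convention Action labels, see [action_sign_convention()].
#' @return A tibble with columns (`tree`,) `joint`, `dof`, `node`, `action`,
#'   `sum_abs`, where `action` covers both directions of each family.
#' @export
sum_by_action <- function(ace_table, convention = action_sign_convention()) {
  grp <- intersect(c("tree", "joint", "dof", "node"), names(ace_table))
  long <- ace_table |>
    dplyr::left_join(convention, by = c("joint", "dof")) |>
    dplyr::mutate(action = dplyr::case_when(
      .data$estimate > 0 ~ .data$positive,
      .data$estimate < 0 ~ .data$negative,
      TRUE ~ NA_character_))
  sums <- long |>
    dplyr::filter(!is.na(.data$action)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "action")))) |>
    dplyr::summarise(sum_abs = sum(abs(.data$estimate)), .groups = "drop")
  # make both directions explicit (all-zero columns give two zero sums)
  frame <- long |>
    dplyr::distinct(dplyr::across(dplyr::all_of(grp)), .data$positive, .data$negative) |>
    tidyr::pivot_longer(c("positive", "negative"), values_to = "action") |>
    dplyr::select(-"name")
  frame |>
    dplyr::left_join(sums, by = c(grp, "action")) |>
    dplyr::mutate(sum_abs = tidyr::replace_na(.data$sum_abs, 0))
}

HYPOTHESIS_RATIOS <- list(
  H1 = list(joint = "hip", dof = "FLEXEX", num = "extension", den = "flexion"),
  H2 = list(joint = "knee", dof = "FLEXEX", num = "flexion", den = "extension"),
  H3 = list(joint = "hip", dof = "LAR", num = "medial_rotation",
            den_joint = "hip", den_dof = "ABAD", den = "abduction")
)

#' Node-wise ratio of summed moment arms for one hypothesis
#'
#' H1 is summed hip extensor over summed hip flexor estimates, H2 knee
#' flexor over knee extensor, and H3 hip medial long-axis rotator over hip
#' abductor. Nodes with a zero denominator are flagged undefined.
#'
#' @param sums Output of [sum_by_action()].
#' @param hypothesis `"H1"`, `"H2"` or `"H3"`.
#' @param node_order Node ordering for the output (default: order of
#'   appearance).
#' @return A tibble of class `ratio_series` with columns (`tree`,) `node`,
#'   `ratio`, `undefined`.
#' @export
ratio_series <- function(sums, hypothesis = c("H1", "H2", "H3"),
                         node_order = NULL) {
  hypothesis <- match.arg(hypothesis)
  h <- HYPOTHESIS_RATIOS[[hypothesis]]
  den_joint <- h$den_joint %||% h$joint
  den_dof <- h$den_dof %||% h$dof
  grp <- intersect(c("tree", "node"), names(sums))
  num <- sums |>
    dplyr::filter(.data$joint == h$joint, .data$dof == h$dof, .data$action == h$num) |>
    dplyr::select(dplyr::all_of(grp), num = "sum_abs")
  den <- sums |>
    dplyr::filter(.data$joint == den_joint, .data$dof == den_dof, .data$action == h$den) |>
    dplyr::select(dplyr::all_of(grp), den = "sum_abs")
  out <- dplyr::inner_join(num, den, by = grp) |>
    dplyr::mutate(ratio = ifelse(.data$den > 0, .data$num / .data$den, NA_real_),
                  undefined = .data$den <= 0,
                  hypothesis = hypothesis) |>
    dplyr::select(dplyr::all_of(grp), "hypothesis", "ratio", "undefined")
  if (!is.null(node_order)) {
    out <- out |>
      dplyr::mutate(node = factor(.data$node, levels = node_order)) |>
      dplyr::arrange(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::mutate(node = as.character(.data$node))
  }
  class(out) <- c("ratio_series", class(out))
  out
}

#' Internodal percentage changes along the main line
#'
#' Computes the percent change of a node series between consecutive
#' main-line nodes, `(R[i+1] - R[i]) / R[i] * 100`, flags changes of
#' magnitude >= 20% as `reliable` and >= 10% as `notable` (thresholds applied
#' to unrounded values), reports the off-line Dromaeosauridae node against
#' its parent Eumaniraptora separately, and the overall first-to-last change.
#'
#' @param series A tibble with columns `node` and a value column (`ratio` by
#'   default); one tree variant at a time.
#' @param main_line Main-line node order, see [main_line_nodes()].
#' @param value Name of the value column.
#' @param offline Named character vector mapping off-line nodes to the
#'   main-line node they are compared against.
#' @return A `change_report` tibble with columns `from`, `to`, `pct_change`,
#'   `reliable`, `notable`, `segment` (`"main"`, `"offline"`, `"overall"`).
#' @export
internodal_changes <- function(series, main_line = main_line_nodes(),
                               value = "ratio",
                               offline = c(Dromaeosauridae = "Eumaniraptora")) {
  v <- setNames(series[[value]], series$node)
  main_line <- main_line[main_line %in% names(v)]
  if (length(main_line) < 2) abort("need at least two main-line nodes",
                                   class = "archolimb_data_error")
  pct <- function(from, to) (v[to] - v[from]) / v[from] * 100
  rows <- tibble::tibble(
    from = main_line[-length(main_line)],
    to = main_line[-1],
    pct_change = unname(pct(main_line[-length(main_line)], main_line[-1])),
    segment = "main")
  off <- offline[names(offline) %in% names(v) & offline %in% names(v)]
  if (length(off)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      from = unname(off), to = names(off),
      pct_change = unname(pct(unname(off), names(off))), segment = "offline"))
  }
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    from = main_line[1], to = main_line[length(main_line)],
    pct_change = unname(pct(main_line[1], main_line[length(main_line)])),
    segment = "overall"))
  # thresholds apply exactly at >=, with a 1e-9 point guard against binary
  # rounding of the percentage itself
  rows <- dplyr::mutate(rows,
                        reliable = !is.na(.data$pct_change) & abs(.data$pct_change) >= 20 - 1e-9,
                        notable = !is.na(.data$pct_change) & abs(.data$pct_change) >= 10 - 1e-9)
  class(rows) <- c("change_report", class(rows))
  rows
}

#' Detect sign switches of ancestral estimates across nodes
#'
#' A switch event is a pair of consecutive nodes (in the given order) whose
#' estimates have opposite signs. Zero estimates take the sign of the nearer
#' nonzero neighbor (the earlier one on ties); an all-zero series has no
#' events.
#'
#' @param ace_table Long tibble with `mtu`, `joint`, `dof`, `node`,
#'   `estimate` (one tree variant).
#' @param node_order Node order, e.g. `c(main_line_nodes(), "Dromaeosauridae")`
#'   with the off-line node excluded by default.
#' @return A tibble of events: `mtu`, `joint`, `dof`, `from`, `to`.
#' @export
detect_switches <- function(ace_table, node_order = main_line_nodes()) {
  ace_table |>
    dplyr::filter(.data$node %in% node_order) |>
    dplyr::group_by(.data$mtu, .data$joint, .data$dof) |>
    dplyr::group_modify(function(d, key) {
      x <- setNames(d$estimate, d$node)[node_order]
      s <- effective_signs(unname(x))
      k <- which(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0)
      tibble::tibble(from = node_order[k], to = node_order[k + 1L])
    }) |>
    dplyr::ungroup()
}

# Replace zeros by the sign of the nearest nonzero value (earlier node wins
# ties); all-zero input stays zero.
effective_signs <- function(x) {
  s <- sign(x)
  nz <- which(s != 0)
  if (length(nz) == 0) return(s)
  for (i in which(s == 0)) {
    d <- abs(nz - i)
    s[i] <- s[nz[which.min(d)]]  # which.min takes the earlier on ties
  }
  s
}

#' Peak and minimum nodes of ancestral estimate series
#'
#' For each muscle x DoF: the peak is the node with the largest absolute
#' estimate (reported per sign for muscles that switch sign); the minimum
#' (value closest to zero) is reported only for non-switching muscles,
#' mirroring the way extrema are annotated on evolutionary moment-arm plots.
#' Ties break toward the earlier node and are flagged.
#'
#' @inheritParams detect_switches
#' @return A tibble: `mtu`, `joint`, `dof`, `kind` (`"peak"`/`"minimum"`),
#'   `sign`, `node`, `value`, `tie`.
#' @export
detect_extrema <- function(ace_table, node_order = main_line_nodes()) {
  ace_table |>
    dplyr::filter(.data$node %in% node_order) |>
    dplyr::group_by(.data$mtu, .data$joint, .data$dof) |>
    dplyr::group_modify(function(d, key) {
      x <- setNames(d$estimate, d$node)[node_order]
      s <- effective_signs(unname(x))
      switching <- length(unique(s[s != 0])) > 1
      rows <- list()
      signs_present <- if (switching) unique(s[s != 0]) else 1
      for (sg in signs_present) {
        xx <- if (switching) ifelse(s == sg, abs(x), -Inf) else abs(x)
        k <- which.max(xx)  # earliest index on exact ties
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = "peak", sign = if (switching) sg else sign(x[k]),
          node = node_order[k], value = unname(x[k]),
          tie = sum(xx == xx[k]) > 1)
      }
      if (!switching) {
        k <- which.min(abs(x))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = "minimum", sign = sign(x[k]), node = node_order[k],
          value = unname(x[k]), tie = sum(abs(x) == abs(x)[k]) > 1)
      }
      dplyr::bind_rows(rows)
    }) |>
    dplyr::ungroup()
}

#' Hypothesis verdicts from ratio change reports
#'
#' H1 (constant hip extensor/flexor ratio) holds iff no reliable (>=20%)
#' internodal change occurs on the main line. H2 (declining knee
#' flexor/extensor ratio) is supported iff the overall change is negative
#' with at least one reliable decrease; H3 (rising hip medial-rotator/
#' abductor ratio) iff the overall change is positive with at least one
#' reliable increase. Verdicts are reported for the time-calibrated tree and,
#' when supplied, the punctuated (branch lengths = 1) variant.
#'
#' @param changes Named list of `change_report`s: `changes$time$H1` etc.
#' @return A tibble: `tree`, `hypothesis`, `verdict`, `overall_pct`,
#'   `n_reliable`.
#' @export
hypothesis_report <- function(changes) {
  out <- list()
  for (vn in names(changes)) {
    for (h in names(changes[[vn]])) {
      cr <- changes[[vn]][[h]]
      main <- cr[cr$segment == "main", ]
      overall <- cr$pct_change[cr$segment == "overall"]
      verdict <- if (length(overall) != 1 || is.na(overall)) {
        "undetermined"
      } else {
        switch(h,
          H1 = if (!any(main$reliable)) "constant" else "rejected",
          H2 = if (overall < 0 && any(main$reliable & main$pct_change < 0, na.rm = TRUE))
            "supported" else "not supported",
          H3 = if (overall > 0 && any(main$reliable & main$pct_change > 0, na.rm = TRUE))
            "supported" else "not supported")
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        tree = vn, hypothesis = h, verdict = verdict,
        overall_pct = overall, n_reliable = sum(main$reliable))
    }
  }
  dplyr::bind_rows(out)
}
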