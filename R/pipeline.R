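#' Run the full leverage-evolution pipeline
#'
#' Orchestrates the stages model acquisition -> range-of-motion sweeps ->
#' mean normalized trait table -> Brownian-motion ancestral states (time
#' tree, and optionally the punctuated branch-lengths-=-1 variant) -> summed
#' moment-arm ratio and threshold trend reports, writing all outputs as CSV
#' plus a YAML run manifest. Outputs are deterministic for a given
#' configuration and seed; a rerun writes byte-identical tables.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `out_dir` (required); `tree_file` (Newick; default: the packaged study
#'   tree); either `model_files` (character vector of model-spec YAML paths)
#'   or `synthetic` (list passed to [generate_clade_series()]: `target`,
#'   `decline`, `sign_flip_tip`); `joints` (default all modeled);
#'   `step`, `h` (degrees); `punctuated` (default `TRUE`); `seed`.
#' @return Invisibly, a list with the trait table, ACE table, ratio series,
#'   change reports, verdicts and file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config),
                                    class = "archolimb_config_error")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) abort("config needs an out_dir",
                                     class = "archolimb_config_error")
  if (!is.null(config$tree_file) && !file.exists(config$tree_file)) {
    abort(paste0("tree file not found: ", config$tree_file),
          class = "archolimb_config_error")
  }
  if (!is.null(config$model_files)) {
    missing <- config$model_files[!file.exists(config$model_files)]
    if (length(missing)) abort(paste0("model spec not found: ", missing[1]),
                               class = "archolimb_config_error")
  }
  set.seed(as.integer(config$seed %||% 1L))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tree <- if (is.null(config$tree_file)) study_tree() else read_timetree(config$tree_file)

  # stage 1: models
  if (!is.null(config$model_files)) {
    models <- lapply(config$model_files, read_model_spec,
                     roster_check = !isFALSE(config$roster_check))
    names(models) <- vapply(models, `[[`, character(1), "taxon")
    schedule <- NULL
  } else {
    syn <- config$synthetic %||% list()
    series <- generate_clade_series(
      tree = tree,
      params = syn$params %||% limb_gen_params(),
      target = syn$target %||% "AMB",
      decline = syn$decline %||% 0.5,
      sign_flip_tip = syn$sign_flip_tip %||% NULL)
    models <- series$models
    schedule <- series$schedule
    readr::write_csv(schedule, file.path(out_dir, "synthetic_schedule.csv"))
  }
  if (!setequal(names(models), tree$tip.label)) {
    abort("model taxa do not match the tree's tips", class = "archolimb_data_error")
  }

  # stage 2: sweeps -> complete trait table (lost muscles as 0, flagged)
  tabs <- lapply(names(models), function(tx) {
    sweep_model(models[[tx]], joints = config$joints,
                step = config$step %||% 1, h = config$h %||% 0.25)
  })
  swept <- dplyr::bind_rows(tabs) |> dplyr::filter(!.data$lost)
  frame <- tidyr::expand_grid(taxon = tree$tip.label,
                              dplyr::distinct(swept, .data$mtu, .data$joint, .data$dof))
  traits <- frame |>
    dplyr::left_join(swept, by = c("taxon", "mtu", "joint", "dof")) |>
    dplyr::mutate(lost = is.na(.data$mean_normalized),
                  mean_normalized = tidyr::replace_na(.data$mean_normalized, 0),
                  mean_mm = tidyr::replace_na(.data$mean_mm, 0))
  readr::write_csv(traits, file.path(out_dir, "mean_normalized_traits.csv"))

  # stage 3: ancestral states
  ace <- ace_all(tree, traits, punctuated = !isFALSE(config$punctuated))
  for (vn in unique(ace$tree)) {
    write_ace_csvs(ace[ace$tree == vn, ], file.path(out_dir, paste0("ace_", vn)))
  }

  # stage 4: trends
  sums <- sum_by_action(ace)
  node_order <- c(main_line_nodes(), "Dromaeosauridae")
  ratios <- list()
  changes <- list()
  for (vn in unique(ace$tree)) {
    changes[[vn]] <- list()
    for (h in names(HYPOTHESIS_RATIOS)) {
      rs <- ratio_series(sums[sums$tree == vn, ], h, node_order = node_order)
      if (all(rs$undefined)) next
      ratios[[paste(vn, h)]] <- rs
      changes[[vn]][[h]] <- internodal_changes(rs)
    }
  }
  ratio_tbl <- dplyr::bind_rows(ratios)
  change_tbl <- dplyr::bind_rows(lapply(names(changes), function(vn) {
    dplyr::bind_rows(lapply(names(changes[[vn]]), function(h) {
      dplyr::mutate(changes[[vn]][[h]], tree = vn, hypothesis = h, .before = 1)
    }))
  }))
  verdicts <- hypothesis_report(changes)
  switches <- detect_switches(ace[ace$tree == "time", ])
  extrema <- detect_extrema(ace[ace$tree == "time", ])
  readr::write_csv(ratio_tbl, file.path(out_dir, "ratio_series.csv"))
  readr::write_csv(change_tbl, file.path(out_dir, "internodal_changes.csv"))
  readr::write_csv(verdicts, file.path(out_dir, "hypothesis_verdicts.csv"))
  readr::write_csv(switches, file.path(out_dir, "sign_switches.csv"))
  readr::write_csv(extrema, file.path(out_dir, "extrema.csv"))

  # stage 5: manifest
  manifest <- list(
    package_version = as.character(utils::packageVersion("archolimb")),
    settings = config[setdiff(names(config), "out_dir")],
    tree = list(tips = ape::Ntip(tree), newick = write_timetree(tree)),
    taxa = sort(names(models)),
    outputs = list.files(out_dir))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(traits = traits, ace = ace, ratios = ratio_tbl,
                 changes = change_tbl, verdicts = verdicts,
                 switches = switches, extrema = extrema,
                 schedule = schedule, out_dir = out_dir))
}
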