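# End-to-end pipelines: morphometrics + mechanics, and phylogeny.
#
# A single config (R list or YAML file) names the inputs, mode flags, and
# search settings; each run writes CSV/TPS/Newick outputs plus a JSON
# manifest with the seed and content hashes, so identical config + seed
# reproduces identical files.

#' Pipeline configuration
#'
#' @param landmarks,sliders,levers,matrix Input file paths (TPS or CSV for
#'   landmarks; CSV slider and lever tables; TNT or NEXUS matrix). Only
#'   the inputs a stage needs must be present.
#' @param output_dir Output directory.
#' @param sliding_criterion `"bending"` or `"procrustes"`.
#' @param residual_convention `"vertical"` or `"perpendicular"` SMA
#'   residuals.
#' @param reps,hold,swap Heuristic-search settings (see
#'   [branch_swap_search()]).
#' @param ordered,exclude 1-based character indices overriding the matrix
#'   file's settings.
#' @param matrix_format `"auto"`, `"tnt"`, or `"nexus"`.
#' @param flip_y Mirror landmark y coordinates on input.
#' @param figures Also write figure files (PNG).
#' @param seed Integer seed recorded in the manifest and used for every
#'   stochastic step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(landmarks = NULL, sliders = NULL, levers = NULL,
                            matrix = NULL, output_dir = tempfile("clawmorph_"),
                            sliding_criterion = c("bending", "procrustes"),
                            residual_convention = c("vertical", "perpendicular"),
                            reps = 100, hold = 10,
                            swap = c("tbr", "spr", "nni"),
                            ordered = NULL, exclude = NULL,
                            matrix_format = c("auto", "tnt", "nexus"),
                            flip_y = FALSE, figures = FALSE, seed = 1) {
  cfg <- list(landmarks = landmarks, sliders = sliders, levers = levers,
              matrix = matrix, output_dir = output_dir,
              sliding_criterion = match.arg(sliding_criterion),
              residual_convention = match.arg(residual_convention),
              reps = reps, hold = hold, swap = match.arg(swap),
              ordered = ordered, exclude = exclude,
              matrix_format = match.arg(matrix_format),
              flip_y = flip_y, figures = figures, seed = as.integer(seed))
  for (f in c("landmarks", "sliders", "levers", "matrix")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(paste0("config input ", f, " does not exist: ", cfg[[f]]))
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "': ", conditionMessage(e)))
  })
}

write_manifest <- function(cfg, dir, files) {
  manifest <- list(
    package = "clawmorph",
    version = as.character(utils::packageVersion("clawmorph")),
    seed = cfg$seed,
    config = cfg[!vapply(cfg, is.null, TRUE)],
    files = as.list(tools::md5sum(file.path(dir, files)) |>
                      stats::setNames(files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the morphometrics + mechanics pipeline
#'
#' Landmarks -> GPA (with sliding when a slider table is given) -> PCA
#' with sign orientation -> lever mechanics -> SMA regressions of MA on
#' the leading PCs, Welch group tests, and grouped five-number summaries.
#' Writes `aligned_coordinates.csv`, `consensus.tps`, `pc_scores.csv`,
#' `pc_variance.csv`, `biomechanics.csv`, `statistics.csv`, and
#' `manifest.json` (plus figures when configured) to the output directory.
#'
#' @param config A `pipeline_config` with at least `landmarks`.
#' @return Invisibly, a list with the in-memory results (`gpa`, `space`,
#'   `scores`, `stats`, `output_dir`).
#' @export
run_morphometrics <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$landmarks)) abort("config needs a landmarks input")
  set.seed(config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  lmk <- run_stage("landmarks", {
    if (grepl("\\.tps$", config$landmarks, ignore.case = TRUE)) {
      read_tps(config$landmarks, flip_y = config$flip_y)
    } else {
      read_landmark_csv(config$landmarks, flip_y = config$flip_y)
    }
  })
  k <- landmarks_k(lmk)
  sliders <- NULL
  if (!is.null(config$sliders)) {
    sliders <- run_stage("sliders", read_sliders(config$sliders, k))
  } else {
    warn("no slider table configured: running plain GPA (all landmarks fixed)")
  }
  fit <- run_stage("gpa", gpa(lmk, sliders = sliders,
                              mode = config$sliding_criterion))
  space <- run_stage("pca", orient_axes(shape_pca(fit)))
  scores <- NULL
  stats_tbl <- tibble()
  if (!is.null(config$levers)) {
    levers <- run_stage("levers", read_levers(config$levers))
    scores <- run_stage("mechanics", claw_scores(levers))
    stats_tbl <- run_stage("statistics",
                           morpho_statistics(space, scores,
                                             config$residual_convention))
  }
  files <- character(0)
  od <- config$output_dir
  readr::write_csv(fit$aligned, file.path(od, "aligned_coordinates.csv"),
                   progress = FALSE)
  write_tps(mutate(fit$consensus, specimen = "consensus"),
            file.path(od, "consensus.tps"))
  readr::write_csv(space$scores, file.path(od, "pc_scores.csv"),
                   progress = FALSE)
  readr::write_csv(variance_table(space), file.path(od, "pc_variance.csv"),
                   progress = FALSE)
  files <- c(files, "aligned_coordinates.csv", "consensus.tps",
             "pc_scores.csv", "pc_variance.csv")
  if (!is.null(scores)) {
    readr::write_csv(scores, file.path(od, "biomechanics.csv"),
                     progress = FALSE)
    readr::write_csv(stats_tbl, file.path(od, "statistics.csv"),
                     progress = FALSE)
    files <- c(files, "biomechanics.csv", "statistics.csv")
  }
  if (isTRUE(config$figures)) {
    ggplot2::ggsave(file.path(od, "morphospace.png"), autoplot(space),
                    width = 6, height = 5, dpi = 150)
    files <- c(files, "morphospace.png")
    if (!is.null(scores)) {
      ggplot2::ggsave(file.path(od, "mechanics_boxplots.png"),
                      plot_mechanics(scores), width = 8, height = 4, dpi = 150)
      files <- c(files, "mechanics_boxplots.png")
    }
  }
  write_manifest(config, od, files)
  invisible(list(gpa = fit, space = space, scores = scores,
                 stats = stats_tbl, output_dir = od))
}

# tidy table of SMA, Welch, and summary statistics for the score set
morpho_statistics <- function(space, scores, residual_convention) {
  joined <- inner_join(space$scores, scores, by = "specimen")
  out <- list()
  for (pc in c("PC1", "PC2")) {
    fit <- tryCatch(sma_fit(joined, !!rlang::sym(pc), MA),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      res <- sma_residual(fit,
                          perpendicular = residual_convention == "perpendicular")
      out[[length(out) + 1L]] <- tibble(
        analysis = paste0("sma_MA_", pc),
        term = c("slope", "intercept", "r", "p_corr", "largest_neg_residual"),
        estimate = c(fit$slope, fit$intercept, fit$r, fit$p_corr, min(res)),
        statistic = NA_real_, df = NA_real_, p = NA_real_)
    }
  }
  grp <- if ("clade_group" %in% names(joined)) joined$clade_group else NULL
  if (!is.null(grp) && length(unique(grp)) == 2) {
    for (v in c("MA", "DFT", "output")) {
      wt <- welch_test(joined, !!rlang::sym(v), clade_group)
      out[[length(out) + 1L]] <- tibble(
        analysis = paste0("welch_", v),
        term = paste(wt$group_a, "vs", wt$group_b),
        estimate = wt$mean_a - wt$mean_b,
        statistic = wt$t, df = wt$df, p = wt$p)
    }
    for (v in c("MA", "DFT", "output")) {
      gs <- group_summary(joined, !!rlang::sym(v), clade_group)
      out[[length(out) + 1L]] <- tibble(
        analysis = paste0("summary_", v),
        term = paste0(gs$group, "_median"),
        estimate = gs$median, statistic = NA_real_, df = NA_real_,
        p = NA_real_)
    }
  }
  bind_rows(out)
}

#' Run the phylogeny pipeline
#'
#' Character matrix -> random-addition Wagner builds with branch swapping
#' -> pooled most-parsimonious trees -> strict and 50% majority-rule
#' consensus, ensemble CI/RI. Writes `best_trees.nwk`,
#' `strict_consensus.nwk`, `majority_consensus.nwk`, `scores.csv`, and
#' `manifest.json`.
#'
#' @param config A `pipeline_config` with at least `matrix`.
#' @return Invisibly, a list with `search`, `strict`, `majority`,
#'   `output_dir`.
#' @export
run_phylogeny <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$matrix)) abort("config needs a matrix input")
  cm <- run_stage("matrix", read_character_matrix(
    config$matrix, format = config$matrix_format,
    ordered = config$ordered, exclude = config$exclude))
  search <- run_stage("search", branch_swap_search(
    cm, replicates = config$reps, strategy = config$swap,
    hold = config$hold, seed = config$seed))
  strict <- run_stage("consensus", strict_consensus(search))
  majority <- run_stage("consensus", majority_rule_consensus(search))
  od <- config$output_dir
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  trees <- search$trees
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file.path(od, "best_trees.nwk"))
  ape::write.tree(strict, file.path(od, "strict_consensus.nwk"))
  ape::write.tree(majority, file.path(od, "majority_consensus.nwk"))
  readr::write_csv(
    tibble(tree = seq_along(search$trees),
           S = search$score$S, CI = search$score$CI, RI = search$score$RI),
    file.path(od, "scores.csv"), progress = FALSE)
  write_manifest(config, od, c("best_trees.nwk", "strict_consensus.nwk",
                               "majority_consensus.nwk", "scores.csv"))
  invisible(list(search = search, strict = strict, majority = majority,
                 output_dir = od))
}
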