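# Pipeline orchestration: generate (or load) -> score -> stats -> report.
# Outputs are written to a staging directory first and moved into place
# only when every stage has succeeded, so a failed run leaves no partial
# artifacts behind.

#' Assemble and validate a pipeline run configuration
#'
#' Exactly one input source must be given: `specs` (simulate), a
#' `measurements_file` (standard CSV), or an `image_dir` of label TIFFs.
#'
#' @param specs named list of [group_spec()]s, or NULL.
#' @param measurements_file path to a measurement CSV, or NULL.
#' @param image_dir directory of label-image TIFFs, or NULL.
#' @param control_group vehicle-control label for drug-activity
#'   normalization.
#' @param activity_exclude groups exempted from drug activity (baseline
#'   arms that received no substance).
#' @param seed master seed for all randomness.
#' @param unit unit of analysis for pairwise tests
#'   (see [pairwise_comparisons()]).
#' @param alpha significance level, in (0, 1).
#' @param output_dir directory for run artifacts.
#' @param um_per_px calibration (image mode only).
#' @param run_mode granular-run mode (image mode only), `"longest"` or
#'   `"sum"`.
#' @param adjust multiple-testing adjustment passed to
#'   [pairwise_comparisons()].
#' @param figures write PNG bar charts (default TRUE).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(specs = NULL, measurements_file = NULL,
                       image_dir = NULL,
                       control_group = "white soft paraffin",
                       activity_exclude = "untreated mice",
                       seed = 1L, unit = "animal", alpha = 0.05,
                       output_dir = "tailmorph-run", um_per_px = NULL,
                       run_mode = "longest", adjust = "none",
                       figures = TRUE) {
  sources <- c(specs = !is.null(specs),
               measurements_file = !is.null(measurements_file),
               image_dir = !is.null(image_dir))
  if (sum(sources) != 1L)
    stop("exactly one input source must be set (specs, measurements_file ",
         "or image_dir); got: ",
         if (any(sources)) paste(names(sources)[sources], collapse = ", ")
         else "none")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(specs = specs, measurements_file = measurements_file,
                 image_dir = image_dir, control_group = control_group,
                 activity_exclude = activity_exclude,
                 seed = as.integer(seed), unit = unit, alpha = alpha,
                 output_dir = output_dir, um_per_px = um_per_px,
                 run_mode = run_mode, adjust = adjust, figures = figures),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the applicable stages in order -- input (generate / read CSV /
#' measure images), group summary, pairwise statistics for both endpoints,
#' figures -- and writes into `config$output_dir`:
#' `measurements.csv`, `summary.csv`, `summary.md`,
#' `pairwise_orthokeratosis.csv` / `.md`, `pairwise_thickness.csv` / `.md`,
#' bar charts (`fig_orthokeratosis.png`, `fig_drug_activity.png`,
#' `fig_thickness.png`) and `manifest.json` (config, seed, package
#' version, per-stage row counts). Re-running with the same config
#' reproduces identical CSV output bytes.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `measurements`, `summary`,
#'   `pairwise` (both endpoints), `ranking`, and `paths` of written files.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(specs = default_study_specs(), seed = 7,
#'                   output_dir = tempfile("run"), figures = FALSE)
#' res <- run_pipeline(cfg)
#' res$summary
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage_counts <- list()

  measurements <- run_stage("input", {
    if (!is.null(config$specs)) {
      generate_study(config$specs, seed = config$seed)
    } else if (!is.null(config$measurements_file)) {
      read_measurements(config$measurements_file)
    } else {
      measure_directory(config$image_dir, um_per_px = config$um_per_px,
                        run_mode = config$run_mode)
    }
  })
  stage_counts$measurements <- nrow(measurements)

  summary <- run_stage("score", summarize_groups(
    measurements, control_group = config$control_group,
    activity_exclude = intersect(config$activity_exclude,
                                 measurements$group)))
  stage_counts$groups <- nrow(summary)

  pw <- run_stage("stats", lapply(
    c(orthokeratosis = "orthokeratosis", thickness = "thickness"),
    function(ep) pairwise_comparisons(
      measurements, endpoint = ep, unit = config$unit,
      alpha = config$alpha, adjust = config$adjust, seed = config$seed)))
  stage_counts$pairwise_tests <- nrow(pw[[1]]$long) + nrow(pw[[2]]$long)

  ranking <- rank_groups(summary, by = "ok_mean")

  # stage outputs, then move into place atomically-ish
  staging <- tempfile("tailmorph-staging-")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  path <- function(f) file.path(staging, f)

  run_stage("report", {
    write_measurements(measurements, path("measurements.csv"))
    write_summary(summary, path("summary.csv"))
    writeLines(format_summary_table(summary), path("summary.md"))
    for (ep in names(pw)) {
      write_pairwise(pw[[ep]], path(sprintf("pairwise_%s.csv", ep)))
      writeLines(format_pairwise_table(pw[[ep]]),
                 path(sprintf("pairwise_%s.md", ep)))
    }
    if (isTRUE(config$figures)) {
      save_fig <- function(p, f)
        ggplot2::ggsave(path(f), p, width = 6, height = 4, dpi = 150)
      save_fig(fig_orthokeratosis(summary), "fig_orthokeratosis.png")
      save_fig(fig_drug_activity(summary), "fig_drug_activity.png")
      save_fig(fig_thickness(summary), "fig_thickness.png")
    }
    manifest <- list(
      package = "tailmorph",
      version = as.character(packageVersion("tailmorph")),
      seed = config$seed,
      config = manifest_config(config),
      ranking_by_orthokeratosis = ranking,
      counts = stage_counts)
    jsonlite::write_json(manifest, path("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging))
    file.copy(file.path(staging, f), file.path(config$output_dir, f),
              overwrite = TRUE)

  invisible(list(measurements = measurements, summary = summary,
                 pairwise = pw, ranking = ranking,
                 paths = file.path(config$output_dir, list.files(staging))))
}

manifest_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$specs)) cfg$specs <- lapply(cfg$specs, unclass)
  cfg$output_dir <- NULL   # location, not part of the scientific config
  cfg
}

#' Order groups by a summary parameter
#'
#' Descending order by the chosen column of a group summary; ties are
#' broken by group label so the ordering is deterministic.
#'
#' @param summary output of [summarize_groups()] (any data frame with a
#'   `group` column and the target column works).
#' @param by `"ok_mean"`, `"thick_mean"` or `"drug_activity"`.
#' @return Character vector of group labels, best first.
#' @export
rank_groups <- function(summary, by = c("ok_mean", "thick_mean",
                                        "drug_activity")) {
  by <- match.arg(by)
  if (!nrow(summary)) stop("empty summary")
  vals <- summary[[by]]
  summary$group[order(-vals, summary$group)]
}

# --- figures: bar charts with SD error bars -------------------------------

fig_bar <- function(summary, value, sd = NULL, ylab) {
  df <- data.frame(group = factor(summary$group, levels = summary$group),
                   y = summary[[value]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = y)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if (!is.null(sd)) {
    df$s <- summary[[sd]]
    p <- p + ggplot2::geom_errorbar(
      data = df, ggplot2::aes(ymin = y - s, ymax = y + s), width = 0.25)
  }
  p
}

#' Bar charts of the group-level parameters
#'
#' Orthokeratosis degree and mean epidermal thickness are drawn with SD
#' error bars; drug activity as plain bars (no uncertainty is defined for
#' it at group level).
#'
#' @param summary output of [summarize_groups()].
#' @return A ggplot object.
#' @export
fig_orthokeratosis <- function(summary)
  fig_bar(summary, "ok_mean", "ok_sd", "Orthokeratosis degree (%)")

#' @rdname fig_orthokeratosis
#' @export
fig_drug_activity <- function(summary)
  fig_bar(summary[!is.na(summary$drug_activity), , drop = FALSE],
          "drug_activity", NULL, "Percentual drug activity (%)")

#' @rdname fig_orthokeratosis
#' @export
fig_thickness <- function(summary)
  fig_bar(summary, "thick_mean", "thick_sd",
          "Mean epidermal thickness (µm)")
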