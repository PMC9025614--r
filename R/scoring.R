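# Derived parameters: orthokeratosis degree, mean epidermal thickness,
# percentual drug activity, and per-group summaries.

#' Per-scale orthokeratosis degree
#'
#' The degree of orthokeratosis of one scale is the percentual ratio of
#' the continuous granular-layer length A to the scale length B:
#' `100 * A / B`.
#'
#' @param A_um granular-layer length, micrometers, `0 <= A <= B`.
#' @param B_um scale length, micrometers, `> 0`.
#' @return Degree in percent, in \[0, 100\]. Vectorized.
#' @export
#' @examples
#' orthokeratosis_degree(175, 500)  # 35
orthokeratosis_degree <- function(A_um, B_um) {
  if (any(B_um <= 0)) stop("B_um must be > 0")
  if (any(A_um < 0 | A_um > B_um)) stop("A_um must satisfy 0 <= A_um <= B_um")
  100 * A_um / B_um
}

#' Mean epidermal thickness of a set of readings
#'
#' Arithmetic mean of valid (non-NA) thickness readings; readings flagged
#' invalid during measurement are excluded. Group-level aggregation pools
#' all readings of the group (default elsewhere) or averages per-animal
#' means, depending on the chosen unit of analysis.
#'
#' @param values thickness readings, micrometers; `NA`s are dropped.
#' @return Mean thickness, micrometers.
#' @export
mean_epidermal_thickness <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no valid thickness readings")
  if (any(values <= 0)) stop("thickness readings must be > 0")
  mean(values)
}

#' Percentual drug activity
#'
#' Normalized orthokeratosis gain of a test substance over the vehicle
#' control: `(Oks - Okc) / (100 - Okc) * 100`, where `Oks` and `Okc` are
#' the group mean orthokeratosis degrees of the test substance and the
#' negative (vehicle) control. Equals 0 when the test group matches the
#' control, 100 at complete orthokeratosis, and is negative -- reported as
#' computed, not clipped -- when the test group falls below the control.
#'
#' @param Oks test-group mean orthokeratosis degree, percent, in \[0, 100\].
#' @param Okc control-group mean degree, percent, in \[0, 100).
#' @return Drug activity in percent. Vectorized over `Oks`.
#' @export
#' @examples
#' drug_activity(56.48, 19.64)  # 45.84...
drug_activity <- function(Oks, Okc) {
  if (length(Okc) != 1L || Okc < 0 || Okc >= 100)
    stop("Okc must be a single value in [0, 100); the formula is undefined at Okc = 100")
  if (any(Oks < 0 | Oks > 100)) stop("Oks must be in [0, 100]")
  (Oks - Okc) / (100 - Okc) * 100
}

# half-away-from-zero rounding, used only for report formatting
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a measurement table per group
#'
#' Per group: mean and sample SD (n - 1 denominator) of the per-scale
#' orthokeratosis degrees, mean and SD of epidermal thickness, and the
#' percentual drug activity of the group mean degree against the control
#' group. The control's own activity is exactly 0; groups listed in
#' `activity_exclude` (e.g. an untreated baseline that is not a treatment)
#' get `NA`. Output rows follow first appearance order in the table and
#' are invariant to record order within groups.
#'
#' @param measurements a measurement data frame
#'   (see [generate_measurements()] / [read_measurements()]).
#' @param control_group label of the vehicle control used for drug-activity
#'   normalization.
#' @param activity_exclude group labels exempted from drug activity.
#' @param unit unit of summary statistics: `"scale"` (default; degree SD
#'   over the 60 scales, thickness SD over the pooled readings) or
#'   `"animal"` (moments over per-animal means).
#' @return Data frame with columns `group, ok_mean, ok_sd, thick_mean,
#'   thick_sd, drug_activity, n_scales, n_thickness`.
#' @export
#' @examples
#' specs <- default_study_specs()
#' tab <- generate_study(specs, seed = 1)
#' summarize_groups(tab, control_group = "white soft paraffin",
#'                  activity_exclude = "untreated mice")
summarize_groups <- function(measurements, control_group,
                             activity_exclude = character(),
                             unit = c("scale", "animal")) {
  unit <- match.arg(unit)
  validate_measurements(measurements)
  groups <- unique(measurements$group)
  if (!control_group %in% groups)
    stop("control group '", control_group, "' not present in the table")
  tc <- thickness_cols(measurements)

  one <- function(g) {
    sub <- measurements[measurements$group == g, , drop = FALSE]
    deg <- orthokeratosis_degree(sub$A_um, sub$B_um)
    th <- as.matrix(sub[tc])
    if (unit == "animal") {
      deg_u <- tapply(deg, sub$animal, mean)
      th_u <- tapply(as.vector(th), rep(sub$animal, times = ncol(th)), mean)
    } else {
      deg_u <- deg
      th_u <- as.vector(th)
    }
    data.frame(group = g,
               ok_mean = mean(deg_u), ok_sd = sd(deg_u),
               thick_mean = mean(th_u), thick_sd = sd(th_u),
               n_scales = nrow(sub), n_thickness = length(th),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(lapply(groups, one), make.row.names = FALSE))

  Okc <- out$ok_mean[out$group == control_group]
  out$drug_activity <- drug_activity(pmin(pmax(out$ok_mean, 0), 100), Okc)
  out$drug_activity[out$group == control_group] <- 0
  out$drug_activity[out$group %in% activity_exclude] <- NA_real_
  out[c("group", "ok_mean", "ok_sd", "thick_mean", "thick_sd",
        "drug_activity", "n_scales", "n_thickness")]
}

#' Bootstrap confidence intervals for percentual drug activity
#'
#' Drug activity is published as a point value without uncertainty. This
#' resamples animals (the exchangeable design unit) with replacement
#' within every group -- including the control -- recomputes group mean
#' degrees and drug activity per resample, and returns percentile
#' intervals.
#'
#' @inheritParams summarize_groups
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed seed for the resampling substream.
#' @return Data frame with `group, drug_activity, lower, upper`; the
#'   control and excluded groups are omitted.
#' @export
drug_activity_bootstrap <- function(measurements, control_group,
                                    activity_exclude = character(),
                                    n_boot = 2000L, conf = 0.95,
                                    seed = 1L) {
  validate_measurements(measurements)
  groups <- unique(measurements$group)
  if (!control_group %in% groups)
    stop("control group '", control_group, "' not present in the table")
  test_groups <- setdiff(groups, c(control_group, activity_exclude))

  animal_means <- function(g) {
    sub <- measurements[measurements$group == g, , drop = FALSE]
    deg <- orthokeratosis_degree(sub$A_um, sub$B_um)
    as.numeric(tapply(deg, sub$animal, mean))
  }
  am <- lapply(setNames(groups, groups), animal_means)

  old <- set_local_seed(substream_seed(seed, "activity-boot"))
  on.exit(restore_seed(old))
  draws <- vapply(seq_len(n_boot), function(b) {
    Okc <- mean(sample(am[[control_group]], replace = TRUE))
    Okc <- min(Okc, 100 - 1e-9)
    vapply(test_groups, function(g)
      drug_activity(clamp(mean(sample(am[[g]], replace = TRUE)), 0, 100),
                    Okc), numeric(1))
  }, numeric(length(test_groups)))
  draws <- matrix(draws, nrow = length(test_groups))

  point <- vapply(test_groups, function(g)
    drug_activity(clamp(mean(unlist(am[[g]])), 0, 100),
                  mean(am[[control_group]])), numeric(1))
  a <- (1 - conf) / 2
  data.frame(group = test_groups,
             drug_activity = point,
             lower = apply(draws, 1, stats::quantile, probs = a),
             upper = apply(draws, 1, stats::quantile, probs = 1 - a),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Render a group summary as a "mean +/- SD" Markdown table
#'
#' Mirrors the published presentation: one row per group, orthokeratosis
#' degree and mean epidermal thickness as `mean ± SD`, drug activity as a
#' single percentage, all rounded half-away-from-zero to 2 decimals.
#'
#' @param summary output of [summarize_groups()].
#' @return Character vector of Markdown lines.
#' @export
format_summary_table <- function(summary) {
  pm <- function(m, s) sprintf("%.2f ± %.2f", round_half_up(m),
                               round_half_up(s))
  act <- ifelse(is.na(summary$drug_activity), "",
                sprintf("%.2f", round_half_up(summary$drug_activity)))
  c("| Group | Orthokeratosis degree (%) | Mean epidermal thickness (µm) | Percentual drug activity (%) |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %s |", summary$group,
            pm(summary$ok_mean, summary$ok_sd),
            pm(summary$thick_mean, summary$thick_sd), act))
}

#' Write a group summary CSV
#'
#' @param summary output of [summarize_groups()].
#' @param path file path.
#' @export
write_summary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
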