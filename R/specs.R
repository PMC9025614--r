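#' Define the distributional parameters of one treatment group
#'
#' A group spec carries the design counts and the group-level moments from
#' which synthetic per-scale measurements are simulated: the mean and SD of
#' the per-scale orthokeratosis degree (percent) and of the per-reading
#' epidermal thickness (micrometers), plus the fraction of variance
#' attributed to animal-level effects (`animal_icc`).
#'
#' @param name group label.
#' @param ok_mean mean orthokeratosis degree, percent, in \[0, 100\].
#' @param ok_sd SD of orthokeratosis degree, percent, >= 0.
#' @param thick_mean mean epidermal thickness, micrometers, > 0.
#' @param thick_sd SD of epidermal thickness, micrometers, >= 0.
#' @param n_animals animals per group (default 6).
#' @param scales_per_animal measured scales per animal (default 10).
#' @param measurements_per_scale thickness readings per scale (default 5).
#' @param animal_icc intraclass correlation: fraction of total variance at
#'   the animal level, in \[0, 1).
#'
#' @return An object of class `group_spec`.
#' @seealso [default_study_specs()], [generate_measurements()]
#' @export
#' @examples
#' group_spec("vehicle", ok_mean = 19.64, ok_sd = 3.2,
#'            thick_mean = 29.76, thick_sd = 2.02)
group_spec <- function(name, ok_mean, ok_sd, thick_mean, thick_sd,
                       n_animals = 6L, scales_per_animal = 10L,
                       measurements_per_scale = 5L, animal_icc = 0.3) {
  spec <- list(
    name = as.character(name),
    ok_mean = as.numeric(ok_mean), ok_sd = as.numeric(ok_sd),
    thick_mean = as.numeric(thick_mean), thick_sd = as.numeric(thick_sd),
    n_animals = as.integer(n_animals),
    scales_per_animal = as.integer(scales_per_animal),
    measurements_per_scale = as.integer(measurements_per_scale),
    animal_icc = as.numeric(animal_icc)
  )
  class(spec) <- "group_spec"
  validate_group_spec(spec)
  spec
}

validate_group_spec <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  with(spec, {
    if (!nzchar(name)) stop("group name must be non-empty")
    if (is.na(ok_mean) || ok_mean < 0 || ok_mean > 100)
      stop("ok_mean must be in [0, 100]")
    if (is.na(ok_sd) || ok_sd < 0) stop("ok_sd must be >= 0")
    if (is.na(thick_mean) || thick_mean <= 0) stop("thick_mean must be > 0")
    if (is.na(thick_sd) || thick_sd < 0) stop("thick_sd must be >= 0")
    if (n_animals < 1L || scales_per_animal < 1L || measurements_per_scale < 1L)
      stop("design counts (n_animals, scales_per_animal, ",
           "measurements_per_scale) must be positive")
    if (is.na(animal_icc) || animal_icc < 0 || animal_icc >= 1)
      stop("animal_icc must be in [0, 1)")
  })
  invisible(spec)
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf(
    "<group_spec> %s\n  orthokeratosis degree: %g +/- %g %%\n  epidermal thickness:   %g +/- %g um\n  design: %d animals x %d scales x %d readings (animal ICC %g)\n",
    x$name, x$ok_mean, x$ok_sd, x$thick_mean, x$thick_sd,
    x$n_animals, x$scales_per_animal, x$measurements_per_scale, x$animal_icc))
  invisible(x)
}

#' Default seven-arm study parameterization
#'
#' Returns the specs of the seven study arms -- two negative controls
#' (untreated mice, white soft paraffin vehicle), a tretinoin 0.05%
#' positive control and four NSAID arms (diclofenac 1%/2%, celecoxib
#' 1%/2%) -- parameterized at the published group means and SDs of
#' orthokeratosis degree and mean epidermal thickness, with the default
#' design counts (6 animals x 10 scales = 60 scales per group; 5 thickness
#' readings per scale = 300 per group).
#'
#' @param n_animals,scales_per_animal,measurements_per_scale,animal_icc
#'   design overrides applied to every arm.
#' @return A named list of [group_spec()] objects, in study order.
#' @export
#' @examples
#' specs <- default_study_specs()
#' specs[["celecoxib 2%"]]
default_study_specs <- function(n_animals = 6L, scales_per_animal = 10L,
                                measurements_per_scale = 5L,
                                animal_icc = 0.3) {
  tab <- list(
    # name,                ok_mean, ok_sd, thick_mean, thick_sd
    list("untreated mice",      17.70,  1.81, 24.77, 2.43),
    list("white soft paraffin", 19.64,  3.20, 29.76, 2.02),
    list("tretinoin 0.05%",     48.72,  6.09, 33.22, 2.61),
    list("diclofenac 1%",       42.24, 13.73, 28.42, 2.62),
    list("diclofenac 2%",       41.42,  8.17, 27.38, 2.75),
    list("celecoxib 1%",        42.15,  7.28, 28.07, 2.37),
    list("celecoxib 2%",        56.48, 11.33, 32.28, 6.18)
  )
  specs <- lapply(tab, function(row) {
    group_spec(row[[1]], ok_mean = row[[2]], ok_sd = row[[3]],
               thick_mean = row[[4]], thick_sd = row[[5]],
               n_animals = n_animals, scales_per_animal = scales_per_animal,
               measurements_per_scale = measurements_per_scale,
               animal_icc = animal_icc)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Read or write a study configuration as JSON
#'
#' A study config is a JSON array of group-spec records; the packaged
#' default ([default_study_specs()]) reproduces the published seven-arm
#' parameterization.
#'
#' @param specs named list of [group_spec()] objects.
#' @param path file path.
#' @return `read_study_specs()` returns a named list of `group_spec`s.
#' @export
write_study_specs <- function(specs, path) {
  recs <- lapply(specs, function(s) unclass(s))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_study_specs
#' @export
read_study_specs <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(recs, function(r) do.call(group_spec, r))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
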