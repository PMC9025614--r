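# Synthetic per-scale measurement generator.
#
# Per-scale orthokeratosis degree and per-reading thickness are simulated
# from a two-level normal model: total variance sigma^2 is split into an
# animal-level component (icc * sigma^2, one draw per animal) and a
# scale/reading-level residual ((1 - icc) * sigma^2), then values are
# truncated to the type's domain (degree clamped to [0, 100], lengths and
# thicknesses clamped strictly positive).

# Deterministic 32-bit FNV-1a hash of a key string, folded to a valid
# set.seed() integer. Multiplication is done in two 16-bit halves so every
# intermediate stays exactly representable in a double.
substream_seed <- function(master, ...) {
  key <- paste(master, ..., sep = "\x1f")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- xor_32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * 16777619) + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

xor_32 <- function(a, b) {
  # bitwXor on doubles up to 2^32 - 1 via 16-bit halves (bitwXor needs ints)
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(as.integer(a_lo), as.integer(b_lo)) +
    bitwXor(as.integer(a_hi), as.integer(b_hi)) * 65536
}

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# smallest admissible positive thickness/length, micrometers
.pos_floor <- 1e-6

#' Generate synthetic per-scale measurements for one group
#'
#' Simulates the full measurement table of one treatment arm: for each of
#' `n_animals x scales_per_animal` scales, a scale length `B_um`, a
#' continuous granular-layer length `A_um` and `measurements_per_scale`
#' epidermal thickness readings. The per-scale orthokeratosis degree is
#' drawn from a normal distribution with moments `(ok_mean, ok_sd)` whose
#' variance is decomposed into animal- and scale-level components by
#' `animal_icc`, then clamped to \[0, 100\]; `A_um = degree / 100 * B_um`.
#' Thickness readings are drawn analogously from
#' `(thick_mean, thick_sd)` and clamped positive.
#'
#' Randomness is fully reproducible: each animal and each scale uses its
#' own RNG substream derived by stable hashing of
#' `(seed, group, animal, scale)`, so identical `(spec, seed)` yields
#' byte-identical tables and regenerating a subset of animals reproduces
#' the original values.
#'
#' @param spec a [group_spec()].
#' @param seed integer master seed.
#' @param b_mean,b_sd,b_min scale-length distribution: normal mean and SD
#'   in micrometers, truncated below at `b_min` (defaults 500, 50, 100).
#' @return A data frame with one row per scale and columns
#'   `group, animal, scale, A_um, B_um, t1_um ... t<m>_um`.
#' @export
#' @examples
#' spec <- default_study_specs()[["celecoxib 2%"]]
#' head(generate_measurements(spec, seed = 42))
generate_measurements <- function(spec, seed, b_mean = 500, b_sd = 50,
                                  b_min = 100) {
  validate_group_spec(spec)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (b_mean <= 0 || b_sd < 0 || b_min <= 0)
    stop("scale-length distribution parameters must be positive")

  m <- spec$measurements_per_scale
  sd_ok_a <- spec$ok_sd * sqrt(spec$animal_icc)
  sd_ok_s <- spec$ok_sd * sqrt(1 - spec$animal_icc)
  sd_th_a <- spec$thick_sd * sqrt(spec$animal_icc)
  sd_th_s <- spec$thick_sd * sqrt(1 - spec$animal_icc)

  rows <- vector("list", spec$n_animals * spec$scales_per_animal)
  k <- 0L
  for (animal in seq_len(spec$n_animals)) {
    seed_a <- substream_seed(seed, spec$name, "animal", animal)
    old <- set_local_seed(seed_a)
    ok_animal <- rnorm(1, 0, sd_ok_a)
    th_animal <- rnorm(1, 0, sd_th_a)
    restore_seed(old)
    for (scale in seq_len(spec$scales_per_animal)) {
      old <- set_local_seed(substream_seed(seed, spec$name, "scale",
                                           animal, scale))
      degree <- clamp(spec$ok_mean + ok_animal + rnorm(1, 0, sd_ok_s), 0, 100)
      B <- clamp(rnorm(1, b_mean, b_sd), b_min, Inf)
      thick <- clamp(spec$thick_mean + th_animal + rnorm(m, 0, sd_th_s),
                     .pos_floor, Inf)
      restore_seed(old)
      k <- k + 1L
      rows[[k]] <- c(A_um = degree / 100 * B, B_um = B,
                     setNames(thick, paste0("t", seq_len(m), "_um")))
    }
  }
  num <- as.data.frame(do.call(rbind, rows))
  out <- data.frame(
    group = spec$name,
    animal = rep(seq_len(spec$n_animals), each = spec$scales_per_animal),
    scale = rep(seq_len(spec$scales_per_animal), times = spec$n_animals),
    num, stringsAsFactors = FALSE)
  validate_measurements(out)
  out
}

# Save/restore the global RNG state around substream use so generation does
# not perturb (and is not perturbed by) the caller's RNG.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Generate the full study measurement table
#'
#' Applies [generate_measurements()] to each group spec and row-binds the
#' results (all specs must share `measurements_per_scale`).
#'
#' @param specs named list of [group_spec()]s.
#' @param seed integer master seed, shared across groups (each group's
#'   draws live in their own substreams keyed by group name).
#' @inheritParams generate_measurements
#' @return A measurement data frame covering all groups.
#' @export
generate_study <- function(specs, seed, b_mean = 500, b_sd = 50,
                           b_min = 100) {
  m <- unique(vapply(specs, `[[`, integer(1), "measurements_per_scale"))
  if (length(m) != 1L)
    stop("all group specs must share measurements_per_scale")
  do.call(rbind, c(lapply(specs, generate_measurements, seed = seed,
                          b_mean = b_mean, b_sd = b_sd, b_min = b_min),
                   make.row.names = FALSE))
}

thickness_cols <- function(measurements) {
  grep("^t[0-9]+_um$", names(measurements), value = TRUE)
}

#' Validate a measurement table
#'
#' Checks the contract every downstream stage relies on: required columns,
#' `0 <= A_um <= B_um`, `B_um > 0`, strictly positive thickness readings.
#'
#' @param measurements a measurement data frame.
#' @return The table, invisibly; stops with an informative error otherwise.
#' @export
validate_measurements <- function(measurements) {
  need <- c("group", "animal", "scale", "A_um", "B_um")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  tc <- thickness_cols(measurements)
  if (!length(tc)) stop("measurement table has no t<k>_um thickness columns")
  with(measurements, {
    if (any(B_um <= 0)) stop("B_um must be > 0 for every scale")
    if (any(A_um < 0 | A_um > B_um)) stop("A_um must satisfy 0 <= A_um <= B_um")
  })
  th <- as.matrix(measurements[tc])
  if (any(!is.finite(th)) || any(th <= 0))
    stop("all thickness readings must be finite and > 0")
  invisible(measurements)
}

#' Read or write the standard measurement CSV
#'
#' Column layout: `group,animal,scale,A_um,B_um,t1_um,...` (thickness
#' columns expand with the number of readings per scale).
#'
#' @param measurements a measurement data frame.
#' @param path file path.
#' @return `read_measurements()` returns a validated data frame.
#' @export
write_measurements <- function(measurements, path) {
  validate_measurements(measurements)
  df <- measurements
  dbl <- vapply(df, is.double, logical(1))
  # %.17g round-trips doubles exactly, so re-reading the CSV reproduces
  # the table bit for bit
  df[dbl] <- lapply(df[dbl], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE,
            quote = which(names(df) == "group"))
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  validate_measurements(out)
  out
}
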