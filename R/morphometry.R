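# Measurement extraction from label images: a defined, testable algorithm
# standing in for interactive on-screen measurement of stained sections.
#
# Conventions: matrix columns are 1-based; a scale window is the closed
# column interval between the centers of two adjacent follicles.

#' Length of the longest contiguous run of TRUE values
#'
#' The horizontal extent of the *continuous* granular layer is the single
#' longest contiguous block of granular-bearing columns; this is the
#' run-length primitive behind that measurement.
#'
#' @param flags logical vector (empty allowed).
#' @return Integer run length; 0 for empty or all-FALSE input.
#' @export
#' @examples
#' longest_run(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))  # 3
longest_run <- function(flags) {
  flags <- as.logical(flags)
  if (anyNA(flags)) stop("flags must not contain NA")
  if (!length(flags)) return(0L)
  r <- rle(flags)
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

#' Detect hair-follicle column intervals in a label image
#'
#' A follicle interval is a maximal contiguous block of columns containing
#' at least one follicle-class pixel. Intervals are returned left to right
#' with their center column (midpoint; for even widths the midpoint is
#' rounded down).
#'
#' @param image a `label_image` (or bare integer matrix).
#' @param follicle_class integer class code (default from
#'   [label_classes()]).
#' @return Data frame with columns `left`, `right` (closed interval,
#'   1-based) and `center`; at least two follicles are required, otherwise
#'   an error ("no scale") is raised.
#' @export
detect_follicles <- function(image, follicle_class = label_classes()[["follicle"]]) {
  grid <- if (inherits(image, "label_image")) image$grid else image
  has_f <- apply(grid == follicle_class, 2, any)
  r <- rle(as.vector(has_f))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(left = starts[keep], right = ends[keep])
  if (nrow(out) < 2L)
    stop("no scale: fewer than two follicles detected (found ",
         nrow(out), ")")
  out$center <- (out$left + out$right) %/% 2L
  out
}

#' Build the scale windows between consecutive follicles
#'
#' @param follicles output of [detect_follicles()].
#' @return Data frame with one row per scale: `left`, `right` (the two
#'   follicle center columns bounding the window, closed interval).
#' @export
scale_windows <- function(follicles) {
  k <- nrow(follicles) - 1L
  data.frame(left = follicles$center[seq_len(k)],
             right = follicles$center[seq_len(k) + 1L])
}

#' Measure one scale: A, B and the epidermal thickness profile
#'
#' Implements the three primary measurements on a label image:
#' \itemize{
#'   \item `B_um`: horizontal scale length, the distance between the two
#'     bounding follicle centers.
#'   \item `A_um`: horizontal length of the continuous granular layer --
#'     the longest contiguous run of window columns containing at least
#'     `min_granular_px` granular-class pixels (`run_mode = "longest"`,
#'     default), or the total granular-bearing column count
#'     (`run_mode = "sum"`, for sensitivity analysis of fragmented
#'     layers). A is capped at B.
#'   \item thickness: at `measurements_per_scale` equally spaced columns
#'     strictly inside the window (fractions 1/(m+1), ..., m/(m+1)), the
#'     viable-epidermis pixel count times `um_per_px` -- i.e. from the
#'     dermo-epidermal junction up to, and excluding, the stratum corneum.
#' }
#' A sampled column with zero epidermis pixels yields `NA` with a warning
#' (an invalid reading, excluded from downstream means), never a silent 0.
#'
#' @param image a `label_image`.
#' @param window one-row data frame (or list) with `left` and `right`
#'   follicle-center columns.
#' @param measurements_per_scale number of thickness sampling columns.
#' @param run_mode `"longest"` (default) or `"sum"`.
#' @param min_granular_px minimum granular pixels for a column to count as
#'   granular-bearing (default 1).
#' @return List with `A_um`, `B_um`, `thickness_um` (length
#'   `measurements_per_scale`, possibly containing `NA`).
#' @export
measure_scale <- function(image, window, measurements_per_scale = 5L,
                          run_mode = c("longest", "sum"),
                          min_granular_px = 1L) {
  run_mode <- match.arg(run_mode)
  stopifnot(inherits(image, "label_image"))
  grid <- image$grid
  cls <- image$class_codes
  left <- as.integer(window$left); right <- as.integer(window$right)
  if (!(left >= 1L && right <= ncol(grid) && left < right))
    stop("invalid scale window [", left, ", ", right, "]")
  um <- image$um_per_px

  B_um <- (right - left) * um

  cols <- left:right
  gcount <- colSums(grid[, cols, drop = FALSE] == cls[["granular"]])
  gflags <- gcount >= min_granular_px
  run_px <- if (run_mode == "longest") longest_run(gflags) else sum(gflags)
  A_um <- min(run_px * um, B_um)

  m <- as.integer(measurements_per_scale)
  w <- right - left
  xs <- left + floor(seq_len(m) * w / (m + 1L))
  tpx <- colSums(grid[, xs, drop = FALSE] == cls[["epidermis"]])
  if (any(tpx == 0L)) {
    warning("excluded ", sum(tpx == 0L),
            " thickness column(s) with no epidermis pixels at column(s) ",
            paste(xs[tpx == 0L], collapse = ", "))
    tpx[tpx == 0L] <- NA_integer_
  }

  list(A_um = A_um, B_um = B_um, thickness_um = tpx * um)
}

#' Measure every scale in a label image
#'
#' Detects follicles, forms the scale windows between consecutive follicle
#' centers and measures each with [measure_scale()].
#'
#' @inheritParams measure_scale
#' @param group,animal labels attached to the output rows.
#' @return A measurement data frame (`group, animal, scale, A_um, B_um,
#'   t1_um, ...`).
#' @export
measure_image <- function(image, measurements_per_scale = 5L,
                          run_mode = c("longest", "sum"),
                          min_granular_px = 1L,
                          group = "unknown", animal = 1L) {
  run_mode <- match.arg(run_mode)
  windows <- scale_windows(detect_follicles(image))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    ms <- measure_scale(image, windows[i, ], measurements_per_scale,
                        run_mode, min_granular_px)
    c(A_um = ms$A_um, B_um = ms$B_um,
      setNames(ms$thickness_um,
               paste0("t", seq_along(ms$thickness_um), "_um")))
  })
  data.frame(group = group, animal = animal, scale = seq_along(rows),
             as.data.frame(do.call(rbind, rows)), stringsAsFactors = FALSE)
}

#' Batch-measure a directory of label-image TIFFs
#'
#' Reads every TIFF in `dir` (with its `.truth.json` sidecar when present,
#' for calibration and group/animal labels) and emits the standard
#' measurement table. Group and animal default to the file stem when the
#' sidecar carries no labels.
#'
#' @param dir directory of TIFF label images.
#' @param um_per_px calibration for images lacking a sidecar.
#' @inheritParams measure_scale
#' @return A measurement data frame, one row per measured scale.
#' @export
measure_directory <- function(dir, um_per_px = NULL,
                              measurements_per_scale = 5L,
                              run_mode = c("longest", "sum"),
                              min_granular_px = 1L) {
  run_mode <- match.arg(run_mode)
  paths <- list.files(dir, pattern = "\\.tiff?$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(paths)) stop("no images found in ", dir)
  tabs <- lapply(sort(paths), function(p) {
    img <- read_label_image(p, um_per_px = um_per_px)
    stem <- sub("\\.tiff?$", "", basename(p), ignore.case = TRUE)
    grp <- if (!is.null(img$truth$group)) img$truth$group else stem
    ani <- if (!is.null(img$truth$animal)) img$truth$animal else 1L
    measure_image(img, measurements_per_scale, run_mode, min_granular_px,
                  group = grp, animal = ani)
  })
  out <- do.call(rbind, c(tabs, make.row.names = FALSE))
  out$scale <- stats::ave(out$scale, out$group, out$animal,
                          FUN = seq_along)
  out
}
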