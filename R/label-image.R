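# Schematic labeled pseudo-histology images.
#
# A label image is an integer matrix (rows = depth into the skin, columns =
# horizontal position along the tail) with semantic classes. It emulates a
# sectioned tail scale: two hair-follicle columns bounding one scale, a
# viable-epidermis band anchored at the dermo-epidermal junction, a
# stratum-corneum band on top, and -- where the scale is orthokeratotic --
# a granular-layer band whose continuous horizontal extent encodes the
# ground-truth A. No staining texture or noise is rendered; class 0 covers
# both background and dermis.

#' Semantic class codes used in label images
#'
#' @return Named integer vector: `background` (= dermis) 0, `epidermis`
#'   (viable) 1, `granular` 2, `corneum` 3, `follicle` 4.
#' @export
label_classes <- function() {
  c(background = 0L, epidermis = 1L, granular = 2L, corneum = 3L,
    follicle = 4L)
}

#' Generate one labeled pseudo-histology scale image
#'
#' Rasterizes a single scale with known ground truth: two follicle columns
#' whose centers are `B_um` apart, a viable-epidermis band with a piecewise
#' thickness profile (one segment per thickness reading), a
#' stratum-corneum band above the epidermis, and a single contiguous
#' granular-layer run of horizontal length `degree / 100 * B_um`, placed at
#' a seed-determined random offset within the inter-follicular window.
#' The exact generated geometry is returned as a ground-truth record
#' (and written to a `.truth.json` sidecar by [write_label_image()]).
#'
#' @param B_um horizontal scale length (follicle center to center), um.
#' @param degree orthokeratosis degree to encode, percent in \[0, 100\].
#' @param thickness_um vector of epidermal thickness values, um; the window
#'   is split into `length(thickness_um)` equal horizontal segments, each
#'   rasterized at its value.
#' @param um_per_px isotropic calibration, micrometers per pixel.
#' @param seed integer seed controlling the granular-run offset.
#' @param width_px,height_px optional fixed canvas size; the default sizes
#'   the canvas to fit the requested geometry. If given and the geometry
#'   does not fit, an error is raised.
#' @param follicle_width_px,corneum_px,granular_px,margin_px band and
#'   margin sizes in pixels (schematic, not measured quantities).
#' @return A list of class `label_image`: `grid` (integer matrix),
#'   `um_per_px`, `class_codes`, and `truth` (A_um, B_um, degree,
#'   thickness_um, granular offset).
#' @export
#' @examples
#' img <- generate_label_image(400, degree = 50,
#'                             thickness_um = rep(30, 5), um_per_px = 2)
#' img$truth$A_um  # 200
generate_label_image <- function(B_um, degree, thickness_um, um_per_px = 1,
                                 seed = 1, width_px = NULL, height_px = NULL,
                                 follicle_width_px = 5L, corneum_px = 3L,
                                 granular_px = 2L, margin_px = 10L) {
  stopifnot(um_per_px > 0, B_um > 0, length(thickness_um) >= 1L,
            all(thickness_um > 0))
  if (degree < 0 || degree > 100) stop("degree must be in [0, 100]")
  cls <- label_classes()

  B_px <- round(B_um / um_per_px)
  t_px <- round(thickness_um / um_per_px)
  if (any(t_px < 1L))
    stop("thickness below half a pixel at this calibration; geometry ",
         "does not fit")
  A_px <- round(degree / 100 * B_px)
  fw <- as.integer(follicle_width_px)
  half_l <- (fw - 1L) %/% 2L   # columns left of the follicle center
  half_r <- fw %/% 2L

  cL <- margin_px + half_l + 1L        # left follicle center (1-based col)
  cR <- cL + B_px                      # right follicle center
  need_w <- cR + half_r + margin_px
  need_h <- margin_px + corneum_px + granular_px + max(t_px) + margin_px
  W <- if (is.null(width_px)) need_w else as.integer(width_px)
  H <- if (is.null(height_px)) need_h else as.integer(height_px)
  if (W < need_w || H < need_h)
    stop(sprintf("requested geometry does not fit: needs %d x %d px, canvas %d x %d",
                 need_h, need_w, H, W))
  if (B_px <= fw)
    stop("scale length too small relative to follicle width; geometry does not fit")

  grid <- matrix(cls[["background"]], nrow = H, ncol = W)
  J <- H - margin_px                   # dermo-epidermal junction row

  # epidermis + corneum bands across the window, piecewise thickness
  n_seg <- length(t_px)
  wnd <- cL:cR
  seg_of <- pmin(floor((seq_along(wnd) - 1L) * n_seg / length(wnd)) + 1L,
                 n_seg)
  for (i in seq_along(wnd)) {
    x <- wnd[i]
    t <- t_px[seg_of[i]]
    grid[(J - t + 1L):J, x] <- cls[["epidermis"]]
    grid[(J - t - corneum_px + 1L):(J - t), x] <- cls[["corneum"]]
  }

  # follicles: full-height bars centered at cL and cR
  for (cc in c(cL, cR))
    grid[, (cc - half_l):(cc + half_r)] <- cls[["follicle"]]

  # granular-layer band: one contiguous run of A_px columns, random offset,
  # drawn last so full-degree runs are visible across follicle columns too
  offset <- 0L
  if (A_px > 0L) {
    old <- set_local_seed(substream_seed(seed, "label", B_um, degree))
    offset <- if (A_px < B_px) sample.int(B_px - A_px + 1L, 1L) - 1L else 0L
    restore_seed(old)
    run_cols <- (cL + offset):(cL + offset + A_px - 1L)
    for (x in run_cols) {
      t <- t_px[seg_of[match(x, wnd)]]
      grid[(J - t - granular_px + 1L):(J - t), x] <- cls[["granular"]]
    }
  }

  structure(list(
    grid = grid, um_per_px = um_per_px, class_codes = cls,
    truth = list(A_um = degree / 100 * B_um, B_um = B_um, degree = degree,
                 thickness_um = as.numeric(thickness_um),
                 um_per_px = um_per_px, granular_offset_px = offset)
  ), class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d px at %g um/px; truth degree %g%%, B %g um\n",
              nrow(x$grid), ncol(x$grid), x$um_per_px,
              x$truth$degree, x$truth$B_um))
  invisible(x)
}

#' Write or read a label image as TIFF plus JSON ground-truth sidecar
#'
#' The grid is stored as an 8-bit single-channel TIFF of class codes; the
#' calibration and exact generated geometry go to `<path>.truth.json`.
#'
#' @param image a `label_image`.
#' @param path TIFF file path.
#' @param um_per_px calibration override when reading an image without a
#'   sidecar.
#' @return `read_label_image()` returns a `label_image` (with `truth` NULL
#'   if no sidecar is present).
#' @export
write_label_image <- function(image, path) {
  stopifnot(inherits(image, "label_image"))
  tiff::writeTIFF(image$grid / 255, path, bits.per.sample = 8L)
  sidecar <- c(image$truth, list(class_codes = as.list(image$class_codes)))
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path, um_per_px = NULL) {
  grid <- round(tiff::readTIFF(path) * 255)
  storage.mode(grid) <- "integer"
  truth <- NULL
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    truth$class_codes <- NULL
    if (is.null(um_per_px)) um_per_px <- truth$um_per_px
  }
  if (is.null(um_per_px))
    stop("um_per_px not given and no ground-truth sidecar found for ", path)
  structure(list(grid = grid, um_per_px = um_per_px,
                 class_codes = label_classes(), truth = truth),
            class = "label_image")
}
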