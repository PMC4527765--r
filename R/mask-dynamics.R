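#' Region label codes
#'
#' Integer codes used in region label matrices: 0 background, 1 stable,
#' 2 protrusion, 3 retraction, 4 short-lived.
#'
#' @format Named integer vector of length 5.
#' @export
REGION_CODES <- c(
  background = 0L, stable = 1L, protrusion = 2L,
  retraction = 3L, short_lived = 4L
)

#' Construct a mask sequence
#'
#' Bundles an ordered series of binary segmentation masks of a single cell
#' with its spatial and temporal calibration. Frames where the cell could
#' not be segmented (loss of focus, cell partially outside the field) are
#' carried as gap frames: they keep their temporal slot but contain no
#' foreground and are flagged, so that downstream region classification can
#' exclude the time points adjacent to them.
#'
#' @param frames List of logical (or 0/1) matrices, all of equal dimension.
#' @param pixel_size_um Pixel side length in micrometres (default 0.21).
#' @param frame_interval_min Time between frames in minutes (default 5).
#' @param gap_flags Logical vector, one per frame; `TRUE` marks an
#'   unsegmentable gap frame. Defaults to flagging empty frames.
#' @param cell_id,experiment_id Identifiers carried through to output tables.
#' @return An object of class `mask_sequence`.
#' @export
mask_sequence <- function(frames, pixel_size_um = 0.21, frame_interval_min = 5,
                          gap_flags = NULL, cell_id = "cell1",
                          experiment_id = "exp1") {
  stopifnot(is.list(frames), length(frames) >= 1)
  frames <- lapply(frames, function(f) {
    if (is.logical(f)) f else matrix(as.logical(f), nrow(f), ncol(f))
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions")
  }
  if (is.null(gap_flags)) {
    gap_flags <- !vapply(frames, any, logical(1))
  }
  stopifnot(length(gap_flags) == length(frames))
  if (any(!gap_flags & !vapply(frames, any, logical(1)))) {
    stop("a non-gap frame must contain at least one foreground pixel")
  }
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min,
         gap_flags = as.logical(gap_flags),
         cell_id = cell_id, experiment_id = experiment_id),
    class = "mask_sequence"
  )
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<mask_sequence> %d frames (%d gaps), %dx%d px, %.2f um/px, %.0f min/frame\n",
    length(x$frames), sum(x$gap_flags), d[1], d[2],
    x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

#' @export
length.mask_sequence <- function(x) length(x$frames)

#' Classify cell pixels into stable, protrusion, retraction and short-lived
#'
#' Partitions the foreground of the focal frame by comparing each pixel's
#' membership in the previous and next frames, at actual positions (no
#' alignment of cell centres): present in both neighbours = stable; absent
#' before, present after = protrusion; present before, absent after =
#' retraction; absent in both = short-lived. The four categories are a
#' strict partition of the focal frame's cell area, so protrusion,
#' retraction and short-lived areas sum (with the stable area) exactly to
#' the cell area; their sum alone is the Dynamic Cell Area.
#'
#' @param mask_prev,mask_curr,mask_next Binary masks of equal dimension;
#'   `mask_curr` must be non-empty.
#' @param pixel_size_um Pixel side length in micrometres.
#' @return A list of class `region_map` with the label matrix (codes as in
#'   [REGION_CODES]), per-category pixel counts and areas (um^2), the cell
#'   area, `dynamic_cell_area` and `delta_cell_area`
#'   (protrusion minus retraction).
#' @export
classify_regions <- function(mask_prev, mask_curr, mask_next,
                             pixel_size_um = 0.21) {
  mask_prev <- as_mask(mask_prev); mask_curr <- as_mask(mask_curr)
  mask_next <- as_mask(mask_next)
  if (!identical(dim(mask_prev), dim(mask_curr)) ||
      !identical(dim(mask_next), dim(mask_curr))) {
    stop("mask dimensions differ")
  }
  if (!any(mask_curr)) stop("focal mask is empty")

  labels <- matrix(REGION_CODES[["background"]], nrow(mask_curr), ncol(mask_curr))
  in_prev <- mask_prev[mask_curr]
  in_next <- mask_next[mask_curr]
  code <- ifelse(in_prev & in_next, REGION_CODES[["stable"]],
          ifelse(!in_prev & in_next, REGION_CODES[["protrusion"]],
          ifelse(in_prev & !in_next, REGION_CODES[["retraction"]],
                 REGION_CODES[["short_lived"]])))
  labels[mask_curr] <- code

  px <- vapply(REGION_CODES[-1], function(k) sum(code == k), integer(1))
  a <- pixel_size_um^2
  structure(
    list(labels = labels,
         pixels = px,
         areas = px * a,
         cell_pixels = sum(mask_curr),
         cell_area = sum(mask_curr) * a,
         dynamic_cell_area = unname((px[["protrusion"]] + px[["retraction"]] +
                                       px[["short_lived"]]) * a),
         delta_cell_area = unname((px[["protrusion"]] - px[["retraction"]]) * a),
         pixel_size_um = pixel_size_um),
    class = "region_map"
  )
}

as_mask <- function(m) {
  if (is.logical(m)) m else matrix(as.logical(m), nrow(m), ncol(m))
}

#' Centre of area of a binary mask
#'
#' Unweighted mean of foreground pixel coordinates (row, col).
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @return Numeric length-2 vector (row, col) in pixel units.
#' @export
mask_centroid <- function(mask) {
  mask <- as_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Cell speed from consecutive masks
#'
#' Euclidean distance between the centres of area of two consecutive
#' segmentation masks, converted to micrometres and divided by the frame
#' interval.
#'
#' @param mask_curr,mask_next Binary masks, both non-empty.
#' @param pixel_size_um Pixel size (um).
#' @param frame_interval_min Frame interval (min).
#' @return Speed in um/min.
#' @export
compute_speed <- function(mask_curr, mask_next, pixel_size_um = 0.21,
                          frame_interval_min = 5) {
  d <- mask_centroid(mask_next) - mask_centroid(mask_curr)
  sqrt(sum(d^2)) * pixel_size_um / frame_interval_min
}

#' Per-frame membrane dynamics of a mask sequence
#'
#' Runs the three-frame region classification along a mask sequence and
#' assembles the per-frame process measures. A frame is valid for dynamic
#' measures only when it has a usable previous and next frame: the first and
#' last frames of the sequence are excluded, as are frames adjacent to gap
#' frames (protrusions are undefined without a previous frame, retractions
#' without a next one). Cell speed is reported for any frame whose previous
#' frame exists and is not a gap, as centroid displacement from the previous
#' frame.
#'
#' @param seq A [mask_sequence].
#' @return A data.frame with one row per frame: `frame`, `valid`, `speed`
#'   (um/min, `NA` where undefined), `cell_area`, per-region pixel counts
#'   and areas, `dynamic_cell_area` and `delta_cell_area` (um^2; `NA` on
#'   invalid frames).
#' @export
sequence_dynamics <- function(seq) {
  stopifnot(inherits(seq, "mask_sequence"))
  n <- length(seq$frames)
  if (n < 3) stop("need at least 3 frames")
  gap <- seq$gap_flags
  px <- seq$pixel_size_um

  usable <- !gap
  valid <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    valid[i] <- usable[i - 1] && usable[i] && usable[i + 1]
  }
  if (!any(valid)) warning("no frame has both neighbours segmented")

  out <- data.frame(
    frame = seq_len(n), valid = valid, speed = NA_real_,
    cell_pixels = NA_real_, cell_area = NA_real_,
    stable_pixels = NA_real_, protrusion_pixels = NA_real_,
    retraction_pixels = NA_real_, short_lived_pixels = NA_real_,
    dynamic_cell_area = NA_real_, delta_cell_area = NA_real_
  )
  for (i in seq_len(n)) {
    if (usable[i]) {
      out$cell_pixels[i] <- sum(as_mask(seq$frames[[i]]))
      out$cell_area[i] <- out$cell_pixels[i] * px^2
      if (i > 1 && usable[i - 1]) {
        out$speed[i] <- compute_speed(seq$frames[[i - 1]], seq$frames[[i]],
                                      px, seq$frame_interval_min)
      }
    }
    if (valid[i]) {
      rm_ <- classify_regions(seq$frames[[i - 1]], seq$frames[[i]],
                              seq$frames[[i + 1]], px)
      out$stable_pixels[i] <- rm_$pixels[["stable"]]
      out$protrusion_pixels[i] <- rm_$pixels[["protrusion"]]
      out$retraction_pixels[i] <- rm_$pixels[["retraction"]]
      out$short_lived_pixels[i] <- rm_$pixels[["short_lived"]]
      out$dynamic_cell_area[i] <- rm_$dynamic_cell_area
      out$delta_cell_area[i] <- rm_$delta_cell_area
    }
  }
  out
}

#' Write a mask sequence as a multi-page TIFF
#'
#' One 8-bit page per frame, foreground 1, background 0; gap frames are
#' written as all-zero pages so the temporal slots are preserved.
#'
#' @param seq A [mask_sequence].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(seq, path) {
  stopifnot(inherits(seq, "mask_sequence"))
  # writeTIFF expects [0,1]; foreground written as 1.0, read back with > 0
  pages <- lapply(seq$frames, function(f) {
    m <- as_mask(f); matrix(as.numeric(m), nrow(m), ncol(m))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a mask sequence from a multi-page TIFF
#'
#' Any strictly positive pixel is foreground. All-zero pages are flagged as
#' gap frames.
#'
#' @param path TIFF file written by [write_mask_tiff()] (or any binary
#'   multi-page TIFF).
#' @inheritParams mask_sequence
#' @return A [mask_sequence].
#' @export
read_mask_tiff <- function(path, pixel_size_um = 0.21, frame_interval_min = 5,
                           cell_id = "cell1", experiment_id = "exp1") {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p > 0
  })
  mask_sequence(frames, pixel_size_um, frame_interval_min,
                cell_id = cell_id, experiment_id = experiment_id)
}
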