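# Segmentation: adaptive local thresholding and size-filtered region
# extraction of candidate worms from a calibrated plate image.

#' Region filter configuration
#'
#' Size bounds used to screen out objects that cannot be worms (debris
#' specks, dust, large smears). Bounds are physical so they hold across
#' calibrations; the defaults bracket L4-to-adult *C. elegans* imaged at
#' 6-7 um/pixel and should be adjusted for unusual strains.
#'
#' @param min_area_um2,max_area_um2 Area bounds in square micrometres.
#' @param min_bbox_diag_um,max_bbox_diag_um Bounding-box diagonal bounds
#'   in micrometres.
#' @param exclude_border Drop regions touching the image border (their
#'   shape parameters would be truncated). Default `TRUE`.
#' @return A `region_filter_config` object.
#' @export
region_filter_config <- function(min_area_um2 = 3000, max_area_um2 = 120000,
                                 min_bbox_diag_um = 120, max_bbox_diag_um = 2500,
                                 exclude_border = TRUE) {
  check_number(min_area_um2, "min_area_um2", lower = 1e-9)
  check_number(max_area_um2, "max_area_um2", lower = 1e-9)
  check_number(min_bbox_diag_um, "min_bbox_diag_um", lower = 1e-9)
  check_number(max_bbox_diag_um, "max_bbox_diag_um", lower = 1e-9)
  if (min_area_um2 >= max_area_um2 || min_bbox_diag_um >= max_bbox_diag_um) {
    stop_invalid("filter minima must be strictly below maxima")
  }
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_bbox_diag_um = min_bbox_diag_um,
                 max_bbox_diag_um = max_bbox_diag_um,
                 exclude_border = isTRUE(exclude_border)),
            class = "region_filter_config")
}

# Local mean over a w x w window (w odd) with replicated edges,
# computed from an integral image in O(N).
box_mean <- function(px, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  ri <- pmin(pmax(seq.int(1L - h, nr + h), 1L), nr)
  ci <- pmin(pmax(seq.int(1L - h, nc + h), 1L), nc)
  pad <- px[ri, ci, drop = FALSE]
  s <- apply(pad, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  z <- matrix(0, nrow(pad) + 1L, ncol(pad) + 1L)
  z[-1, -1] <- s
  r2 <- seq_len(nr) + 2L * h; r1 <- seq_len(nr) - 1L + 0L
  c2 <- seq_len(nc) + 2L * h; c1 <- seq_len(nc) - 1L + 0L
  (z[r2 + 1L, c2 + 1L, drop = FALSE] - z[r1 + 1L, c2 + 1L, drop = FALSE] -
   z[r2 + 1L, c1 + 1L, drop = FALSE] + z[r1 + 1L, c1 + 1L, drop = FALSE]) /
    (w * w)
}

#' Binarize a plate image by adaptive local-mean thresholding
#'
#' A pixel is foreground when it is darker than the mean intensity of a
#' square window centred on it by more than `offset`. Local (rather than
#' global) thresholding makes segmentation robust to the uneven
#' illumination typical of stitched brightfield plate scans. Holes inside
#' foreground components are filled so downstream skeletonization is not
#' perforated.
#'
#' @param image A [as_worm_image()] object.
#' @param window_um Side of the averaging window in micrometres. Default
#'   300 um (about 46 px at 6.5 um/px), roughly one worm-width scale
#'   above adult thickness so a worm does not dominate its own window.
#' @param offset Threshold offset as a fraction of the intensity range
#'   (images are normalised to `[0, 1]`). Default 0.02.
#' @param dark_foreground Worms darker than background (brightfield,
#'   the default). Set `FALSE` for inverted-polarity images.
#' @return A `worm_mask` object: logical `pixels` matrix plus the
#'   calibration carried over from `image`.
#' @export
binarize <- function(image, window_um = 300, offset = 0.02,
                     dark_foreground = TRUE) {
  if (!inherits(image, "worm_image")) stop_invalid("image must be a worm_image")
  check_number(window_um, "window_um", lower = 1e-9)
  check_number(offset, "offset", lower = 0, upper = 1)
  w <- round(window_um / image$um_per_pixel)
  if (w < 3) stop_invalid("window_um spans fewer than 3 pixels at ",
                          image$um_per_pixel, " um/px")
  if (w %% 2 == 0) w <- w + 1
  px <- image$pixels
  mu <- box_mean(px, w)
  fg <- if (dark_foreground) px < mu - offset else px > mu + offset
  filled <- t(as.matrix(EBImage::fillHull(EBImage::Image(t(fg * 1)))) ) > 0.5
  structure(list(pixels = filled, um_per_pixel = image$um_per_pixel),
            class = "worm_mask")
}

#' Extract size-filtered candidate-worm regions from a binary mask
#'
#' Labels 8-connected foreground components and keeps those whose area
#' and bounding-box diagonal fall inside the configured physical bounds.
#' Border-touching components are dropped when `cfg$exclude_border` is
#' set. Regions are returned ordered by bounding-box origin (row, then
#' column), each cropped to its bounding box.
#'
#' @param mask A `worm_mask` from [binarize()].
#' @param cfg A [region_filter_config()].
#' @return List of `worm_region` objects with fields `mask` (logical
#'   matrix cropped to the bounding box, containing only this
#'   component's pixels), `bbox` (`c(row0, col0, height, width)`,
#'   0-based origin), `area_px`, `touches_border`, `region_id` and
#'   `um_per_pixel`.
#' @export
extract_regions <- function(mask, cfg = region_filter_config()) {
  if (!inherits(mask, "worm_mask")) stop_invalid("mask must be a worm_mask")
  if (!inherits(cfg, "region_filter_config")) {
    stop_invalid("cfg must be a region_filter_config")
  }
  upp <- mask$um_per_pixel
  lab <- .label8(matrix(as.integer(mask$pixels), nrow(mask$pixels)))
  nr <- nrow(lab); nc <- ncol(lab)
  fg <- which(lab > 0L)
  if (length(fg) == 0L) return(list())
  labs <- lab[fg]
  areas <- tabulate(labs)
  # discard speck/oversize labels on area alone before any per-label work
  area_ok <- which(areas * upp^2 >= cfg$min_area_um2 &
                   areas * upp^2 <= cfg$max_area_um2)
  if (length(area_ok) == 0L) return(list())
  sel <- labs %in% area_ok
  fg <- fg[sel]; labs <- labs[sel]
  rows <- (fg - 1L) %% nr + 1L
  cols <- (fg - 1L) %/% nr + 1L
  keep <- list()
  for (px in split(seq_along(fg), labs)) {
    r1 <- min(rows[px]); r2 <- max(rows[px])
    c1 <- min(cols[px]); c2 <- max(cols[px])
    h <- r2 - r1 + 1L; w <- c2 - c1 + 1L
    touches <- r1 == 1L || c1 == 1L || r2 == nr || c2 == nc
    diag_um <- sqrt((h * upp)^2 + (w * upp)^2)
    if (diag_um < cfg$min_bbox_diag_um || diag_um > cfg$max_bbox_diag_um) next
    if (cfg$exclude_border && touches) next
    sub <- matrix(FALSE, h, w)
    sub[cbind(rows[px] - r1 + 1L, cols[px] - c1 + 1L)] <- TRUE
    keep[[length(keep) + 1L]] <- structure(
      list(mask = sub,
           bbox = c(row0 = r1 - 1L, col0 = c1 - 1L, height = h, width = w),
           area_px = length(px), touches_border = touches,
           region_id = NA_integer_, um_per_pixel = upp),
      class = "worm_region")
  }
  if (length(keep) == 0L) return(list())
  ord <- order(vapply(keep, function(r) r$bbox[["row0"]], 0),
               vapply(keep, function(r) r$bbox[["col0"]], 0))
  keep <- keep[ord]
  for (i in seq_along(keep)) keep[[i]]$region_id <- i
  keep
}

#' Tabulate extracted regions
#'
#' @param regions List of `worm_region` objects from [extract_regions()].
#' @return Data frame with one row per region
#'   (`region_id,row0,col0,height,width,area_px,touches_border`).
#' @export
regions_table <- function(regions) {
  if (length(regions) == 0L) {
    return(data.frame(region_id = integer(), row0 = integer(),
                      col0 = integer(), height = integer(), width = integer(),
                      area_px = integer(), touches_border = logical()))
  }
  do.call(rbind, lapply(regions, function(r) {
    data.frame(region_id = r$region_id, row0 = r$bbox[["row0"]],
               col0 = r$bbox[["col0"]], height = r$bbox[["height"]],
               width = r$bbox[["width"]], area_px = r$area_px,
               touches_border = r$touches_border)
  }))
}

#' Render a label image for region debugging
#'
#' @param regions List of `worm_region` objects.
#' @param dim Dimensions `c(rows, cols)` of the source image.
#' @return Integer matrix with each region painted as its `region_id`.
#' @export
regions_label_image <- function(regions, dim) {
  lab <- matrix(0L, dim[1], dim[2])
  for (r in regions) {
    rows <- (r$bbox[["row0"]] + 1L):(r$bbox[["row0"]] + r$bbox[["height"]])
    cols <- (r$bbox[["col0"]] + 1L):(r$bbox[["col0"]] + r$bbox[["width"]])
    sub <- lab[rows, cols]
    sub[r$mask] <- r$region_id
    lab[rows, cols] <- sub
  }
  lab
}

#' @export
print.worm_mask <- function(x, ...) {
  cat("<worm_mask> ", nrow(x$pixels), "x", ncol(x$pixels), " px, ",
      sum(x$pixels), " foreground\n", sep = "")
  invisible(x)
}
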