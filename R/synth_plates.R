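# Synthetic plate-image generator with per-animal ground truth.
#
# Emulates what the segmentation and metrology stages assume about real
# plates: elongated smooth-midline animals darker than a bright, possibly
# unevenly lit background, with class-specific sizes and tail tapers,
# egg-shaped confounders, debris specks, and crowding-induced contact.
# Rasterization stamps discs along the midline with no anti-aliasing, so
# the per-animal mask truth is exact.

#' Specification of one synthetic worm class
#'
#' @param class_label `"hermaphrodite"`, `"male"` or `"larva"`.
#' @param length_um_range Min/max midline length (um).
#' @param halfwidth_um_range Min/max mid-body half-width (um).
#' @param end_a,end_b Target body diameters `c(d20, d120)` (um) at 20 and
#'   120 um of arc from each end; the tail taper interpolates through
#'   them. A blunt (male-like) end has d20 close to d120.
#' @param tip_diameter_um Diameter of the visible blob at the very tip
#'   (default 12 um; at 6-7 um/pixel a worm end never resolves to a
#'   sub-pixel point).
#' @param blend_um Arc length over which the taper blends into the
#'   mid-body width beyond the 120 um probe (default 150 um).
#' @param curvature_per_um Maximum heading change per micrometre of arc
#'   (rad/um), bounding the sinusoidal body undulation; 0 gives a
#'   straight worm.
#' @param intensity_contrast Fractional darkening of worm pixels
#'   relative to the local background.
#' @return A `worm_spec` object.
#' @export
worm_spec <- function(class_label, length_um_range, halfwidth_um_range,
                      end_a, end_b = end_a, tip_diameter_um = 12,
                      blend_um = 150, curvature_per_um = 0.010,
                      intensity_contrast = 0.35) {
  class_label <- match.arg(class_label, WORM_CLASSES)
  stopifnot(length(length_um_range) == 2L, diff(length_um_range) >= 0,
            all(length_um_range > 0),
            length(halfwidth_um_range) == 2L, all(halfwidth_um_range > 0),
            length(end_a) == 2L, length(end_b) == 2L,
            curvature_per_um >= 0,
            intensity_contrast > 0, intensity_contrast <= 1)
  structure(list(class_label = class_label,
                 length_um_range = as.numeric(length_um_range),
                 halfwidth_um_range = as.numeric(halfwidth_um_range),
                 end_a = as.numeric(end_a), end_b = as.numeric(end_b),
                 tip_diameter_um = tip_diameter_um, blend_um = blend_um,
                 curvature_per_um = curvature_per_um,
                 intensity_contrast = intensity_contrast),
            class = "worm_spec")
}

#' Default class specifications for the generator
#'
#' Sizes and tapers chosen to reproduce the qualitative ordering between
#' classes on real plates (males shorter and thinner than hermaphrodites
#' with one blunt tail end; larvae much smaller): these are generator
#' conventions, not measured constants.
#'
#' @return Named list of three [worm_spec()] objects.
#' @export
default_worm_specs <- function() {
  list(
    # end_a is the (blunt-ish) head, end_b the tail; only the male tail
    # is a blunt fan, the hermaphrodite tail tapers to a fine point
    hermaphrodite = worm_spec("hermaphrodite", c(900, 1200), c(30, 40),
                              end_a = c(22, 46), end_b = c(14, 42)),
    male = worm_spec("male", c(700, 900), c(22, 30),
                     end_a = c(22, 42), end_b = c(34, 44)),
    larva = worm_spec("larva", c(250, 600), c(10, 20),
                      end_a = c(11, 20), end_b = c(7, 16),
                      tip_diameter_um = 7, curvature_per_um = 0.012)
  )
}

# Half-width (um) at arc position s for a worm of length L: the minimum
# of the two end-taper profiles and the mid-body half-width.
halfwidth_profile <- function(spec, L, h, jitter_a = 1, jitter_b = 1) {
  mk <- function(ends, jit) {
    xs <- c(0, 20, 120, 120 + spec$blend_um)
    ys <- c(spec$tip_diameter_um / 2, jit * ends[1] / 2, jit * ends[2] / 2, h)
    ys <- pmin(ys, h)
    function(s) stats::approx(xs, ys, xout = pmin(s, max(xs)), rule = 2)$y
  }
  pa <- mk(spec$end_a, jitter_a)
  pb <- mk(spec$end_b, jitter_b)
  function(s) pmin(pa(s), pb(L - s), h)
}

#' Generate one synthetic worm raster with ground truth
#'
#' Draws a smooth midline as a sinusoidal body undulation (the S-shaped
#' posture worms settle into on a plate) with random phase, wavelength
#' and orientation, bounded by the spec's maximum curvature; applies the
#' class half-width profile; and rasterizes by stamping discs along the
#' midline. Deterministic for a fixed seed.
#'
#' @param spec A [worm_spec()].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param um_per_pixel Calibration of the rendered raster (default 6.5).
#' @param theta0 Optional fixed base heading in radians (`NULL`, the
#'   default, draws it at random). Useful for controlled-orientation
#'   metrology phantoms.
#' @return List with `mask` (logical matrix on a local canvas), `truth`
#'   (class, `length_um`, `midline_um` n x 2 polyline in local-canvas
#'   micrometre coordinates, per-end target diameters `d20_a`, `d120_a`,
#'   `d20_b`, `d120_b`, mid-body `halfwidth_um`) and
#'   `intensity_contrast`.
#' @export
make_worm <- function(spec, seed = NULL, um_per_pixel = 6.5, theta0 = NULL) {
  if (!inherits(spec, "worm_spec")) stop_invalid("spec must be a worm_spec")
  with_seed(seed, {
    L <- runif(1, spec$length_um_range[1], spec$length_um_range[2])
    h <- runif(1, spec$halfwidth_um_range[1], spec$halfwidth_um_range[2])
    jit_a <- runif(1, 0.92, 1.08)
    jit_b <- runif(1, 0.92, 1.08)
    ds <- 5
    n <- max(2L, ceiling(L / ds))
    steps <- rep(L / n, n)
    if (is.null(theta0)) theta0 <- runif(1, 0, 2 * pi)
    lambda <- L / runif(1, 1.3, 1.8)       # undulation wavelength
    amp <- min(runif(1, 0.45, 0.8),        # heading amplitude (rad)
               spec$curvature_per_um * lambda / (2 * pi))
    phase <- runif(1, 0, 2 * pi)
    s_mid <- cumsum(steps) - steps / 2
    jit <- min(0.002, spec$curvature_per_um)  # zero curvature = straight
    theta <- theta0 + amp * sin(2 * pi * s_mid / lambda + phase) +
      cumsum(runif(n, -jit, jit) * steps)
    xy <- cbind(c(0, cumsum(steps * cos(theta))),
                c(0, cumsum(steps * sin(theta))))
    hw <- halfwidth_profile(spec, L, h, jit_a, jit_b)
    # sample the midline densely (sub-pixel) for disc stamping
    arc <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
    s_dense <- seq(0, L, by = um_per_pixel * 0.35)
    px <- stats::approx(arc, xy[, 1], xout = s_dense)$y
    py <- stats::approx(arc, xy[, 2], xout = s_dense)$y
    rad_um <- hw(s_dense)
    pad_um <- max(rad_um) + 2 * um_per_pixel
    x0 <- min(px) - pad_um
    y0 <- min(py) - pad_um
    nr <- ceiling((max(px) - x0 + pad_um) / um_per_pixel) + 1L
    nc <- ceiling((max(py) - y0 + pad_um) / um_per_pixel) + 1L
    canvas <- matrix(FALSE, nr, nc)
    canvas <- .stamp_discs(canvas, (px - x0) / um_per_pixel,
                           (py - y0) / um_per_pixel, rad_um / um_per_pixel)
    midline <- cbind(xy[, 1] - x0, xy[, 2] - y0)
    # The rendered body is the envelope of the stamped disc family: on a
    # steep taper it is wider than the probe profile 2*hw(s), and the
    # mask extends past each midline end by the tip disc radius. Truth
    # diameters are the envelope widths at probe arcs measured from the
    # visible (mask) end, matching how the metrology counts arc "from
    # the end".
    env_hw <- function(x) {
      d2 <- rad_um^2 - (x - s_dense)^2
      if (any(d2 > 0)) sqrt(max(d2)) else 0
    }
    tip_a <- max(rad_um - s_dense)
    tip_b <- max(rad_um - (L - s_dense))
    truth <- list(class_label = spec$class_label, length_um = L,
                  midline_um = midline,
                  d20_a = 2 * env_hw(20 - tip_a),
                  d120_a = 2 * env_hw(120 - tip_a),
                  d20_b = 2 * env_hw(L - 20 + tip_b),
                  d120_b = 2 * env_hw(L - 120 + tip_b),
                  halfwidth_um = h)
    list(mask = canvas, truth = truth,
         intensity_contrast = spec$intensity_contrast)
  })
}

stamp_ellipse <- function(canvas, cr, cc, ra, rb, angle) {
  ca <- cos(angle); sa <- sin(angle)
  r1 <- max(1L, floor(cr - ra - rb)); r2 <- min(nrow(canvas), ceiling(cr + ra + rb))
  c1 <- max(1L, floor(cc - ra - rb)); c2 <- min(ncol(canvas), ceiling(cc + ra + rb))
  if (r1 > r2 || c1 > c2) return(canvas)
  rs <- r1:r2; cs <- c1:c2
  dr <- outer(rs - cr, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - cc)
  u <- dr * ca + dc * sa
  v <- -dr * sa + dc * ca
  canvas[rs, cs] <- canvas[rs, cs] | ((u / ra)^2 + (v / rb)^2 <= 1)
  canvas
}

#' Render a synthetic plate image with ground truth
#'
#' Composes seeded synthetic worms onto a bright background. The
#' `spaced` layout rejection-samples positions so each animal keeps at
#' least three worm-widths of clearance; `crowded` places animals
#' uniformly at random on a deliberately small canvas so contact and
#' clump formation occur, emulating overcrowded wells. Optional
#' egg-shaped confounders, debris specks, a linear illumination gradient
#' and Gaussian intensity noise complete the image. Deterministic per
#' seed.
#'
#' @param n_hermaphrodite,n_male,n_larva Animals per class.
#' @param layout `"spaced"` or `"crowded"`.
#' @param attach_prob In the crowded layout, the probability that an
#'   animal is dropped onto an already-placed one to form a contact
#'   clump (default 0.04, i.e. roughly 8% of animals end up clumped;
#'   clump membership is independent of class, emulating overcrowded
#'   wells where clustered animals become unmeasurable).
#' @param noise_sd Gaussian intensity noise sd (image scale 0-1;
#'   default 0.02).
#' @param illum_gradient Amplitude of a linear left-right illumination
#'   ramp as a fraction of background (default 0.10, i.e. +/-10%).
#' @param eggs Number of egg-shaped objects scattered on the plate.
#' @param eggs_at_tails If `TRUE`, eggs are placed touching hermaphrodite
#'   tail ends instead of scattered, reproducing the known failure mode
#'   in which an egg-capped hermaphrodite tail reads as blunt.
#' @param debris Number of small dark debris specks.
#' @param seed Integer seed controlling every random choice.
#' @param specs Named list of class [worm_spec()]s
#'   (default [default_worm_specs()]).
#' @param um_per_pixel Calibration (default 6.5).
#' @param background Background intensity (default 0.85).
#' @param canvas_px Optional `c(rows, cols)`; sized automatically from
#'   the layout when `NULL`.
#' @return List with `image` (a [as_worm_image()]) and `truth`: per-animal
#'   records (id, class, local mask + plate offset, midline in plate
#'   micrometre coordinates, length and per-end taper diameters), plus
#'   plate-level counts, the true male percentage among adults, canvas
#'   size, calibration, seed and noise settings.
#' @export
render_plate <- function(n_hermaphrodite, n_male, n_larva = 0,
                         layout = c("spaced", "crowded"), attach_prob = 0.04,
                         noise_sd = 0.02,
                         illum_gradient = 0.10, eggs = 0,
                         eggs_at_tails = FALSE, debris = 0, seed = 1,
                         specs = default_worm_specs(), um_per_pixel = 6.5,
                         background = 0.85, canvas_px = NULL) {
  layout <- match.arg(layout)
  stopifnot(n_hermaphrodite >= 0, n_male >= 0, n_larva >= 0)
  with_seed(seed, {
    labels <- rep(WORM_CLASSES, times = c(n_hermaphrodite, n_male, n_larva))
    worms <- lapply(labels, function(cl) make_worm(specs[[cl]],
                                                   um_per_pixel = um_per_pixel))
    clearance_px <- ceiling(3 * 70 / um_per_pixel)  # three adult widths
    if (is.null(canvas_px)) {
      if (length(worms)) {
        areas <- vapply(worms, function(w) prod(dim(w$mask)), 0)
        if (layout == "spaced") {
          pad2 <- vapply(worms, function(w)
            prod(dim(w$mask) + 2 * clearance_px), 0)
          side <- ceiling(sqrt(sum(pad2) / 0.30))
        } else {
          # packed tightly, with contact clumps injected explicitly below
          pad2 <- vapply(worms, function(w) prod(dim(w$mask) + 4), 0)
          side <- ceiling(sqrt(sum(pad2) / 0.30))
        }
        side <- max(side, 400L)
      } else side <- 400L
      canvas_px <- c(side, side)
    }
    nr <- canvas_px[1]; nc <- canvas_px[2]
    worm_lab <- matrix(0L, nr, nc)
    contrast <- matrix(0, nr, nc)
    placed <- list()
    boxes <- matrix(numeric(0), ncol = 4)  # r1, c1, r2, c2 (expanded)
    for (i in seq_along(worms)) {
      w <- worms[[i]]
      d <- dim(w$mask)
      if (d[1] >= nr || d[2] >= nc) {
        stop_invalid("animal ", i, " does not fit the canvas; enlarge canvas_px")
      }
      gap <- if (layout == "spaced") clearance_px else 2L
      attach <- layout == "crowded" && nrow(boxes) > 0 &&
        runif(1) < attach_prob
      ok <- FALSE
      if (attach) {
        # emulate crowding-induced clustering: drop this animal onto a
        # randomly chosen already-placed one so the two masks touch
        for (try in seq_len(100L)) {
          a <- boxes[sample.int(nrow(boxes), 1L), ]
          r0 <- round(runif(1, a[1] - d[1] / 2, a[3] - d[1] / 2))
          c0 <- round(runif(1, a[2] - d[2] / 2, a[4] - d[2] / 2))
          if (r0 >= 1 && c0 >= 1 && r0 + d[1] - 1L <= nr &&
              c0 + d[2] - 1L <= nc) { ok <- TRUE; break }
        }
      }
      if (!ok) {
        for (try in seq_len(500L)) {
          r0 <- sample.int(nr - d[1], 1L)
          c0 <- sample.int(nc - d[2], 1L)
          if (nrow(boxes) > 0) {
            e <- c(r0 - gap, c0 - gap, r0 + d[1] + gap, c0 + d[2] + gap)
            hit <- any(boxes[, 1] <= e[3] & boxes[, 3] >= e[1] &
                       boxes[, 2] <= e[4] & boxes[, 4] >= e[2])
            if (hit) next
          }
          ok <- TRUE
          break
        }
      }
      if (!ok) stop_invalid("could not place animal ", i,
                            " with the required clearance; enlarge the canvas")
      boxes <- rbind(boxes, c(r0, c0, r0 + d[1], c0 + d[2]))
      rows <- r0:(r0 + d[1] - 1L); cols <- c0:(c0 + d[2] - 1L)
      sub <- worm_lab[rows, cols]; sub[w$mask] <- i
      worm_lab[rows, cols] <- sub
      subc <- contrast[rows, cols]
      subc[w$mask] <- pmax(subc[w$mask], w$intensity_contrast)
      contrast[rows, cols] <- subc
      tr <- w$truth
      tr$animal_id <- i
      tr$offset_px <- c(row0 = r0 - 1L, col0 = c0 - 1L)
      tr$mask <- w$mask
      tr$midline_um <- sweep(tr$midline_um, 2,
                             -c(r0 - 1L, c0 - 1L) * um_per_pixel)
      placed[[i]] <- tr
    }
    # eggs: ~55 x 32 um ellipses, scattered or capping hermaphrodite tails
    egg_mask <- matrix(FALSE, nr, nc)
    herm_ids <- which(labels == "hermaphrodite")
    if (eggs > 0) {
      for (k in seq_len(eggs)) {
        ang <- runif(1, 0, pi)
        if (eggs_at_tails && length(herm_ids)) {
          tgt <- placed[[herm_ids[1 + (k - 1) %% length(herm_ids)]]]
          ml <- tgt$midline_um / um_per_pixel
          end <- if (k %% 2 == 0) ml[1, ] else ml[nrow(ml), ]
          nxt <- if (k %% 2 == 0) ml[2, ] else ml[nrow(ml) - 1, ]
          dirv <- end - nxt; dirv <- dirv / sqrt(sum(dirv^2))
          ctr <- end + dirv * (20 / um_per_pixel)
          ang <- atan2(dirv[2], dirv[1])
        } else {
          ctr <- c(runif(1, 5, nr - 5), runif(1, 5, nc - 5))
        }
        egg_mask <- stamp_ellipse(egg_mask, ctr[1], ctr[2],
                                  27.5 / um_per_pixel, 16 / um_per_pixel, ang)
      }
    }
    if (debris > 0) {
      for (k in seq_len(debris)) {
        ctr <- c(runif(1, 3, nr - 3), runif(1, 3, nc - 3))
        egg_mask <- stamp_ellipse(egg_mask, ctr[1], ctr[2],
                                  runif(1, 0.6, 1.6), runif(1, 0.6, 1.6),
                                  runif(1, 0, pi))
      }
    }
    ramp <- matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr, nc)
    img <- background * (1 + illum_gradient * ramp)
    dark <- pmax(contrast, ifelse(egg_mask, 0.25, 0))
    img <- img * (1 - dark)
    if (noise_sd > 0) img <- img + rnorm(nr * nc, 0, noise_sd)
    img <- pmin(pmax(img, 0), 1)
    adults <- n_hermaphrodite + n_male
    truth <- list(animals = placed,
                  counts = c(hermaphrodite = n_hermaphrodite, male = n_male,
                             larva = n_larva),
                  male_percentage = if (adults > 0) 100 * n_male / adults
                                    else NA_real_,
                  image_size = c(nr, nc), um_per_pixel = um_per_pixel,
                  seed = seed, noise_sd = noise_sd,
                  illum_gradient = illum_gradient, layout = layout,
                  eggs = eggs, debris = debris)
    list(image = as_worm_image(img, um_per_pixel), truth = truth)
  })
}

#' Rasterized ground-truth label image of a rendered plate
#'
#' @param truth The `truth` component of [render_plate()].
#' @return Integer matrix with each animal painted as its id.
#' @export
truth_label_image <- function(truth) {
  lab <- matrix(0L, truth$image_size[1], truth$image_size[2])
  for (a in truth$animals) {
    d <- dim(a$mask)
    rows <- (a$offset_px[["row0"]] + 1L):(a$offset_px[["row0"]] + d[1])
    cols <- (a$offset_px[["col0"]] + 1L):(a$offset_px[["col0"]] + d[2])
    sub <- lab[rows, cols]; sub[a$mask] <- a$animal_id
    lab[rows, cols] <- sub
  }
  lab
}

#' Write plate ground truth as JSON (masks omitted)
#'
#' @param truth The `truth` component of [render_plate()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$counts <- as.list(truth$counts)
  out$animals <- lapply(truth$animals, function(a) {
    a$mask <- NULL
    a$midline_um <- unname(a$midline_um)
    a$offset_px <- as.list(a$offset_px)
    a
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic per-well count table for agreement analyses
#'
#' Emulates a manual-versus-automatic counting experiment across wells
#' with widely varying population sizes and sex ratios: the automatic
#' counter misses a fraction of animals that grows with crowding (beyond
#' about 150 animals per well) and misclassifies a small fraction of
#' each sex. Manual counts are taken as truth. This is a synthetic
#' stand-in with the same schema as a real per-well raw-data table.
#'
#' @param n_wells Number of wells (default 60).
#' @param seed Integer seed.
#' @return Data frame with columns `well_id, manual_male, manual_herm,
#'   auto_male, auto_herm`.
#' @export
synth_well_records <- function(n_wells = 60, seed = 1) {
  with_seed(seed, {
    total <- pmax(2L, round(exp(runif(n_wells, log(2), log(350)))))
    p <- runif(n_wells, 0.02, 0.5)
    manual_male <- rbinom(n_wells, total, p)
    manual_herm <- total - manual_male
    retain <- ifelse(total > 150, 0.78, 0.93)
    auto_male <- rbinom(n_wells, manual_male, retain)
    auto_herm <- rbinom(n_wells, manual_herm, retain)
    # small symmetric misclassification between the sexes
    flip_m <- rbinom(n_wells, auto_male, 0.03)
    flip_h <- rbinom(n_wells, auto_herm, 0.03)
    auto_male <- auto_male - flip_m + flip_h
    auto_herm <- auto_herm - flip_h + flip_m
    data.frame(well_id = seq_len(n_wells), manual_male = manual_male,
               manual_herm = manual_herm, auto_male = auto_male,
               auto_herm = auto_herm)
  })
}
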