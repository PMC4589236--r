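# Morphometry: reduce a segmented worm region to four shape parameters
# (midline length, mean thickness, and the two end diameter ratios) via
# thinning-based skeleton metrology.

#' Tail probe configuration
#'
#' Positions along the midline, measured in arc length from each end of
#' the skeleton, where body diameters are probed to characterise tail
#' taper. The diameter ratio D(x1)/D(x2) is near 1 for a blunt (male)
#' tail and small for a sharply tapered (hermaphrodite) tail.
#'
#' @param x1_um Inner probe position, micrometres from the end (default 20).
#' @param x2_um Outer probe position (default 120). Must exceed `x1_um`.
#' @param spur_prune_um Maximum length of skeleton side branches (spurs)
#'   removed during cleanup, micrometres. Thinning produces short spurs
#'   at wide worm heads; 40 um removes those without erasing anatomy.
#' @return A `tail_probe_config` object.
#' @export
tail_probe_config <- function(x1_um = 20, x2_um = 120, spur_prune_um = 40) {
  check_number(x1_um, "x1_um", lower = 1e-9)
  check_number(x2_um, "x2_um", lower = 1e-9)
  check_number(spur_prune_um, "spur_prune_um", lower = 0)
  if (x1_um >= x2_um) stop_invalid("x1_um must be smaller than x2_um")
  structure(list(x1_um = x1_um, x2_um = x2_um, spur_prune_um = spur_prune_um),
            class = "tail_probe_config")
}

# Build the pixel-adjacency structure of a skeleton mask. Diagonal links
# that are shortcut by an orthogonal neighbour shared by both pixels are
# dropped so that staircase pixels are not miscounted as junctions.
skeleton_graph <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[cbind(idx[, 1], idx[, 2])] <- seq_len(n)
  nbr <- vector("list", n)
  nr <- nrow(skel); nc <- ncol(skel)
  for (i in seq_len(n)) {
    r <- idx[i, 1]; c <- idx[i, 2]
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !skel[rr, cc]) next
      if (dr != 0 && dc != 0) {
        # drop diagonal edge when an orthogonal 2-step path exists
        if (skel[r, cc] || skel[rr, c]) next
      }
      out <- c(out, id[rr, cc])
    }
    nbr[[i]] <- out
  }
  list(coords = idx, nbr = nbr, deg = lengths(nbr))
}

# Smooth an ordered pixel path with a short boxcar (window shrinking at
# the ends) and re-digitize it as a minimal 8-connected chain, removing
# the transverse one-pixel wiggle that thinning leaves on curved bodies.
smooth_redigitize <- function(pts) {
  n <- nrow(pts)
  if (n < 5L) return(pts)
  half <- 2L
  cs_r <- cumsum(pts[, 1]); cs_c <- cumsum(pts[, 2])
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  m_r <- (cs_r[hi] - c(0, cs_r)[lo]) / (hi - lo + 1L)
  m_c <- (cs_c[hi] - c(0, cs_c)[lo]) / (hi - lo + 1L)
  # anchor points every ~2.5 px of arc, endpoints always included
  d <- sqrt(diff(m_r)^2 + diff(m_c)^2)
  arc <- c(0, cumsum(d))
  anchors <- unique(c(findInterval(seq(0, arc[n], by = 2), arc), n))
  ar <- round(m_r[anchors]); ac <- round(m_c[anchors])
  out_r <- ar[1]; out_c <- ac[1]
  for (k in seq_len(length(anchors) - 1L)) {
    dr <- ar[k + 1] - ar[k]; dc <- ac[k + 1] - ac[k]
    ns <- max(abs(dr), abs(dc))
    if (ns == 0) next
    seg_r <- ar[k] + round(seq_len(ns) * dr / ns)
    seg_c <- ac[k] + round(seq_len(ns) * dc / ns)
    out_r <- c(out_r, seg_r); out_c <- c(out_c, seg_c)
  }
  keep <- c(TRUE, diff(out_r) != 0 | diff(out_c) != 0)
  cbind(out_r[keep], out_c[keep])
}

# Canonical orientation of a mask: the lexicographically smallest of its
# eight dihedral transforms (by dimensions, then foreground indices).
# Measuring in this frame makes every skeleton quantity invariant under
# 90-degree rotations and flips of the input, which pixel-level thinning
# is not; `to_orig` maps point coordinates back to the input frame.
canonical_mask <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  best <- NULL
  for (tr in c(FALSE, TRUE)) for (fr in c(FALSE, TRUE)) for (fc in c(FALSE, TRUE)) {
    m2 <- if (tr) t(m) else m
    if (fr) m2 <- m2[rev(seq_len(nrow(m2))), , drop = FALSE]
    if (fc) m2 <- m2[, rev(seq_len(ncol(m2))), drop = FALSE]
    key <- c(nrow(m2), ncol(m2), which(m2))
    if (is.null(best)) {
      take <- TRUE
    } else {
      take <- FALSE
      k0 <- best$key
      len <- min(length(key), length(k0))
      cmp <- which(key[seq_len(len)] != k0[seq_len(len)])[1]
      if (!is.na(cmp) && key[cmp] < k0[cmp]) take <- TRUE
    }
    if (take) best <- list(mask = m2, key = key, tr = tr, fr = fr, fc = fc)
  }
  tr <- best$tr; fr <- best$fr; fc <- best$fc
  nr2 <- nrow(best$mask); nc2 <- ncol(best$mask)
  to_orig <- function(pts) {
    r <- pts[, 1]; c <- pts[, 2]
    if (fc) c <- nc2 + 1 - c
    if (fr) r <- nr2 + 1 - r
    if (tr) cbind(c, r) else cbind(r, c)
  }
  list(mask = best$mask, to_orig = to_orig)
}

# Euclidean distance transform of the region mask, padded by one pixel of
# background so the crop boundary counts as background.
region_distmap <- function(mask) {
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  d <- t(as.matrix(EBImage::distmap(EBImage::Image(t(pad)), "euclidean")))
  d[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
}

# Extend an ordered path from both ends along the local tangent until it
# leaves the mask, then trim each end back to just past the medial-axis
# endpoint of the end cap: the point whose arc distance from the mask
# tip equals the local inscribed-disc radius plus one and a half pixels
# of boundary-noise guard. Raw thinning erodes blunt end caps by a
# highly shape-dependent amount; anchoring the endpoints to the cap
# geometry makes end-shortening consistent across body shapes.
anchor_endpoints <- function(pts, mask, dt) {
  extend_end <- function(pts, head) {
    n <- nrow(pts)
    if (n < 5L) return(pts)
    p0 <- if (head) pts[1, ] else pts[n, ]
    pin <- if (head) pts[5, ] else pts[n - 4L, ]
    v <- p0 - pin
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(pts)
    v <- v / nv
    t <- 0.5
    last <- p0
    while (TRUE) {
      q <- round(p0 + v * t)
      if (q[1] < 1 || q[1] > nrow(mask) || q[2] < 1 || q[2] > ncol(mask) ||
          !mask[q[1], q[2]]) break
      last <- q
      t <- t + 0.5
    }
    if (all(last == p0)) return(pts)
    dr <- last[1] - p0[1]; dc <- last[2] - p0[2]
    ns <- max(abs(dr), abs(dc))
    ext <- cbind(p0[1] + round(seq_len(ns) * dr / ns),
                 p0[2] + round(seq_len(ns) * dc / ns))
    keep <- c(TRUE, diff(ext[, 1]) != 0 | diff(ext[, 2]) != 0)
    ext <- ext[keep, , drop = FALSE]
    if (head) rbind(ext[rev(seq_len(nrow(ext))), , drop = FALSE], pts)
    else rbind(pts, ext)
  }
  trim_end <- function(pts, head) {
    n <- nrow(pts)
    if (n < 3L) return(list(pts = pts, gap = 0))
    ord <- if (head) seq_len(n) else rev(seq_len(n))
    d <- sqrt(rowSums((pts[ord[-1], , drop = FALSE] -
                       pts[ord[-n], , drop = FALSE])^2))
    arc <- c(0, cumsum(d))
    dtv <- dt[pts[ord, , drop = FALSE]]
    cut <- which(arc >= dtv + 1)[1]
    if (is.na(cut) || cut <= 1L || n - cut + 1L < 2L) {
      return(list(pts = pts, gap = 0))
    }
    out <- if (head) pts[cut:n, , drop = FALSE]
           else pts[1:(n - cut + 1L), , drop = FALSE]
    list(pts = out, gap = arc[cut])
  }
  pts <- extend_end(pts, head = TRUE)
  pts <- extend_end(pts, head = FALSE)
  a <- trim_end(pts, head = TRUE)
  b <- trim_end(a$pts, head = FALSE)
  # full: the tip-to-tip path (kept for diameter probing);
  # gaps: arc (px) from each trimmed endpoint back to its mask tip
  list(pts = b$pts, full = pts, gap_a = a$gap, gap_b = b$gap)
}

# Walk from an endpoint until hitting a junction (degree >= 3), another
# endpoint, or running out; returns visited node ids and arc length (px).
walk_spur <- function(g, start) {
  path <- start
  len <- 0
  prev <- 0L
  cur <- start
  repeat {
    nxt <- setdiff(g$nbr[[cur]], prev)
    if (length(nxt) == 0L) return(list(path = path, len_px = len, hit = NA))
    if (g$deg[cur] >= 3L && cur != start) {
      return(list(path = path[-length(path)], len_px = len, hit = cur))
    }
    nxt <- nxt[1]
    step <- sqrt(sum((g$coords[nxt, ] - g$coords[cur, ])^2))
    if (g$deg[nxt] >= 3L) {
      return(list(path = path, len_px = len + step, hit = nxt))
    }
    len <- len + step
    path <- c(path, nxt)
    prev <- cur
    cur <- nxt
  }
}

#' Skeletonize a worm region into an ordered midline
#'
#' Thins the (hole-filled) region mask to a one-pixel-wide skeleton,
#' iteratively removes spurs shorter than `cfg$spur_prune_um`, and, if
#' the result is a single endpoint-to-endpoint path, returns it ordered
#' from the endpoint with the smaller (row, col). Regions whose pruned
#' skeleton still branches (clumped or coiled animals) or degenerates to
#' fewer than two pixels are returned as typed rejections, not errors.
#'
#' @param region A `worm_region` from [extract_regions()].
#' @param cfg A [tail_probe_config()] (supplies `spur_prune_um`).
#' @return A `midline_skeleton` with fields `points` (n x 2 matrix of
#'   1-based row/col within the region crop), `step_lengths` (px; 1 for
#'   orthogonal, sqrt(2) for diagonal moves), `total_length_px`,
#'   `cumulative_um` (arc length from endpoint A at each point) and
#'   `um_per_pixel` — or a [worm_rejection()].
#' @export
skeletonize_region <- function(region, cfg = tail_probe_config()) {
  if (!inherits(region, "worm_region")) stop_invalid("region must be a worm_region")
  upp <- region$um_per_pixel
  # thin in the canonical orientation so results do not depend on how
  # the plate (and hence the region crop) happened to be oriented
  can <- canonical_mask(region$mask)
  skel <- .thin_mask(matrix(as.integer(can$mask), nrow(can$mask))) > 0
  if (sum(skel) < 2L) return(worm_rejection("degenerate", region$region_id))

  prune_px <- cfg$spur_prune_um / upp
  repeat {
    g <- skeleton_graph(skel)
    ends <- which(g$deg == 1L)
    if (!any(g$deg >= 3L)) break
    removed <- FALSE
    for (e in ends) {
      w <- walk_spur(g, e)
      if (!is.na(w$hit) && g$deg[w$hit] >= 3L && w$len_px <= prune_px) {
        skel[g$coords[w$path, , drop = FALSE]] <- FALSE
        removed <- TRUE
        break  # graph is stale after a removal; rebuild
      }
    }
    if (!removed) break
    if (sum(skel) < 2L) return(worm_rejection("degenerate", region$region_id))
  }

  g <- skeleton_graph(skel)
  n <- length(g$deg)
  if (n < 2L) return(worm_rejection("degenerate", region$region_id))
  ends <- which(g$deg == 1L)
  if (any(g$deg >= 3L) || length(ends) != 2L) {
    # residual junctions (clumps), or a closed loop (coiled animal)
    return(worm_rejection("branched", region$region_id))
  }
  # order from the endpoint with smaller (row, col)
  a <- ends[order(g$coords[ends, 1], g$coords[ends, 2])][1]
  w <- walk_spur(g, a)
  if (length(w$path) != n) return(worm_rejection("branched", region$region_id))
  anchored <- anchor_endpoints(smooth_redigitize(g$coords[w$path, , drop = FALSE]),
                               can$mask, region_distmap(can$mask))
  pts <- can$to_orig(anchored$pts)
  full <- can$to_orig(anchored$full)
  gaps <- c(A = anchored$gap_a, B = anchored$gap_b)
  n <- nrow(pts)
  if (n < 2L) return(worm_rejection("degenerate", region$region_id))
  if (pts[1, 1] > pts[n, 1] ||
      (pts[1, 1] == pts[n, 1] && pts[1, 2] > pts[n, 2])) {
    pts <- pts[rev(seq_len(n)), , drop = FALSE]
    full <- full[rev(seq_len(nrow(full))), , drop = FALSE]
    gaps <- gaps[c(2, 1)]
    names(gaps) <- c("A", "B")
  }
  steps <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  total <- sum(steps)
  if (total <= 0) return(worm_rejection("degenerate", region$region_id))
  structure(list(points = pts, step_lengths = steps, total_length_px = total,
                 cumulative_um = c(0, cumsum(steps)) * upp,
                 tip_gap_um = gaps * upp, full_points = full,
                 um_per_pixel = upp),
            class = "midline_skeleton")
}

#' Midline length in micrometres
#'
#' @param skel A `midline_skeleton`.
#' @param um_per_pixel Calibration; defaults to the skeleton's own.
#' @return Length in micrometres.
#' @export
measure_length <- function(skel, um_per_pixel = skel$um_per_pixel) {
  if (!inherits(skel, "midline_skeleton")) stop_invalid("skel must be a midline_skeleton")
  skel$total_length_px * um_per_pixel
}

#' Mean worm thickness: area divided by midline length
#'
#' @param region The `worm_region` the skeleton was derived from.
#' @param skel Its `midline_skeleton`.
#' @param um_per_pixel Calibration; defaults to the region's own.
#' @return Thickness in micrometres.
#' @export
measure_thickness <- function(region, skel, um_per_pixel = region$um_per_pixel) {
  if (!inherits(region, "worm_region")) stop_invalid("region must be a worm_region")
  if (!inherits(skel, "midline_skeleton")) stop_invalid("skel must be a midline_skeleton")
  (region$area_px / skel$total_length_px) * um_per_pixel
}

#' Body diameter at an arc-length position along the midline
#'
#' The probe position is an arc length from the worm's end (the mask
#' tip). Endpoint anchoring trims the skeleton used for length about one
#' end-cap radius short of each tip but keeps the full tip-to-tip path;
#' the probe point is located at the requested arc from the tip on that
#' full path. Rays are cast from it along both local normals to the
#' midline in quarter-pixel steps until they leave the mask, and the
#' diameter is the distance between the two crossings. Unlike a
#' distance-transform read at the (integer) skeleton pixel, this is
#' insensitive to the one-pixel off-axis placement of a digital
#' skeleton; residual quantization is about half a pixel.
#'
#' @param region A `worm_region`.
#' @param skel Its `midline_skeleton`.
#' @param s_um Arc position in micrometres from the chosen end of the
#'   worm (the mask tip).
#' @param from_end `"A"` (path start) or `"B"` (path end).
#' @return Diameter in micrometres.
#' @export
diameter_at <- function(region, skel, s_um, from_end = c("A", "B")) {
  from_end <- match.arg(from_end)
  total_um <- skel$total_length_px * skel$um_per_pixel
  check_number(s_um, "s_um", lower = 0)
  if (s_um > total_um) stop_invalid("s_um (", s_um, ") exceeds midline length (",
                                    round(total_um, 2), ")")
  pts <- if (!is.null(skel$full_points)) skel$full_points else skel$points
  n <- nrow(pts)
  st <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(st)) * skel$um_per_pixel
  if (from_end == "B") cum <- cum[n] - cum
  i <- which.min(abs(cum - s_um))
  j1 <- max(1L, i - 4L); j2 <- min(n, i + 4L)
  v <- pts[j2, ] - pts[j1, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) v <- c(1, 0) else v <- v / nv
  nrm <- c(-v[2], v[1])
  m <- region$mask
  inside <- function(p) {
    r <- round(p[1]); c <- round(p[2])
    r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) && m[r, c]
  }
  p0 <- pts[i, ]
  # sample at k/4 - 1/8 so axis-aligned rays never land exactly on a
  # half-pixel boundary, keeping crossings mirror-symmetric
  march <- function(dir) {
    t <- 0.125
    while (t < 60 && inside(p0 + dir * t)) t <- t + 0.25
    t - 0.125
  }
  (march(nrm) + march(-nrm)) * skel$um_per_pixel
}

#' Tail-taper diameter ratios R1 and R2
#'
#' For each end of the midline the ratio D(x1)/D(x2) of body diameters at
#' the inner and outer probe positions is computed; R2 is the larger of
#' the two end ratios and R1 the smaller. Blunt (male) tails give R2
#' near 1, tapered (hermaphrodite) tails give smaller values. Which end
#' is the anatomical tail is never decided.
#'
#' @param region A `worm_region`.
#' @param skel Its `midline_skeleton`.
#' @param cfg A [tail_probe_config()].
#' @return `list(r1 =, r2 =)` or a [worm_rejection()] with reason
#'   `"too_short"` when the midline is shorter than `2 * x2_um`.
#' @export
tail_ratios <- function(region, skel, cfg = tail_probe_config()) {
  total_um <- skel$total_length_px * skel$um_per_pixel
  if (total_um < 2 * cfg$x2_um) {
    return(worm_rejection("too_short", region$region_id))
  }
  ra <- diameter_at(region, skel, cfg$x1_um, "A") /
        diameter_at(region, skel, cfg$x2_um, "A")
  rb <- diameter_at(region, skel, cfg$x1_um, "B") /
        diameter_at(region, skel, cfg$x2_um, "B")
  list(r1 = min(ra, rb), r2 = max(ra, rb))
}

#' Extract the four shape parameters from a region
#'
#' Composes [skeletonize_region()], [measure_length()],
#' [measure_thickness()] and [tail_ratios()]. Any rejection along the
#' way propagates with its reason and the region id.
#'
#' @param region A `worm_region`.
#' @param um_per_pixel Calibration; defaults to the region's own.
#' @param cfg A [tail_probe_config()].
#' @return A `worm_features` object (`length_um`, `thickness_um`, `r1`,
#'   `r2`, `region_id`) or a [worm_rejection()].
#' @export
extract_features <- function(region, um_per_pixel = region$um_per_pixel,
                             cfg = tail_probe_config()) {
  skel <- skeletonize_region(region, cfg)
  if (is_rejection(skel)) return(skel)
  rat <- tail_ratios(region, skel, cfg)
  if (is_rejection(rat)) return(rat)
  structure(list(length_um = measure_length(skel, um_per_pixel),
                 thickness_um = measure_thickness(region, skel, um_per_pixel),
                 r1 = rat$r1, r2 = rat$r2,
                 region_id = region$region_id),
            class = "worm_features")
}

#' Shape-feature table for a list of regions
#'
#' @param regions List of `worm_region` objects.
#' @param cfg A [tail_probe_config()].
#' @return Data frame with columns `region_id, length_um, thickness_um,
#'   r1, r2, status` where `status` is `ok` or the rejection reason.
#' @export
features_table <- function(regions, cfg = tail_probe_config()) {
  rows <- lapply(regions, function(r) {
    f <- extract_features(r, cfg = cfg)
    if (is_rejection(f)) {
      data.frame(region_id = r$region_id, length_um = NA_real_,
                 thickness_um = NA_real_, r1 = NA_real_, r2 = NA_real_,
                 status = f$reason)
    } else {
      data.frame(region_id = r$region_id, length_um = f$length_um,
                 thickness_um = f$thickness_um, r1 = f$r1, r2 = f$r2,
                 status = "ok")
    }
  })
  if (length(rows) == 0L) {
    return(data.frame(region_id = integer(), length_um = numeric(),
                      thickness_um = numeric(), r1 = numeric(),
                      r2 = numeric(), status = character()))
  }
  do.call(rbind, rows)
}

#' @export
print.midline_skeleton <- function(x, ...) {
  cat("<midline_skeleton> ", nrow(x$points), " points, ",
      round(x$total_length_px * x$um_per_pixel, 1), " um\n", sep = "")
  invisible(x)
}

#' @export
print.worm_features <- function(x, ...) {
  cat(sprintf("<worm_features> length %.1f um, thickness %.1f um, r1 %.3f, r2 %.3f\n",
              x$length_um, x$thickness_um, x$r1, x$r2))
  invisible(x)
}
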