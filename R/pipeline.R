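# End-to-end orchestration: image -> regions -> features ->
# classification -> report, plus review export / correction re-import.

#' Run configuration for the plate pipeline
#'
#' Config precedence in the command-line driver is flags > config file >
#' these defaults; the effective configuration is echoed into every
#' report for provenance.
#'
#' @param um_per_pixel Calibration (default 6.5).
#' @param window_um,offset Adaptive threshold parameters ([binarize()]).
#' @param dark_foreground Worms darker than background (default `TRUE`).
#' @param filter A [region_filter_config()].
#' @param probe A [tail_probe_config()].
#' @param model A fitted `worm_model`, or `NULL` to fit from
#'   `training_csv`.
#' @param training_csv Path to a training table; ignored when `model`
#'   is given. Defaults to the shipped synthetic table.
#' @return A `run_config` object.
#' @export
run_config <- function(um_per_pixel = 6.5, window_um = 300, offset = 0.02,
                       dark_foreground = TRUE,
                       filter = region_filter_config(),
                       probe = tail_probe_config(),
                       model = NULL, training_csv = NULL) {
  check_number(um_per_pixel, "um_per_pixel", lower = 1e-6)
  if (is.null(model)) {
    training <- if (is.null(training_csv)) default_training_table()
                else read_training_csv(training_csv)
    model <- fit_training(training)
  }
  structure(list(um_per_pixel = um_per_pixel, window_um = window_um,
                 offset = offset, dark_foreground = dark_foreground,
                 filter = filter, probe = probe, model = model),
            class = "run_config")
}

#' Analyse one plate image in memory
#'
#' @param image A [as_worm_image()] object.
#' @param cfg A [run_config()].
#' @return A `plate_report` (see [classify_plate()]) extended with the
#'   region table and a config echo.
#' @export
analyze_plate <- function(image, cfg = run_config()) {
  mask <- binarize(image, window_um = cfg$window_um, offset = cfg$offset,
                   dark_foreground = cfg$dark_foreground)
  regions <- extract_regions(mask, cfg$filter)
  feats <- features_table(regions, cfg$probe)
  report <- classify_plate(feats, cfg$model)
  report$regions <- regions_table(regions)
  if (nrow(report$worms) > 0) {
    report$worms <- merge(report$regions[, c("region_id", "row0", "col0",
                                             "height", "width")],
                          report$worms, by = "region_id")
  }
  report$config <- list(um_per_pixel = cfg$um_per_pixel,
                        window_um = cfg$window_um, offset = cfg$offset,
                        dark_foreground = cfg$dark_foreground,
                        filter = unclass(cfg$filter),
                        probe = unclass(cfg$probe))
  report
}

#' Run the pipeline over one or more image files
#'
#' Failures on one image are recorded and do not abort the batch.
#'
#' @param paths Character vector of TIFF/PNG paths.
#' @param cfg A [run_config()].
#' @param out_dir Optional directory; when given, a per-image report
#'   JSON and per-worm CSV are written there.
#' @return Named list of `plate_report`s (or error records), one per
#'   image, plus a `summary` data frame of per-image counts.
#' @export
run_pipeline <- function(paths, cfg = run_config(), out_dir = NULL) {
  reports <- list()
  for (p in paths) {
    rep <- tryCatch({
      img <- read_plate_image(p, um_per_pixel = cfg$um_per_pixel)
      analyze_plate(img, cfg)
    }, error = function(e) {
      structure(list(error = conditionMessage(e), path = p),
                class = "plate_error")
    })
    reports[[basename(p)]] <- rep
    if (!is.null(out_dir) && !inherits(rep, "plate_error")) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      base <- tools::file_path_sans_ext(basename(p))
      write_report_json(rep, file.path(out_dir, paste0(base, "_report.json")))
      write.csv(rep$worms, file.path(out_dir, paste0(base, "_worms.csv")),
                row.names = FALSE)
    }
  }
  summary <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    if (inherits(r, "plate_error")) {
      data.frame(image = nm, hermaphrodite = NA_integer_, male = NA_integer_,
                 larva = NA_integer_, rejected = NA_integer_,
                 male_percentage = NA_real_, error = r$error)
    } else {
      data.frame(image = nm, hermaphrodite = r$counts[["hermaphrodite"]],
                 male = r$counts[["male"]], larva = r$counts[["larva"]],
                 rejected = sum(r$rejected),
                 male_percentage = r$male_percentage, error = NA_character_)
    }
  }))
  list(reports = reports, summary = summary)
}

#' Write a plate report as JSON
#'
#' @param report A `plate_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(counts = as.list(report$counts),
              rejected = as.list(report$rejected),
              male_percentage = report$male_percentage,
              worms = report$worms, config = report$config,
              version = report$version)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Fit a model from a training CSV and write it as JSON
#'
#' @param csv_path Training CSV (`class,length_um,thickness_um,r1,r2`).
#' @param model_path Output model JSON path.
#' @param cond_bound Ridge trigger passed to [fit_training()].
#' @return The fitted `worm_model`, invisibly.
#' @export
train_from_csv <- function(csv_path, model_path, cond_bound = 1e8) {
  model <- fit_training(read_training_csv(csv_path), cond_bound = cond_bound)
  write_model_json(model, model_path)
  invisible(model)
}

#' Export the lowest-margin classifications for manual review
#'
#' Replaces interactive inspection: the `k` worms whose nearest-class
#' margin is smallest (ties and ambiguous calls first) are exported with
#' their bounding boxes so a human can look them up in the image and
#' correct the label, then feed the edited table back through
#' [apply_corrections()].
#'
#' @param report A `plate_report` from [analyze_plate()].
#' @param k Number of worms to export; if larger than the worm count,
#'   all are exported.
#' @param path Optional CSV output path.
#' @return Data frame of the selected rows (lowest margin first) with a
#'   blank `corrected_label` column.
#' @export
export_review <- function(report, k, path = NULL) {
  w <- report$worms
  k <- min(k, nrow(w))
  sel <- w[order(w$margin), , drop = FALSE][seq_len(k), , drop = FALSE]
  sel$corrected_label <- rep("", nrow(sel))
  if (!is.null(path)) write.csv(sel, path, row.names = FALSE)
  sel
}

#' Re-import corrected labels and recompute plate counts
#'
#' @param report A `plate_report`.
#' @param corrections Data frame with `region_id` and `corrected_label`
#'   (rows with an empty or missing correction are ignored).
#' @return The report with labels replaced and counts / male percentage
#'   recomputed; total classified count is preserved.
#' @export
apply_corrections <- function(report, corrections) {
  if (!all(c("region_id", "corrected_label") %in% names(corrections))) {
    stop_invalid("corrections must have columns region_id, corrected_label")
  }
  w <- report$worms
  for (i in seq_len(nrow(corrections))) {
    lbl <- corrections$corrected_label[i]
    if (is.na(lbl) || !nzchar(lbl)) next
    if (!lbl %in% WORM_CLASSES) stop_invalid("unknown corrected label: ", lbl)
    j <- which(w$region_id == corrections$region_id[i])
    if (length(j) != 1L) stop_invalid("unknown region_id in corrections: ",
                                      corrections$region_id[i])
    w$label[j] <- lbl
  }
  report$worms <- w
  counts <- setNames(vapply(WORM_CLASSES, function(cl)
    sum(w$label == cl), 0L), WORM_CLASSES)
  adults <- counts[["male"]] + counts[["hermaphrodite"]]
  report$counts <- counts
  report$male_percentage <- if (adults > 0) 100 * counts[["male"]] / adults
                            else NA_real_
  report
}
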