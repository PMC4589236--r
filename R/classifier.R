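# Nearest-class Mahalanobis classifier over the four shape parameters.

WORM_CLASSES <- c("hermaphrodite", "male", "larva")
FEATURE_ORDER <- c("length_um", "thickness_um", "r1", "r2")
MODEL_SCHEMA <- "nemasex-model-1"

#' Fit per-class feature statistics from a labeled training table
#'
#' Computes, for each of the three classes, the sample mean vector and
#' unbiased sample covariance matrix over the fixed feature order
#' (length_um, thickness_um, r1, r2). Records are sorted by label and
#' then by feature values before fitting so the result is independent of
#' input order. A near-singular class covariance (condition number above
#' `cond_bound`) is regularised by adding the smallest ridge from a
#' doubling schedule that restores conditioning.
#'
#' @param records Data frame with columns `class` (one of
#'   `hermaphrodite`, `male`, `larva`) and the four feature columns.
#' @param cond_bound Condition-number bound that triggers ridge
#'   regularisation (default 1e8).
#' @return A `worm_model` with one entry per class: `mean`, `cov`
#'   (4 x 4), `n`, `ridge`, plus the shared `feature_order`.
#' @export
fit_training <- function(records, cond_bound = 1e8) {
  req <- c("class", FEATURE_ORDER)
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop_invalid("records must be a data frame with columns: ",
                 paste(req, collapse = ", "))
  }
  feats <- as.matrix(records[, FEATURE_ORDER])
  if (!is.numeric(feats)) stop_invalid("feature columns must be numeric")
  bad <- which(!apply(is.finite(feats), 1, all))
  if (length(bad) > 0L) {
    stop_invalid("non-finite feature values at record(s): ",
                 paste(head(bad, 5), collapse = ", "))
  }
  lab <- as.character(records$class)
  if (!all(lab %in% WORM_CLASSES)) {
    stop_invalid("unknown class label(s): ",
                 paste(unique(setdiff(lab, WORM_CLASSES)), collapse = ", "))
  }
  classes <- list()
  for (cl in WORM_CLASSES) {
    x <- feats[lab == cl, , drop = FALSE]
    if (nrow(x) < 5L) {
      stop_invalid("training requires >= 5 records for class '", cl,
                   "', got ", nrow(x))
    }
    x <- x[do.call(order, as.data.frame(x)), , drop = FALSE]
    mu <- colMeans(x)
    sigma <- cov(x)
    ridge <- 0
    base <- mean(diag(sigma))
    if (base <= 0) base <- 1
    step <- base * 1e-10
    while (cond_number(sigma + ridge * diag(4)) > cond_bound) {
      ridge <- if (ridge == 0) step else ridge * 2
    }
    classes[[cl]] <- list(label = cl, mean = mu, cov = sigma,
                          n = nrow(x), ridge = ridge)
  }
  structure(list(classes = classes, feature_order = FEATURE_ORDER,
                 schema = MODEL_SCHEMA),
            class = "worm_model")
}

cond_number <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(Inf)
  max(ev) / min(ev)
}

as_feature_vector <- function(x) {
  if (inherits(x, "worm_features")) {
    v <- c(x$length_um, x$thickness_um, x$r1, x$r2)
  } else if (is.numeric(x) && length(x) == 4L) {
    v <- as.numeric(x)
  } else {
    stop_invalid("x must be a worm_features object or a numeric 4-vector ",
                 "in order (length_um, thickness_um, r1, r2)")
  }
  if (!all(is.finite(v))) stop_invalid("feature vector contains non-finite values")
  v
}

#' Mahalanobis distance from a feature vector to a class model
#'
#' `sqrt((x - mu)' (Sigma + ridge I)^{-1} (x - mu))`, evaluated by a
#' Cholesky solve of the linear system (no explicit matrix inverse).
#'
#' @param x A `worm_features` object or numeric 4-vector in the model's
#'   feature order.
#' @param cm One class entry of a [fit_training()] model.
#' @return Non-negative distance; 0 iff `x` equals the class mean.
#' @export
mahalanobis_distance <- function(x, cm) {
  v <- as_feature_vector(x)
  d <- v - cm$mean
  sigma <- cm$cov + cm$ridge * diag(length(d))
  ch <- chol(sigma)
  y <- backsolve(ch, d, transpose = TRUE)
  sqrt(sum(y^2))
}

#' Assign a worm to the nearest class by Mahalanobis distance
#'
#' Distances to all three class models are computed and the label with
#' the smallest distance assigned. Exact ties are broken in the fixed
#' order hermaphrodite, male, larva and flagged in the result.
#'
#' @param x A `worm_features` object or numeric 4-vector.
#' @param model A `worm_model` from [fit_training()].
#' @return A `worm_classification`: `label`, named `distances`, `margin`
#'   (second-smallest minus smallest distance) and `tie` flag.
#' @export
classify <- function(x, model) {
  if (!inherits(model, "worm_model")) stop_invalid("model must be a worm_model")
  d <- vapply(model$classes[WORM_CLASSES], function(cm)
    mahalanobis_distance(x, cm), 0)
  names(d) <- WORM_CLASSES
  i <- which(d == min(d))
  tie <- length(i) > 1L
  label <- WORM_CLASSES[min(i)]
  sorted <- sort(d)
  structure(list(label = label, distances = d,
                 margin = unname(sorted[2] - sorted[1]), tie = tie),
            class = "worm_classification")
}

#' Classify a plate's worth of extracted features
#'
#' @param features Data frame from [features_table()] (columns
#'   `region_id`, features, `status`) or a list of `worm_features` /
#'   [worm_rejection()] values.
#' @param model A `worm_model`.
#' @return A `plate_report`: per-class `counts`, `rejected` tallies by
#'   reason, `male_percentage` (`NA` when no adults were classified;
#'   larvae are excluded from the denominator), and a per-worm data
#'   frame `worms` with labels, distances, margins and tie flags.
#' @export
classify_plate <- function(features, model) {
  if (is.data.frame(features)) {
    feats <- features
  } else {
    feats <- do.call(rbind, lapply(features, function(f) {
      if (is_rejection(f)) {
        data.frame(region_id = f$region_id, length_um = NA_real_,
                   thickness_um = NA_real_, r1 = NA_real_, r2 = NA_real_,
                   status = f$reason)
      } else {
        data.frame(region_id = f$region_id, length_um = f$length_um,
                   thickness_um = f$thickness_um, r1 = f$r1, r2 = f$r2,
                   status = "ok")
      }
    }))
    if (is.null(feats)) feats <- features_table(list())
  }
  rej_reasons <- c("branched", "too_short", "degenerate")
  rejected <- setNames(integer(3), rej_reasons)
  rows <- list()
  for (i in seq_len(nrow(feats))) {
    st <- feats$status[i]
    if (!identical(st, "ok")) {
      if (st %in% rej_reasons) rejected[st] <- rejected[st] + 1L
      next
    }
    cl <- classify(as.numeric(feats[i, FEATURE_ORDER]), model)
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = feats$region_id[i], label = cl$label,
      length_um = feats$length_um[i], thickness_um = feats$thickness_um[i],
      r1 = feats$r1[i], r2 = feats$r2[i],
      dist_hermaphrodite = cl$distances[["hermaphrodite"]],
      dist_male = cl$distances[["male"]],
      dist_larva = cl$distances[["larva"]],
      margin = cl$margin, tie_flag = cl$tie)
  }
  worms <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = integer(), label = character(),
               length_um = numeric(), thickness_um = numeric(),
               r1 = numeric(), r2 = numeric(),
               dist_hermaphrodite = numeric(), dist_male = numeric(),
               dist_larva = numeric(), margin = numeric(),
               tie_flag = logical())
  counts <- setNames(vapply(WORM_CLASSES, function(cl)
    sum(worms$label == cl), 0L), WORM_CLASSES)
  adults <- counts[["male"]] + counts[["hermaphrodite"]]
  male_pct <- if (adults > 0) 100 * counts[["male"]] / adults else NA_real_
  structure(list(counts = counts, rejected = rejected,
                 male_percentage = male_pct, worms = worms,
                 version = as.character(packageVersion("nemasex"))),
            class = "plate_report")
}

#' @export
print.plate_report <- function(x, ...) {
  cat("<plate_report>\n  counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
      "\n  rejected:",
      paste(names(x$rejected), x$rejected, sep = "=", collapse = ", "),
      "\n  male %:",
      if (is.na(x$male_percentage)) "undefined (no adults)"
      else sprintf("%.2f", x$male_percentage), "\n")
  invisible(x)
}

#' Read a training table from CSV
#'
#' Expected header: `class,length_um,thickness_um,r1,r2`.
#'
#' @param path CSV path.
#' @return Data frame validated against the schema, with row numbers
#'   reported for non-numeric feature cells.
#' @export
read_training_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("training CSV not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("class", FEATURE_ORDER)
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_invalid("training CSV missing column(s): ",
                                 paste(miss, collapse = ", "))
  for (col in FEATURE_ORDER) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop_invalid("non-numeric value in column '", col, "' at row(s): ",
                   paste(head(bad, 5), collapse = ", "))
    }
    df[[col]] <- v
  }
  df
}

#' The default synthetic training table shipped with the package
#'
#' A 131-row table (46 hermaphrodites, 46 males, 39 larvae) of shape
#' features measured by this package's own morphometry on rendered
#' synthetic worms. It mirrors the class structure of a real default
#' training set; replace it with features from your own imaging
#' conditions for real plates.
#'
#' @return Training data frame.
#' @export
default_training_table <- function() {
  read_training_csv(system.file("extdata", "training_synthetic.csv",
                                package = "nemasex", mustWork = TRUE))
}

#' Write / read a fitted model as versioned JSON
#'
#' @param model A `worm_model`.
#' @param path Output JSON path.
#' @return `path` (write) or a `worm_model` (read).
#' @export
write_model_json <- function(model, path) {
  if (!inherits(model, "worm_model")) stop_invalid("model must be a worm_model")
  out <- list(schema = MODEL_SCHEMA, feature_order = model$feature_order,
              classes = lapply(model$classes, function(cm) {
                list(label = cm$label, n = cm$n, mean = unname(cm$mean),
                     covariance = unname(cm$cov), ridge = cm$ridge)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_invalid("model file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$schema, MODEL_SCHEMA)) {
    stop_invalid("unsupported model schema: ", raw$schema)
  }
  classes <- lapply(WORM_CLASSES, function(cl) {
    cm <- raw$classes[[cl]]
    list(label = cl, mean = setNames(as.numeric(cm$mean), FEATURE_ORDER),
         cov = matrix(as.numeric(cm$covariance), 4, 4,
                      dimnames = list(FEATURE_ORDER, FEATURE_ORDER)),
         n = as.integer(cm$n), ridge = as.numeric(cm$ridge))
  })
  names(classes) <- WORM_CLASSES
  structure(list(classes = classes, feature_order = FEATURE_ORDER,
                 schema = MODEL_SCHEMA),
            class = "worm_model")
}
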