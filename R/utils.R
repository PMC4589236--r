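# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("nemasex_invalid", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_invalid(name, " must be a finite number in [", lower, ", ", upper, "]")
  }
  as.numeric(x)
}

#' Create a typed rejection value
#'
#' Regions that cannot be measured (clumped/coiled animals whose skeleton
#' branches, objects too short to probe at the outer tail position, or
#' degenerate skeletons) are reported as rejection values rather than
#' errors, so a plate run can tally them per reason.
#'
#' @param reason One of `"branched"`, `"too_short"`, `"degenerate"`.
#' @param region_id Optional identifier of the offending region.
#' @return An object of class `worm_rejection`.
#' @export
worm_rejection <- function(reason, region_id = NA_integer_) {
  reason <- match.arg(reason, c("branched", "too_short", "degenerate"))
  structure(list(reason = reason, region_id = region_id),
            class = "worm_rejection")
}

#' Test for a rejection value
#' @param x Object to test.
#' @return `TRUE` if `x` is a [worm_rejection()].
#' @export
is_rejection <- function(x) inherits(x, "worm_rejection")

#' @export
print.worm_rejection <- function(x, ...) {
  cat("<worm_rejection>", x$reason,
      if (!is.na(x$region_id)) paste0("(region ", x$region_id, ")"), "\n")
  invisible(x)
}
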