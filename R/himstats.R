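# Sex-ratio statistics: chi-square him screen over strain count tables
# and manual-versus-automatic agreement analyses.

#' Construct a strain count record
#'
#' Published count tables report male percentage and total animals per
#' strain; the male count is reconstructed by nearest-integer rounding
#' of `male_pct * n / 100`.
#'
#' @param strain Genotype string.
#' @param male_pct Male percentage (0-100).
#' @param n Total number of animals (> 0).
#' @param source `"automatic"` or `"manual"`.
#' @return A `strain_counts` object with the reconstructed `males`.
#' @export
strain_counts <- function(strain, male_pct, n, source = c("automatic", "manual")) {
  source <- match.arg(source)
  check_number(male_pct, "male_pct", lower = 0, upper = 100)
  check_number(n, "n", lower = 1)
  males <- round(male_pct * n / 100)
  structure(list(strain = as.character(strain), male_pct = male_pct,
                 n = as.integer(n), males = as.integer(males),
                 source = source),
            class = "strain_counts")
}

#' Chi-square comparison of a strain's sex ratio against a reference
#'
#' Builds the 2x2 contingency table (male vs non-male, strain vs
#' reference) from reconstructed counts and applies Pearson's chi-square
#' test with 1 degree of freedom. Continuity correction is off by
#' default: at the sample sizes of pooled plate counts it is immaterial,
#' and the uncorrected statistic is the conventional screen.
#'
#' @param test,ref [strain_counts()] records.
#' @param alpha Significance threshold (default 1e-4).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `p_value`, `significant`.
#' @export
chi_square_vs_reference <- function(test, ref, alpha = 1e-4, correct = FALSE) {
  stopifnot(inherits(test, "strain_counts"), inherits(ref, "strain_counts"))
  tab <- rbind(c(test$males, test$n - test$males),
               c(ref$males, ref$n - ref$males))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    stop_invalid("chi-square undefined: zero margin in the 2x2 table")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       significant = unname(ht$p.value) < alpha)
}

#' Screen a strain table for the him phenotype
#'
#' Applies [chi_square_vs_reference()] to every non-reference strain
#' against the reference (wild-type) row and returns the strains whose
#' male percentage differs at `p < alpha`.
#'
#' @param table Data frame with columns `strain`, `male_pct`, `n`.
#' @param ref_label Reference strain name (default `"wild-type"`).
#' @param source Count source recorded on the rows.
#' @param alpha Significance threshold (default 1e-4).
#' @return Data frame of all non-reference strains sorted by name, with
#'   `statistic`, `p_value` and logical `flagged`.
#' @export
him_screen <- function(table, ref_label = "wild-type",
                       source = c("automatic", "manual"), alpha = 1e-4) {
  source <- match.arg(source)
  req <- c("strain", "male_pct", "n")
  if (!is.data.frame(table) || !all(req %in% names(table))) {
    stop_invalid("table must have columns: ", paste(req, collapse = ", "))
  }
  iref <- which(table$strain == ref_label)
  if (length(iref) != 1L) {
    stop_invalid("reference strain '", ref_label,
                 "' must appear exactly once in the table")
  }
  ref <- strain_counts(ref_label, table$male_pct[iref], table$n[iref], source)
  rest <- table[-iref, , drop = FALSE]
  rest <- rest[order(rest$strain), , drop = FALSE]
  if (nrow(rest) == 0L) {
    return(data.frame(strain = character(), male_pct = numeric(),
                      n = numeric(), statistic = numeric(),
                      p_value = numeric(), flagged = logical()))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(rest)), function(i) {
    sc <- strain_counts(rest$strain[i], rest$male_pct[i], rest$n[i], source)
    ht <- chi_square_vs_reference(sc, ref, alpha = alpha)
    data.frame(strain = sc$strain, male_pct = sc$male_pct, n = sc$n,
               statistic = ht$statistic, p_value = ht$p_value,
               flagged = ht$significant)
  }))
  rownames(res) <- NULL
  res
}

#' Manual-versus-automatic agreement across strains
#'
#' @param auto,manual Data frames with columns `strain`, `male_pct`
#'   covering the same strain set (the reference row included).
#' @return List with `pearson_r`, `max_abs_diff_pct` (full precision),
#'   `max_abs_diff_2sf` (rounded to 2 significant figures) and
#'   `max_diff_strain`.
#' @export
agreement_summary <- function(auto, manual) {
  m <- merge(auto[, c("strain", "male_pct")], manual[, c("strain", "male_pct")],
             by = "strain", suffixes = c("_auto", "_manual"))
  if (nrow(m) < 3L) stop_invalid("need at least 3 matched strains")
  if (nrow(m) < nrow(auto) || nrow(m) < nrow(manual)) {
    stop_invalid("strain sets do not match between sources")
  }
  diffs <- abs(m$male_pct_auto - m$male_pct_manual)
  i <- which.max(diffs)
  list(pearson_r = cor(m$male_pct_auto, m$male_pct_manual),
       max_abs_diff_pct = diffs[i],
       max_abs_diff_2sf = signif(diffs[i], 2),
       max_diff_strain = m$strain[i])
}

#' Per-well error analysis of automatic counting
#'
#' For each well, the male percentage is computed from manual and from
#' automatic counts (wells with no adults in a source are dropped for
#' the correlations involving that source's percentage). The absolute
#' error is the difference in percentage points between the two.
#'
#' @param wells Data frame with columns `well_id, manual_male,
#'   manual_herm, auto_male, auto_herm`.
#' @param min_animals Wells with fewer manual animals than this are
#'   excluded from the error-versus-male-percentage correlation
#'   (default 10), since tiny wells make that relation degenerate.
#' @return List with `r_sexratio` (manual vs automatic male %),
#'   `pct_cases_error_lt_10` (share of wells with error < 10 points),
#'   `r_error_vs_malepct_filtered`, `r_error_vs_total` and `n_wells`
#'   actually used.
#' @export
error_analysis <- function(wells, min_animals = 10) {
  req <- c("well_id", "manual_male", "manual_herm", "auto_male", "auto_herm")
  if (!is.data.frame(wells) || !all(req %in% names(wells)) || nrow(wells) == 0) {
    stop_invalid("wells must be a non-empty data frame with columns: ",
                 paste(req, collapse = ", "))
  }
  man_tot <- wells$manual_male + wells$manual_herm
  aut_tot <- wells$auto_male + wells$auto_herm
  ok <- man_tot > 0 & aut_tot > 0
  if (!any(ok)) stop_invalid("no well has adults in both sources")
  man_pct <- 100 * wells$manual_male[ok] / man_tot[ok]
  aut_pct <- 100 * wells$auto_male[ok] / aut_tot[ok]
  err <- abs(man_pct - aut_pct)
  keep <- man_tot[ok] >= min_animals
  # a constant error vector (e.g. perfect agreement) has no correlation
  safe_cor <- function(x, y) {
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  list(r_sexratio = safe_cor(man_pct, aut_pct),
       pct_cases_error_lt_10 = 100 * mean(err < 10),
       r_error_vs_malepct_filtered = safe_cor(err[keep], man_pct[keep]),
       r_error_vs_total = safe_cor(err, man_tot[ok]),
       n_wells = sum(ok))
}

#' The bundled strain count table (automatic and manual counts)
#'
#' Per-strain male percentages and total animal counts for wild-type and
#' 27 him-candidate mutants, measured both automatically and manually.
#'
#' @return Data frame with columns `strain, auto_male_pct, auto_n,
#'   manual_male_pct, manual_n`.
#' @export
strain_table <- function() {
  read.csv(system.file("extdata", "table2.csv", package = "nemasex",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Read a per-well raw count table (CSV)
#'
#' Column mapping: `well_id`, `manual_male`, `manual_herm`, `auto_male`,
#' `auto_herm`. Extra columns are ignored.
#'
#' @param path CSV path.
#' @return Data frame suitable for [error_analysis()].
#' @export
read_well_records <- function(path) {
  if (!file.exists(path)) stop_invalid("well record file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("well_id", "manual_male", "manual_herm", "auto_male", "auto_herm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_invalid("well table missing column(s): ",
                                 paste(miss, collapse = ", "))
  df[, req]
}

#' Full him-screen report over a two-source strain table
#'
#' @param table Data frame as returned by [strain_table()].
#' @param alpha Significance threshold (default 1e-4).
#' @return List with per-source screen results, flagged strain names,
#'   and the agreement summary.
#' @export
him_report <- function(table, alpha = 1e-4) {
  auto <- data.frame(strain = table$strain, male_pct = table$auto_male_pct,
                     n = table$auto_n)
  manual <- data.frame(strain = table$strain, male_pct = table$manual_male_pct,
                       n = table$manual_n)
  scr_a <- him_screen(auto, alpha = alpha, source = "automatic")
  scr_m <- him_screen(manual, alpha = alpha, source = "manual")
  list(automatic = scr_a, manual = scr_m,
       flagged_automatic = scr_a$strain[scr_a$flagged],
       flagged_manual = scr_m$strain[scr_m$flagged],
       agreement = agreement_summary(auto, manual),
       alpha = alpha)
}
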