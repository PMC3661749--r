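#' Combine species metadata and assessments into fauna records
#'
#' Joins a metadata table to an assessment table by `species_id`. Records
#' flagged `excluded` are retained in the output but skipped by every tally
#' and correlation (extinct, extirpated, or taxonomically ambiguous species
#' are excluded from analysis, not from the record).
#'
#' @param metadata Data frame with columns `species_id`, `origin`
#'   (`"native"`/`"alien"`), `family`, and optionally `name`, `anadromous`,
#'   `external_status` (a 1.0--5.0 status score from an independent
#'   assessment), `excluded` (logical), `exclusion_reason`.
#' @param assessments Data frame as returned by [assess_sheets()].
#' @return Data frame of class `vuln_records`.
#' @export
fauna_records <- function(metadata, assessments) {
  req <- c("species_id", "origin", "family")
  if (!all(req %in% names(metadata)))
    stop("metadata: missing column(s): ",
         paste(setdiff(req, names(metadata)), collapse = ", "), call. = FALSE)
  if (!all(metadata$origin %in% c("native", "alien")))
    stop("metadata: origin must be 'native' or 'alien'", call. = FALSE)
  if (is.null(metadata$excluded)) metadata$excluded <- FALSE
  metadata$excluded <- isTRUE_vec(metadata$excluded)
  if (is.null(metadata$external_status))
    metadata$external_status <- NA_real_
  if (is.null(metadata$anadromous)) metadata$anadromous <- NA
  miss <- setdiff(metadata$species_id[!metadata$excluded],
                  assessments$species_id)
  if (length(miss))
    stop("no assessment for species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- merge(metadata, assessments, by = "species_id", all.x = TRUE)
  class(out) <- c("vuln_records", "data.frame")
  out
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == "true" | x == 1)

active_records <- function(records) {
  records[!records$excluded, , drop = FALSE]
}

record_fields <- function(module) {
  module <- match.arg(module, MODULE_NAMES)
  if (module == "baseline")
    list(total = "v_b", cert = "certainty_b", cat = "category_b",
         ord = "ordinal_b")
  else
    list(total = "v_c", cert = "certainty_c", cat = "category_c",
         ord = "ordinal_c")
}

#' Tally species counts by vulnerability category
#'
#' Counts non-excluded records per category band of one module, optionally
#' split by origin. Counts are exhaustive and mutually exclusive: they sum to
#' the number of non-excluded records (per origin).
#'
#' @param records A `vuln_records` table.
#' @param rubric The `vuln_rubric` the assessments were made under.
#' @param module `"baseline"` or `"climate"`.
#' @param by_origin Split counts into native/alien columns?
#' @return Named integer vector of band counts (band order, most vulnerable
#'   first), or a bands x origin matrix when `by_origin = TRUE`.
#' @export
tally_by_category <- function(records, rubric, module, by_origin = FALSE) {
  mod <- get_module(rubric, module)
  f <- record_fields(module)
  rec <- active_records(records)
  cat <- factor(rec[[f$cat]], levels = mod$bands$label)
  if (any(is.na(cat)))
    stop("records contain categories not present in this rubric module ",
         "(mixed-rubric records?)", call. = FALSE)
  if (by_origin)
    table(band = cat, origin = factor(rec$origin, c("native", "alien")))
  else
    c(table(cat))
}

#' Percentage of species in a subset of categories
#'
#' @param counts Named vector of band counts (as from [tally_by_category()]).
#' @param bands Character vector naming the subset of bands.
#' @return List with `exact` (the unrounded percentage) and `display` (the
#'   integer percentage, rounded half away from zero).
#' @examples
#' counts <- c(`Critically vulnerable` = 16, `Highly vulnerable` = 45,
#'             `Less vulnerable` = 47, `Least vulnerable` = 13)
#' percent_in_bands(counts, c("Critically vulnerable", "Highly vulnerable"))
#' @export
percent_in_bands <- function(counts, bands) {
  if (!length(counts) || sum(counts) == 0)
    stop("percent_in_bands: zero total count", call. = FALSE)
  unknown <- setdiff(bands, names(counts))
  if (length(unknown))
    stop("unknown band(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  exact <- 100 * sum(counts[bands]) / sum(counts)
  list(exact = exact, display = round_half_away(exact))
}

#' Mean and standard deviation of module totals by origin
#'
#' @inheritParams tally_by_category
#' @return Data frame with one row per origin: `origin`, `n`, `mean`, `sd`.
#' @export
origin_summary <- function(records, rubric, module) {
  f <- record_fields(module)
  rec <- active_records(records)
  out <- do.call(rbind, lapply(c("native", "alien"), function(o) {
    x <- rec[[f$total]][rec$origin == o]
    data.frame(origin = o, n = length(x), mean = mean(x), sd = stats::sd(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-family vulnerability breakdown
#'
#' One row per family with taxon count, integer percent native, and per-band
#' counts with integer percentages (rounded half away from zero; percentages
#' within a row sum to 100 up to integer rounding).
#'
#' @inheritParams tally_by_category
#' @return Data frame: `family`, `n`, `pct_native`, then `n_<band>` and
#'   `pct_<band>` column pairs in band order.
#' @export
family_breakdown <- function(records, rubric, module) {
  mod <- get_module(rubric, module)
  f <- record_fields(module)
  rec <- active_records(records)
  if (any(is.na(rec$family) | rec$family == ""))
    stop("family missing on one or more records", call. = FALSE)
  fams <- sort(unique(rec$family))
  rows <- lapply(fams, function(fam) {
    sub <- rec[rec$family == fam, , drop = FALSE]
    cat <- factor(sub[[f$cat]], levels = mod$bands$label)
    counts <- c(table(cat))
    pcts <- round_half_away(100 * counts / nrow(sub))
    row <- data.frame(family = fam, n = nrow(sub),
                      pct_native = round_half_away(
                        100 * mean(sub$origin == "native")),
                      stringsAsFactors = FALSE)
    for (b in seq_along(counts)) {
      key <- gsub("[^a-z]+", "_", tolower(names(counts)[b]))
      row[[paste0("n_", key)]] <- unname(counts[b])
      row[[paste0("pct_", key)]] <- unname(pcts[b])
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with average ranks
#'
#' Rank correlation between two score vectors, with ties handled by average
#' ranks. P-values use the t approximation by default; for `n <= 10` an
#' exact permutation p-value is available.
#'
#' @param x,y Numeric vectors of equal length (at least 3). A constant vector
#'   leaves the coefficient undefined and is an error, never reported as 0.
#' @param labels Length-2 character vector naming the pair.
#' @param p_method `"t"` (approximation) or `"exact"` (full permutation,
#'   only for `n <= 10`).
#' @return Data frame of class `vuln_cor`: `pair`, `coefficient`, `n`,
#'   `p_value`, `method`.
#' @examples
#' rank_correlation(c(1, 2, 3), c(3, 1, 2))  # rho = -0.5
#' @export
rank_correlation <- function(x, y, labels = c("x", "y"), p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y))
    stop("rank_correlation: length mismatch", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("rank_correlation: need at least 3 complete pairs",
                   call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank_correlation: constant vector, coefficient undefined",
         call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (p_method == "exact") {
    if (n > 10L) stop("exact permutation p-value limited to n <= 10",
                      call. = FALSE)
    perms <- permutations(n)
    rx <- rank(x); ry <- rank(y)
    obs <- abs(stats::cor(rx, ry))
    mean(apply(perms, 1, function(p) abs(stats::cor(rx, ry[p]))) >= obs - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(data.frame(pair = paste(labels, collapse = " vs "),
                       coefficient = rho, n = n, p_value = p,
                       method = paste0("spearman/", p_method),
                       stringsAsFactors = FALSE),
            class = c("vuln_cor", "data.frame"))
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Correlation between the two vulnerability scores
#'
#' Spearman rank correlation of baseline (Vb) against climate (Vc) totals
#' over non-excluded records.
#'
#' @param records A `vuln_records` table.
#' @return A `vuln_cor` row.
#' @export
vb_vc_correlation <- function(records) {
  rec <- active_records(records)
  rank_correlation(rec$v_b, rec$v_c, labels = c("Vb", "Vc"))
}

#' Correlation of vulnerability scores with an external status score
#'
#' Compares both module totals against an independent status score (e.g. a
#' seven-metric conservation status rating on a 1.0--5.0 scale), over records
#' that carry one.
#'
#' @param records A `vuln_records` table with `external_status` on at least
#'   3 non-excluded records.
#' @return Data frame with two `vuln_cor` rows (Vb and Vc vs external).
#' @export
compare_external_status <- function(records) {
  rec <- active_records(records)
  rec <- rec[!is.na(rec$external_status), , drop = FALSE]
  if (nrow(rec) < 3L)
    stop("external status present on fewer than 3 records", call. = FALSE)
  rbind(
    rank_correlation(rec$v_b, rec$external_status,
                     labels = c("Vb", "external status")),
    rank_correlation(rec$v_c, rec$external_status,
                     labels = c("Vc", "external status"))
  )
}

#' Correlation between module totals and their certainty totals
#'
#' @param records A `vuln_records` table.
#' @param module `"baseline"` or `"climate"`.
#' @return A `vuln_cor` row (total vs certainty total for the module).
#' @export
certainty_vs_score <- function(records, module) {
  f <- record_fields(module)
  rec <- active_records(records)
  rank_correlation(rec[[f$total]], rec[[f$cert]],
                   labels = c(paste0(get_module_prefix(module)),
                              "certainty"))
}

get_module_prefix <- function(module) {
  if (match.arg(module, MODULE_NAMES) == "baseline") "Vb" else "Vc"
}

#' Metric-redundancy correlation matrix
#'
#' Pearson correlation matrix of per-metric point scores across species (one
#' sheet per species), computed per module and pooled over all 20 metrics,
#' with the fraction of unordered off-diagonal pairs whose correlation meets
#' each threshold. Metrics with zero variance across species are excluded
#' from the fractions with a warning.
#'
#' @param sheets List of `vuln_sheet` objects, one per species (at least 3).
#' @param rubric A `vuln_rubric`.
#' @param thresholds Correlation thresholds for the redundancy fractions.
#' @return List with `matrices` (named list `baseline`, `climate`, `pooled`)
#'   and `fractions` (data frame: `scope`, `threshold`, `fraction`,
#'   `n_pairs`).
#' @export
metric_correlation_matrix <- function(sheets, rubric, thresholds = c(0.5, 0.7)) {
  if (length(sheets) < 3L)
    stop("metric correlation: need at least 3 species", call. = FALSE)
  species <- vapply(sheets, attr, character(1), "species_id")
  if (anyDuplicated(species))
    stop("metric correlation: one sheet per species required", call. = FALSE)
  pts <- points_matrix(sheets, rubric)
  scopes <- list(
    baseline = pts[, grep_metric_cols(rubric, "baseline"), drop = FALSE],
    climate  = pts[, grep_metric_cols(rubric, "climate"), drop = FALSE],
    pooled   = pts
  )
  matrices <- list(); fr <- list()
  for (sc in names(scopes)) {
    m <- scopes[[sc]]
    const <- apply(m, 2, stats::sd) == 0
    if (any(const)) {
      warning(sprintf("%s: constant metric column(s) excluded: %s", sc,
                      paste(colnames(m)[const], collapse = ", ")),
              call. = FALSE)
      m <- m[, !const, drop = FALSE]
    }
    cm <- stats::cor(m)
    matrices[[sc]] <- cm
    off <- cm[upper.tri(cm)]
    fr[[sc]] <- data.frame(scope = sc, threshold = thresholds,
                           fraction = vapply(thresholds, function(t)
                             mean(off >= t), numeric(1)),
                           n_pairs = length(off), stringsAsFactors = FALSE)
  }
  list(matrices = matrices,
       fractions = { out <- do.call(rbind, fr); rownames(out) <- NULL; out })
}

grep_metric_cols <- function(rubric, module) {
  vapply(get_module(rubric, module)$metrics, `[[`, character(1), "id")
}

# species x metric matrix of best-estimate points
points_matrix <- function(sheets, rubric) {
  metric_defs <- unlist(lapply(rubric$modules, `[[`, "metrics"),
                        recursive = FALSE)
  ids <- vapply(metric_defs, `[[`, character(1), "id")
  m <- t(vapply(sheets, function(s) {
    vapply(seq_along(metric_defs), function(i) {
      code <- s$best[s$metric_id == ids[i]]
      as.numeric(level_points(metric_defs[[i]], code))
    }, numeric(1))
  }, numeric(length(ids))))
  dimnames(m) <- list(vapply(sheets, attr, character(1), "species_id"), ids)
  m
}

#' Full faunal summary
#'
#' Rolls a record table up into the standard report: per-module band tallies
#' by origin, headline percentages, origin means, and family tables.
#'
#' @param records A `vuln_records` table.
#' @param rubric A `vuln_rubric`.
#' @return List of class `fauna_summary` with elements `n`, `tallies`,
#'   `percentages`, `origin_means`, `families`.
#' @export
fauna_summary <- function(records, rubric) {
  rec <- active_records(records)
  out <- list(n = c(native = sum(rec$origin == "native"),
                    alien = sum(rec$origin == "alien")))
  out$tallies <- lapply(stats::setNames(MODULE_NAMES, MODULE_NAMES),
                        function(m) tally_by_category(records, rubric, m,
                                                      by_origin = TRUE))
  vulnerable2 <- c("Critically vulnerable", "Highly vulnerable")
  pct <- function(module, origin, bands) {
    t2 <- out$tallies[[module]][, origin]
    percent_in_bands(t2, bands)$display
  }
  out$percentages <- data.frame(
    quantity = c("native baseline critical+high", "native climate critical+high",
                 "alien climate high", "alien climate any vulnerability"),
    percent = c(pct("baseline", "native", vulnerable2),
                pct("climate", "native", vulnerable2),
                pct("climate", "alien", "Highly vulnerable"),
                pct("climate", "alien",
                    c(vulnerable2, "Less vulnerable", "Least vulnerable"))),
    stringsAsFactors = FALSE)
  out$origin_means <- lapply(stats::setNames(MODULE_NAMES, MODULE_NAMES),
                             function(m) origin_summary(records, rubric, m))
  out$families <- lapply(stats::setNames(MODULE_NAMES, MODULE_NAMES),
                         function(m) family_breakdown(records, rubric, m))
  class(out) <- "fauna_summary"
  out
}

#' @export
print.fauna_summary <- function(x, ...) {
  cat(sprintf("<fauna_summary> %d native, %d alien species\n",
              x$n["native"], x$n["alien"]))
  for (m in names(x$tallies)) {
    cat("  ", m, "tallies:\n")
    print(x$tallies[[m]])
  }
  print(x$percentages)
  invisible(x)
}
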