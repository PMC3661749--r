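#' Build a validated score sheet
#'
#' A score sheet is one reviewer's complete set of 20 metric scores for one
#' species: per metric a best-estimate level, an optional alternate level
#' (omitted when the best estimate is held with high certainty), and a
#' certainty score in 1--3. Every metric of both modules must be scored
#' exactly once; missing or duplicate metrics are a hard error, never imputed.
#'
#' @param species_id Species identifier (opaque string; subspecies/ESU/DPS
#'   qualifiers allowed verbatim).
#' @param reviewer_id Reviewer identifier.
#' @param scores Data frame with columns `metric_id`, `best` (level code),
#'   `alternate` (level code or `NA`), `certainty` (integer 1--3).
#' @param rubric A `vuln_rubric` to validate against.
#' @return An object of class `vuln_sheet`: the scores data frame (ordered as
#'   in the rubric) with `species_id` and `reviewer_id` attributes.
#' @export
score_sheet <- function(species_id, reviewer_id, scores, rubric) {
  stopifnot(inherits(rubric, "vuln_rubric"))
  req <- c("metric_id", "best", "alternate", "certainty")
  if (!all(req %in% names(scores)))
    stop("score sheet: missing column(s): ",
         paste(setdiff(req, names(scores)), collapse = ", "), call. = FALSE)
  scores$metric_id <- as.character(scores$metric_id)
  scores$best      <- as.character(scores$best)
  scores$alternate <- as.character(scores$alternate)
  scores$certainty <- as.integer(scores$certainty)

  all_metrics <- unlist(lapply(rubric$modules, function(m)
    vapply(m$metrics, `[[`, character(1), "id")), use.names = FALSE)
  if (anyDuplicated(scores$metric_id))
    stop(sprintf("score sheet %s/%s: duplicate metric(s): %s",
                 species_id, reviewer_id,
                 paste(unique(scores$metric_id[duplicated(scores$metric_id)]),
                       collapse = ", ")), call. = FALSE)
  unknown <- setdiff(scores$metric_id, all_metrics)
  if (length(unknown))
    stop(sprintf("score sheet %s/%s: unknown metric(s): %s",
                 species_id, reviewer_id, paste(unknown, collapse = ", ")),
         call. = FALSE)
  missing <- setdiff(all_metrics, scores$metric_id)
  if (length(missing))
    stop(sprintf("score sheet %s/%s: missing metric(s): %s",
                 species_id, reviewer_id, paste(missing, collapse = ", ")),
         call. = FALSE)

  # per-metric level and certainty validation
  for (mod in rubric$modules) {
    for (m in mod$metrics) {
      row <- scores[scores$metric_id == m$id, ]
      if (!row$best %in% m$levels$code)
        stop(sprintf("score sheet %s/%s: metric %s: unknown best level '%s'",
                     species_id, reviewer_id, m$id, row$best), call. = FALSE)
      if (!is.na(row$alternate) && !row$alternate %in% m$levels$code)
        stop(sprintf(
          "score sheet %s/%s: metric %s: unknown alternate level '%s'",
          species_id, reviewer_id, m$id, row$alternate), call. = FALSE)
      if (is.na(row$certainty) || !row$certainty %in% 1:3)
        stop(sprintf("score sheet %s/%s: metric %s: certainty must be 1-3",
                     species_id, reviewer_id, m$id), call. = FALSE)
    }
  }
  scores <- scores[match(all_metrics, scores$metric_id),
                   req, drop = FALSE]
  rownames(scores) <- NULL
  structure(scores, species_id = as.character(species_id),
            reviewer_id = as.character(reviewer_id), class = c("vuln_sheet", "data.frame"))
}

# points of a level code within one metric definition
level_points <- function(metric, code) {
  i <- match(code, metric$levels$code)
  if (any(is.na(i) & !is.na(code)))
    stop(sprintf("metric %s: unknown level code '%s'", metric$id,
                 paste(code[is.na(i) & !is.na(code)], collapse = ", ")),
         call. = FALSE)
  metric$levels$points[i]
}

module_rows <- function(sheet, mod) {
  ids <- vapply(mod$metrics, `[[`, character(1), "id")
  sheet[match(ids, sheet$metric_id), , drop = FALSE]
}

#' Module total of the best-estimate scores
#'
#' @param sheet A `vuln_sheet`.
#' @param rubric A `vuln_rubric`.
#' @param module `"baseline"` or `"climate"`.
#' @return Integer: the sum of the points of the best-estimate level over the
#'   module's ten metrics (Vb for baseline, Vc for climate).
#' @export
total_best <- function(sheet, rubric, module) {
  mod <- get_module(rubric, module)
  rows <- module_rows(sheet, mod)
  sum(vapply(seq_along(mod$metrics), function(i)
    level_points(mod$metrics[[i]], rows$best[i]), numeric(1)))
}

#' Low/high module totals from best and alternate scores
#'
#' Per metric the low contribution is the smaller of the best and alternate
#' points and the high contribution the larger; a metric without an alternate
#' contributes its best points to both. The bounds bracket the best total:
#' `low <= total_best <= high`.
#'
#' @inheritParams total_best
#' @return Named integer vector `c(low, high)`.
#' @export
total_range <- function(sheet, rubric, module) {
  mod <- get_module(rubric, module)
  rows <- module_rows(sheet, mod)
  lo <- hi <- 0
  for (i in seq_along(mod$metrics)) {
    b <- level_points(mod$metrics[[i]], rows$best[i])
    a <- if (is.na(rows$alternate[i])) b
         else level_points(mod$metrics[[i]], rows$alternate[i])
    lo <- lo + min(b, a)
    hi <- hi + max(b, a)
  }
  c(low = lo, high = hi)
}

#' Module certainty total
#'
#' Sum of the ten per-metric certainty scores; ranges from 10 (highly
#' uncertain) to 30 (highly certain).
#'
#' @inheritParams total_best
#' @return Integer in 10--30.
#' @export
certainty_total <- function(sheet, rubric, module) {
  mod <- get_module(rubric, module)
  rows <- module_rows(sheet, mod)
  if (any(!rows$certainty %in% 1:3))
    stop("certainty scores must lie in {1, 2, 3}", call. = FALSE)
  sum(rows$certainty)
}

#' Names of the thirteen stressor-narrative categories
#'
#' The packaged default naming of the thirteen non-climate stressor
#' categories rated high/intermediate/low on the stressor narrative form that
#' feeds baseline metric `b6`. Any thirteen uniquely named ratings are
#' accepted by [score_stressors()]; these names are a convenience.
#' @return Character vector of length 13.
#' @export
stressor_categories <- function() {
  c("major dams", "agriculture", "grazing", "rural development",
    "urbanization", "instream mining", "transportation corridors", "logging",
    "fire", "recreation", "harvest", "hatcheries", "alien species")
}

#' Aggregate a stressor narrative into a baseline metric 6 level
#'
#' Collapses the thirteen high/intermediate/low stressor ratings into the
#' three-level score of baseline metric `b6`. The default rule: level `"1"`
#' (highly vulnerable) if at least `high_critical` stressors are rated high;
#' level `"2"` (vulnerable) if any stressor is high (but fewer than
#' `high_critical`) or at least `intermediate_vulnerable` are intermediate;
#' otherwise level `"3"` (low or no vulnerability). The thresholds are
#' configuration, not code.
#'
#' @param ratings Character vector of exactly 13 ratings, each `"high"`,
#'   `"intermediate"`, or `"low"`.
#' @param high_critical Number of high ratings that forces level 1 (default 2).
#' @param intermediate_vulnerable Number of intermediate ratings that forces
#'   level 2 (default 4).
#' @return Level code `"1"`, `"2"`, or `"3"`.
#' @examples
#' score_stressors(rep("low", 13))                      # "3"
#' score_stressors(c("high", rep("low", 12)))           # "2"
#' score_stressors(c("high", "high", rep("low", 11)))   # "1"
#' @export
score_stressors <- function(ratings, high_critical = 2L,
                            intermediate_vulnerable = 4L) {
  ratings <- as.character(ratings)
  if (length(ratings) != 13L)
    stop(sprintf("stressor narrative: expected 13 ratings, found %d",
                 length(ratings)), call. = FALSE)
  if (any(is.na(ratings)) || !all(ratings %in% c("high", "intermediate", "low")))
    stop("stressor ratings must each be 'high', 'intermediate' or 'low'",
         call. = FALSE)
  n_high <- sum(ratings == "high")
  n_int  <- sum(ratings == "intermediate")
  if (n_high >= high_critical) "1"
  else if (n_high >= 1L || n_int >= intermediate_vulnerable) "2"
  else "3"
}

#' Assess one species from a score sheet
#'
#' Composes the module totals, best/alternate bounds, certainty totals and
#' category-band assignments into a single species assessment.
#'
#' @param sheet A `vuln_sheet`.
#' @param rubric A `vuln_rubric`.
#' @return An object of class `vuln_assessment`: a list with `species_id`,
#'   `reviewer_id`, `v_b`, `v_c`, `v_b_low`, `v_b_high`, `v_c_low`,
#'   `v_c_high`, `certainty_b`, `certainty_c`, `category_b`, `category_c`
#'   (band labels) and `ordinal_b`, `ordinal_c` (band ranks, 1 = most
#'   vulnerable).
#' @export
assess_species <- function(sheet, rubric) {
  v_b <- total_best(sheet, rubric, "baseline")
  v_c <- total_best(sheet, rubric, "climate")
  rb  <- total_range(sheet, rubric, "baseline")
  rc  <- total_range(sheet, rubric, "climate")
  band_b <- assign_band(v_b, rubric, "baseline")
  band_c <- assign_band(v_c, rubric, "climate")
  structure(list(
    species_id  = attr(sheet, "species_id"),
    reviewer_id = attr(sheet, "reviewer_id"),
    v_b = v_b, v_c = v_c,
    v_b_low = unname(rb["low"]), v_b_high = unname(rb["high"]),
    v_c_low = unname(rc["low"]), v_c_high = unname(rc["high"]),
    certainty_b = certainty_total(sheet, rubric, "baseline"),
    certainty_c = certainty_total(sheet, rubric, "climate"),
    category_b = as.character(band_b), category_c = as.character(band_c),
    ordinal_b = attr(band_b, "ordinal"), ordinal_c = attr(band_c, "ordinal")
  ), class = "vuln_assessment")
}

#' @export
print.vuln_assessment <- function(x, ...) {
  cat(sprintf("<vuln_assessment> %s (reviewer %s)\n", x$species_id,
              x$reviewer_id))
  cat(sprintf("  Vb %d [%d-%d] %s (certainty %d)\n", x$v_b, x$v_b_low,
              x$v_b_high, x$category_b, x$certainty_b))
  cat(sprintf("  Vc %d [%d-%d] %s (certainty %d)\n", x$v_c, x$v_c_low,
              x$v_c_high, x$category_c, x$certainty_c))
  invisible(x)
}

#' Assess many score sheets into a flat table
#'
#' @param sheets A list of `vuln_sheet` objects.
#' @param rubric A `vuln_rubric`.
#' @return Data frame with one row per sheet and the fields of
#'   [assess_species()] as columns.
#' @export
assess_sheets <- function(sheets, rubric) {
  if (!length(sheets)) stop("no sheets to assess", call. = FALSE)
  rows <- lapply(sheets, function(s) {
    a <- assess_species(s, rubric)
    as.data.frame(unclass(a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
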