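#' Flatten score sheets to the standard table
#'
#' The interchange format is a comma-separated UTF-8 table with header
#' `species_id, reviewer_id, module, metric_id, best_level, alternate_level,
#' certainty`, one row per metric per reviewer per species. An empty
#' `alternate_level` means no alternate was assigned.
#'
#' @param sheets List of `vuln_sheet` objects.
#' @param rubric A `vuln_rubric` (to label each metric's module).
#' @return Data frame in the interchange layout.
#' @export
sheets_to_table <- function(sheets, rubric) {
  mod_of <- metric_module_map(rubric)
  rows <- lapply(sheets, function(s) {
    data.frame(species_id = attr(s, "species_id"),
               reviewer_id = attr(s, "reviewer_id"),
               module = unname(mod_of[s$metric_id]),
               metric_id = s$metric_id,
               best_level = s$best,
               alternate_level = ifelse(is.na(s$alternate), "", s$alternate),
               certainty = s$certainty, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

metric_module_map <- function(rubric) {
  unlist(lapply(rubric$modules, function(m)
    stats::setNames(rep(m$name, length(m$metrics)),
                    vapply(m$metrics, `[[`, character(1), "id"))),
    use.names = TRUE) -> v
  names(v) <- sub("^(baseline|climate)\\.", "", names(v))
  v
}

#' Rebuild validated score sheets from the standard table
#'
#' @param tbl Data frame in the layout of [sheets_to_table()].
#' @param rubric A `vuln_rubric`.
#' @param context Optional file name used in error messages.
#' @return Named list of `vuln_sheet` objects (one per species x reviewer),
#'   keyed `"<species_id>|<reviewer_id>"`.
#' @export
table_to_sheets <- function(tbl, rubric, context = "score table") {
  req <- c("species_id", "reviewer_id", "module", "metric_id", "best_level",
           "alternate_level", "certainty")
  if (!all(req %in% names(tbl)))
    stop(sprintf("%s: missing column(s): %s", context,
                 paste(setdiff(req, names(tbl)), collapse = ", ")),
         call. = FALSE)
  if (!nrow(tbl))
    stop(sprintf("%s: no sheets (empty table)", context), call. = FALSE)
  tbl$.line <- seq_len(nrow(tbl)) + 1L  # header is line 1
  key <- paste(tbl$species_id, tbl$reviewer_id, sep = "|")
  dup <- duplicated(paste(key, tbl$metric_id))
  if (any(dup))
    stop(sprintf("%s: line %d: duplicate (species, reviewer, metric) row",
                 context, tbl$.line[which(dup)[1]]), call. = FALSE)
  bad_cert <- !as.character(tbl$certainty) %in% c("1", "2", "3")
  if (any(bad_cert))
    stop(sprintf("%s: line %d: certainty '%s' outside {1, 2, 3}", context,
                 tbl$.line[which(bad_cert)[1]],
                 tbl$certainty[which(bad_cert)[1]]), call. = FALSE)
  sheets <- lapply(split(tbl, key), function(g) {
    alt <- as.character(g$alternate_level)
    alt[is.na(alt) | alt == ""] <- NA_character_
    scores <- data.frame(metric_id = as.character(g$metric_id),
                         best = as.character(g$best_level),
                         alternate = alt,
                         certainty = as.integer(g$certainty),
                         stringsAsFactors = FALSE)
    tryCatch(
      score_sheet(g$species_id[1], g$reviewer_id[1], scores, rubric),
      error = function(e)
        stop(sprintf("%s (rows near line %d): %s", context, g$.line[1],
                     conditionMessage(e)), call. = FALSE))
  })
  sheets[order(names(sheets))]
}

#' Read score sheets from a CSV file
#'
#' Strict reader for the interchange format (see [sheets_to_table()]);
#' validation failures are reported with the file name and line number.
#'
#' @param path CSV file path.
#' @param rubric A `vuln_rubric`.
#' @return Named list of `vuln_sheet` objects.
#' @export
read_score_sheets <- function(path, rubric) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  table_to_sheets(tbl, rubric, context = basename(path))
}

#' Write score sheets to a CSV file
#'
#' @param sheets List of `vuln_sheet` objects.
#' @param path Output CSV path.
#' @param rubric A `vuln_rubric`.
#' @return `path`, invisibly.
#' @export
write_score_sheets <- function(sheets, path, rubric) {
  utils::write.csv(sheets_to_table(sheets, rubric), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read a species metadata table
#'
#' Columns: `species_id`, `origin`, `family` (required); `name`,
#' `anadromous`, `external_status`, `excluded`, `exclusion_reason`
#' (optional).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_species_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species_id", "origin", "family")
  if (!all(req %in% names(md)))
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(setdiff(req, names(md)), collapse = ", ")),
         call. = FALSE)
  bad <- !md$origin %in% c("native", "alien")
  if (any(bad))
    stop(sprintf("%s: line %d: origin '%s' must be 'native' or 'alien'",
                 basename(path), which(bad)[1] + 1L, md$origin[which(bad)[1]]),
         call. = FALSE)
  md
}

#' Write a machine-readable JSON report
#'
#' Wraps any list of results with the rubric fingerprint (see
#' [rubric_hash()]) and schema version so numbers remain auditable against a
#' specific point calibration.
#'
#' @param results Named list of result objects (data frames become arrays of
#'   row objects).
#' @param rubric The `vuln_rubric` the results were computed under.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(results, rubric, path) {
  payload <- c(list(rubric_schema_version = rubric$schema_version,
                    rubric_hash = rubric_hash(rubric)),
               results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
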