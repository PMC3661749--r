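#' Mean and range of a reviewer panel's totals
#'
#' @param totals Numeric vector of at least two reviewer module totals for
#'   the same species.
#' @return Named vector `c(mean, min, max)`.
#' @export
panel_mean_range <- function(totals) {
  check_panel(totals)
  c(mean = mean(totals), min = min(totals), max = max(totals))
}

#' Inter-reviewer spread of a panel
#'
#' @inheritParams panel_mean_range
#' @return `max(totals) - min(totals)`.
#' @export
panel_spread <- function(totals) {
  check_panel(totals)
  max(totals) - min(totals)
}

check_panel <- function(totals) {
  if (length(totals) < 2L || any(is.na(totals)))
    stop("a panel needs at least 2 reviewer totals (no NAs)", call. = FALSE)
  invisible(totals)
}

#' Consensus category rating for a reviewer panel
#'
#' The consensus band is the band of the unrounded panel mean. The rating is
#' annotated when individual reviewers cross category boundaries: `"+"` if at
#' least one reviewer total falls in a less-vulnerable (higher-ordinal) band
#' than the consensus, `"-"` if at least one falls in a more-vulnerable band,
#' `"+-"` when both occur. Because banding is monotone in the total, the
#' annotation is fully determined by the extreme totals, so `totals` may be
#' either the full vector of reviewer totals or just the `(min, max)` pair.
#'
#' @param mean_total Real panel mean (banded unrounded; display rounding is
#'   one decimal, half away from zero).
#' @param totals Reviewer totals, or the `c(min, max)` range endpoints.
#' @param rubric A `vuln_rubric`.
#' @param module `"baseline"` or `"climate"`.
#' @return Object of class `vuln_consensus`: list with `mean`,
#'   `display_mean`, `range`, `band` (label), `ordinal`, `annotation` (one of
#'   `""`, `"+"`, `"-"`, `"+-"`) and `rating` (e.g. `"Vb3-"`).
#' @examples
#' r <- default_rubric()
#' consensus_rating(34.0, c(31, 35), r, "baseline")$rating  # "Vb4-"
#' @export
consensus_rating <- function(mean_total, totals, rubric, module) {
  check_panel(totals)
  mod <- get_module(rubric, module)
  ord_mean <- band_ordinal(mean_total, mod)
  ord_rev  <- band_ordinal(range(totals), mod)
  plus  <- any(ord_rev > ord_mean)   # less vulnerable than consensus
  minus <- any(ord_rev < ord_mean)   # more vulnerable than consensus
  annotation <- paste0(if (plus) "+" else "", if (minus) "-" else "")
  structure(list(
    mean = mean_total,
    display_mean = round_half_away(mean_total, 1L),
    range = c(min(totals), max(totals)),
    band = mod$bands$label[ord_mean],
    ordinal = ord_mean,
    annotation = annotation,
    rating = paste0(mod$prefix, ord_mean, annotation)
  ), class = "vuln_consensus")
}

#' @export
print.vuln_consensus <- function(x, ...) {
  cat(sprintf("<vuln_consensus> %s: mean %.1f (%g-%g), %s\n", x$rating,
              x$display_mean, x$range[1], x$range[2], x$band))
  invisible(x)
}

#' Consensus table for a multi-reviewer panel of score sheets
#'
#' Groups sheets by species, computes each reviewer's module totals and rolls
#' them up into the consensus mean/range/rating, the best/alternate bound
#' means and the certainty-total mean.
#'
#' @param sheets List of `vuln_sheet` objects; every species must be scored
#'   by at least two reviewers.
#' @param rubric A `vuln_rubric`.
#' @param module `"baseline"` or `"climate"`.
#' @return Data frame, one row per species: `species_id`, `n_reviewers`,
#'   `mean`, `min`, `max`, `spread`, `high_mean`, `low_mean`,
#'   `certainty_mean`, `band`, `ordinal`, `annotation`, `rating`.
#' @export
panel_consensus <- function(sheets, rubric, module) {
  if (!length(sheets)) stop("no sheets supplied", call. = FALSE)
  species <- vapply(sheets, attr, character(1), "species_id")
  rows <- lapply(split(sheets, species), function(grp) {
    totals <- vapply(grp, total_best, numeric(1), rubric, module)
    ranges <- vapply(grp, total_range, numeric(2), rubric, module)
    certs  <- vapply(grp, certainty_total, numeric(1), rubric, module)
    cr <- consensus_rating(mean(totals), totals, rubric, module)
    data.frame(
      species_id = attr(grp[[1]], "species_id"),
      n_reviewers = length(grp),
      mean = mean(totals), min = min(totals), max = max(totals),
      spread = panel_spread(totals),
      high_mean = mean(ranges["high", ]), low_mean = mean(ranges["low", ]),
      certainty_mean = mean(certs),
      band = cr$band, ordinal = cr$ordinal,
      annotation = cr$annotation, rating = cr$rating,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows[order(names(rows))])
  rownames(out) <- NULL
  out
}

#' Re-run the consensus banding over a stored panel fixture
#'
#' Applies [consensus_rating()] to each `(mean, min, max)` triplet of a
#' fixture table such as [klamath_fixture()] and compares the computed rating
#' string against the printed one. On the packaged Klamath panel this
#' mechanical re-run reproduces 39 of the 40 printed ratings; the remaining
#' row (eulachon, baseline module) is a documented discrepancy in the printed
#' record, flagged here rather than silently patched.
#'
#' @param fixture Data frame with columns `taxon`, `module`, `mean`, `min`,
#'   `max`, `rating` (category ordinal plus optional `+`/`-`).
#' @param rubric A `vuln_rubric`.
#' @return The fixture with computed `band`, `computed_rating` and logical
#'   `match` columns.
#' @export
concordance_regression <- function(fixture, rubric) {
  req <- c("taxon", "module", "mean", "min", "max", "rating")
  if (!all(req %in% names(fixture)))
    stop("fixture: missing column(s): ",
         paste(setdiff(req, names(fixture)), collapse = ", "), call. = FALSE)
  out <- fixture
  out$band <- out$computed_rating <- NA_character_
  for (i in seq_len(nrow(fixture))) {
    cr <- consensus_rating(fixture$mean[i],
                           c(fixture$min[i], fixture$max[i]),
                           rubric, fixture$module[i])
    out$band[i] <- cr$band
    out$computed_rating[i] <- paste0(cr$ordinal, cr$annotation)
  }
  out$match <- out$computed_rating == as.character(fixture$rating)
  out
}

# round half away from zero (display convention for panel means and percents)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
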