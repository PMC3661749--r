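# Builders for score sheets used across the suite. Levels are specified by
# ordinal index (1 = most vulnerable level) and translated to rubric codes.

rubric_metrics <- function(rubric) {
  unlist(lapply(rubric$modules, `[[`, "metrics"), recursive = FALSE)
}

# baseline/climate: integer vectors of 10 level indices each
# alt: named list metric_id -> alternate level index
# certainty: scalar or length-20 vector
make_sheet <- function(rubric, baseline = rep(1, 10), climate = rep(1, 10),
                       certainty = 3, alt = list(),
                       species_id = "sp1", reviewer_id = "R1") {
  mets <- rubric_metrics(rubric)
  idx <- c(baseline, climate)
  certainty <- rep_len(certainty, length(mets))
  rows <- lapply(seq_along(mets), function(i) {
    m <- mets[[i]]
    stopifnot(idx[i] >= 1, idx[i] <= nrow(m$levels))
    a <- alt[[m$id]]
    data.frame(metric_id = m$id,
               best = m$levels$code[idx[i]],
               alternate = if (is.null(a)) NA_character_
                           else m$levels$code[a],
               certainty = certainty[i], stringsAsFactors = FALSE)
  })
  score_sheet(species_id, reviewer_id, do.call(rbind, rows), rubric)
}

# sheet with every metric at its top (least vulnerable) level
max_sheet <- function(rubric, ...) {
  mets <- rubric_metrics(rubric)
  tops <- vapply(mets, function(m) nrow(m$levels), integer(1))
  make_sheet(rubric, tops[1:10], tops[11:20], ...)
}

# uniformly random level indices; optionally random alternates/certainty
random_sheet <- function(rubric, species_id = "sp1", reviewer_id = "R1",
                         with_alternates = FALSE) {
  mets <- rubric_metrics(rubric)
  idx <- vapply(mets, function(m) sample(nrow(m$levels), 1), integer(1))
  alt <- list()
  cert <- sample(1:3, length(mets), replace = TRUE)
  if (with_alternates) {
    for (i in seq_along(mets)) {
      if (cert[i] < 3 && runif(1) < 0.7) {
        K <- nrow(mets[[i]]$levels)
        alt[[mets[[i]]$id]] <- sample(K, 1)
      }
    }
  }
  make_sheet(rubric, idx[1:10], idx[11:20], certainty = cert, alt = alt,
             species_id = species_id, reviewer_id = reviewer_id)
}

# independent oracle for Spearman: explicit average ranks + Pearson formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i])
      ties <- sum(v == v[i])
      r[i] <- less + (ties + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# build a records table straight from module totals (bands derived)
make_records <- function(rubric, v_b, v_c,
                         origin = rep("native", length(v_b)),
                         family = rep("Cyprinidae", length(v_b)),
                         certainty_b = rep(20L, length(v_b)),
                         certainty_c = rep(20L, length(v_b)),
                         external_status = rep(NA_real_, length(v_b)),
                         excluded = rep(FALSE, length(v_b))) {
  bb <- assign_band(v_b, rubric, "baseline")
  bc <- assign_band(v_c, rubric, "climate")
  out <- data.frame(
    species_id = sprintf("s%02d", seq_along(v_b)), origin = origin,
    family = family, anadromous = FALSE, external_status = external_status,
    excluded = excluded, v_b = v_b, v_c = v_c,
    certainty_b = certainty_b, certainty_c = certainty_c,
    category_b = as.character(bb), category_c = as.character(bc),
    ordinal_b = attr(bb, "ordinal"), ordinal_c = attr(bc, "ordinal"),
    stringsAsFactors = FALSE)
  class(out) <- c("vuln_records", "data.frame")
  out
}

# edit the default rubric's parsed YAML and return the modified YAML string
mutated_rubric_yaml <- function(mutate) {
  doc <- yaml::yaml.load(serialize_rubric(default_rubric()))
  yaml::as.yaml(mutate(doc))
}
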