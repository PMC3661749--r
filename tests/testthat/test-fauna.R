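r <- default_rubric()

test_that("category tallies are exhaustive and respect exclusions", {
  rec <- make_records(r, v_b = c(10, 20, 40), v_c = c(12, 20, 30))
  tb <- tally_by_category(rec, r, "baseline")
  expect_equal(unname(tb), c(1, 1, 0, 1))
  expect_equal(sum(tb), 3)
  # the printed Klamath baseline rating column counts 4/6/7/3
  fx <- klamath_fixture()
  ords <- as.integer(substr(fx$rating[fx$module == "baseline"], 1, 1))
  expect_equal(as.vector(table(factor(ords, 1:4))), c(4L, 6L, 7L, 3L))
  # excluded records never enter tallies
  rec2 <- make_records(r, v_b = c(10, 20, 40), v_c = c(12, 20, 30),
                       excluded = c(FALSE, TRUE, FALSE))
  expect_equal(sum(tally_by_category(rec2, r, "baseline")), 2)
  # empty collections tally to zeros
  rec0 <- make_records(r, v_b = 20, v_c = 20, excluded = TRUE)
  expect_equal(sum(tally_by_category(rec0, r, "climate")), 0)
})

test_that("band percentages use half-away-from-zero display rounding", {
  bands_b <- r$modules$baseline$bands$label
  bands_c <- r$modules$climate$bands$label
  native_b <- stats::setNames(c(16, 45, 47, 13), bands_b)
  p <- percent_in_bands(native_b, bands_b[1:2])
  expect_equal(p$exact, 100 * 61 / 121)
  expect_equal(p$display, 50)
  native_c <- stats::setNames(c(37, 63, 18, 3, 0), bands_c)
  p2 <- percent_in_bands(native_c, bands_c[1:2])
  expect_equal(p2$display, 83)
  alien_c <- stats::setNames(c(0, 8, 13, 16, 6), bands_c)
  expect_equal(percent_in_bands(alien_c, bands_c[2])$display, 19)
  expect_equal(percent_in_bands(alien_c, bands_c[1:4])$display, 86)
  # full-band subset is exactly 100 before rounding
  expect_equal(percent_in_bands(native_b, bands_b)$exact, 100)
  expect_error(percent_in_bands(stats::setNames(0, bands_b[1]), bands_b[1]),
               "zero")
  expect_error(percent_in_bands(native_b, "No such band"), "unknown band")
})

test_that("family tables report counts and integer percentages per band", {
  # 12-species family: 11 least vulnerable, 1 highly vulnerable
  rec <- make_records(r, v_b = c(rep(35, 11), 20), v_c = rep(20, 12),
                      origin = c(rep("alien", 11), "native"),
                      family = rep("Centrarchidae", 12))
  fb <- family_breakdown(rec, r, "baseline")
  expect_equal(fb$n, 12)
  expect_equal(fb$pct_native, 8)
  expect_equal(fb$n_highly_vulnerable, 1)
  expect_equal(fb$pct_highly_vulnerable, 8)
  expect_equal(fb$pct_least_vulnerable, 92)
  # single-species family is 100% in its band
  rec1 <- make_records(r, v_b = 12, v_c = 12, family = "Osmeridae")
  fb1 <- family_breakdown(rec1, r, "baseline")
  expect_equal(fb1$pct_critically_vulnerable, 100)
  # 36-species family split 18/17/1 over the first three bands
  rec3 <- make_records(r, v_b = c(rep(12, 18), rep(20, 17), 30),
                       v_c = rep(20, 36), family = rep("Salmonidae", 36))
  fb3 <- family_breakdown(rec3, r, "baseline")
  expect_equal(c(fb3$pct_critically_vulnerable, fb3$pct_highly_vulnerable,
                 fb3$pct_less_vulnerable), c(50, 47, 3))
  expect_error(family_breakdown(make_records(r, 20, 20, family = ""),
                                r, "baseline"), "family")
})

test_that("rank correlation handles ties like the explicit-rank oracle", {
  expect_equal(rank_correlation(1:10, 2 * (1:10) + 3)$coefficient, 1)
  expect_equal(rank_correlation(c(1, 2, 3), c(3, 1, 2))$coefficient, -0.5)
  set.seed(19)
  for (i in 1:40) {
    n <- sample(4:25, 1)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- x + sample(-2:2, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(rank_correlation(x, y)$coefficient, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_error(rank_correlation(rep(2, 5), 1:5), "constant")
  expect_error(rank_correlation(1:4, 1:5), "length mismatch")
  # exact permutation p-value for tiny n
  out <- rank_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4), p_method = "exact")
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  expect_error(rank_correlation(1:12, 12:1, p_method = "exact"), "n <= 10")
})

test_that("metric correlation matrix flags redundancy and degenerate columns", {
  set.seed(55)
  # high-loading cohort: strong shared factor across metrics
  sim <- simulate_cohort(cohort_spec(n_native = 60, n_alien = 20,
                                     loading = 0.9, seed = 9), r)
  mm <- metric_correlation_matrix(sim$sheets, r)
  expect_true(all(vapply(mm$matrices, isSymmetric, logical(1))))
  expect_equal(dim(mm$matrices$pooled), c(20, 20))
  fr <- mm$fractions
  # threshold nestedness
  for (sc in unique(fr$scope))
    expect_gte(fr$fraction[fr$scope == sc & fr$threshold == 0.5],
               fr$fraction[fr$scope == sc & fr$threshold == 0.7])
  # a metric duplicated against itself correlates perfectly
  sheets <- lapply(1:30, function(i) {
    idx <- sample(3, 1)
    make_sheet(r, baseline = c(sample(4:6, 1), rep(1, 9)),
               climate = c(idx, idx, rep(1, 8)),
               species_id = sprintf("d%02d", i))
  })
  suppressWarnings(mm2 <- metric_correlation_matrix(sheets, r))
  expect_equal(mm2$matrices$climate["c1", "c2"], 1)
  # constant columns are excluded with a warning per affected scope
  w <- capture_warnings(metric_correlation_matrix(sheets, r))
  expect_true(all(grepl("constant", w)) && length(w) >= 1)
  expect_error(metric_correlation_matrix(sheets[1:2], r), "at least 3")
})

test_that("independent metrics show near-zero correlation at n = 500", {
  set.seed(23)
  sheets <- lapply(1:500, function(i) random_sheet(r, sprintf("u%03d", i)))
  mm <- metric_correlation_matrix(sheets, r)
  expect_lt(abs(mm$matrices$pooled["b1", "c1"]), 0.15)
  expect_equal(mm$fractions$fraction[mm$fractions$scope == "pooled" &
                                       mm$fractions$threshold == 0.5], 0)
})

test_that("external status and certainty correlations behave at the extremes", {
  rec <- make_records(r, v_b = c(12, 18, 25, 30, 36), v_c = c(11, 15, 20, 25, 30),
                      external_status = c(1.2, 2.1, 3.0, 3.8, 4.9))
  out <- compare_external_status(rec)
  expect_equal(out$coefficient, c(1, 1))  # affine transform preserves ranks
  rec$external_status <- rev(rec$external_status)
  expect_equal(compare_external_status(rec)$coefficient, c(-1, -1))
  rec$external_status <- NA_real_
  expect_error(compare_external_status(rec), "fewer than 3")
  # constant certainty leaves the coefficient undefined
  rec2 <- make_records(r, v_b = c(12, 20, 30), v_c = c(12, 20, 30))
  expect_error(certainty_vs_score(rec2, "baseline"), "constant")
  rec3 <- make_records(r, v_b = c(12, 20, 30), v_c = c(12, 20, 30),
                       certainty_b = c(12, 20, 30))
  expect_equal(certainty_vs_score(rec3, "baseline")$coefficient, 1)
})

test_that("fauna_summary conserves counts and covers all bands", {
  sim <- simulate_cohort(cohort_spec(n_native = 40, n_alien = 15, seed = 3), r)
  rec <- fauna_records(sim$metadata, assess_sheets(sim$sheets, r))
  summ <- fauna_summary(rec, r)
  for (m in c("baseline", "climate")) {
    tl <- summ$tallies[[m]]
    expect_equal(unname(colSums(tl)), unname(summ$n))
  }
  expect_equal(sum(summ$families$baseline$n), 55)
  expect_true(all(summ$percentages$percent >= 0 &
                    summ$percentages$percent <= 100))
})
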