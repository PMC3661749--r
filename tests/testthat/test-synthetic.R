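r <- default_rubric()

test_that("cohort simulation is deterministic in its seed", {
  spec <- cohort_spec(n_native = 12, n_alien = 5, reviewers = 2, seed = 77)
  a <- simulate_cohort(spec, r)
  b <- simulate_cohort(spec, r)
  expect_identical(a$metadata, b$metadata)
  expect_identical(sheets_to_table(a$sheets, r), sheets_to_table(b$sheets, r))
  c <- simulate_cohort(cohort_spec(n_native = 12, n_alien = 5,
                                   reviewers = 2, seed = 78), r)
  expect_false(identical(sheets_to_table(a$sheets, r),
                         sheets_to_table(c$sheets, r)))
})

test_that("degenerate and invalid cohort specs are handled", {
  empty <- simulate_cohort(cohort_spec(n_native = 0, n_alien = 0), r)
  expect_equal(nrow(empty$metadata), 0)
  expect_length(empty$sheets, 0)
  expect_error(cohort_spec(disagreement = 1.4), "probabilities")
  expect_error(cohort_spec(n_native = -1), "non-negative")
  expect_error(cohort_spec(loading = 1.2), "loading")
  expect_error(cohort_spec(scale = c(native = 0, alien = 1)), "positive")
  expect_error(cohort_spec(certainty_probs = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("default cohorts separate native and alien vulnerability", {
  sim <- simulate_cohort(cohort_spec(seed = 4), r)
  rec <- fauna_records(sim$metadata, assess_sheets(sim$sheets, r))
  ob <- origin_summary(rec, r, "baseline")
  oc <- origin_summary(rec, r, "climate")
  expect_equal(ob$n, c(121, 43))
  expect_lt(ob$mean[ob$origin == "native"], ob$mean[ob$origin == "alien"])
  expect_lt(oc$mean[oc$origin == "native"], oc$mean[oc$origin == "alien"])
  # all simulated sheets survive strict re-validation through the table layer
  sheets2 <- table_to_sheets(sheets_to_table(sim$sheets, r), r)
  expect_length(sheets2, length(sim$sheets))
})

test_that("simulated origin gap matches the latent-model expectation", {
  # oracle: closed-form expected total under the ordered-threshold model
  expected_total <- function(rubric, module, delta, sd_z) {
    sum(vapply(rubric$modules[[module]]$metrics, function(m) {
      K <- nrow(m$levels)
      q <- stats::qnorm(seq_len(K - 1) / K)
      pr <- diff(c(0, stats::pnorm((q - delta) / sd_z), 1))
      sum(m$levels$points * pr)
    }, numeric(1)))
  }
  spec <- cohort_spec(seed = 12)
  sd_z <- function(origin) sqrt(spec$loading^2 * spec$scale[origin]^2 +
                                  1 - spec$loading^2)
  implied_gap <- expected_total(r, "baseline",
                                spec$location$alien["baseline"], sd_z("alien")) -
    expected_total(r, "baseline",
                   spec$location$native["baseline"], sd_z("native"))
  gaps <- vapply(1:8, function(i) {
    sim <- simulate_cohort(cohort_spec(seed = 100 + i), r)
    rec <- fauna_records(sim$metadata, assess_sheets(sim$sheets, r))
    ob <- origin_summary(rec, r, "baseline")
    ob$mean[ob$origin == "alien"] - ob$mean[ob$origin == "native"]
  }, numeric(1))
  expect_lt(abs(mean(gaps) - implied_gap), 2)
})

test_that("reviewer panels perturb levels as specified", {
  base <- make_sheet(r, baseline = c(3, 3, 2, 3, 2, 2, 2, 2, 2, 2),
                     climate = rep(2, 10), species_id = "spP")
  same <- simulate_panel(base, k = 4, disagreement = 0, rubric = r, seed = 2)
  totals <- vapply(same, total_best, numeric(1), r, "baseline")
  expect_equal(panel_spread(totals), 0)
  expect_identical(as.data.frame(same[[1]]), as.data.frame(base))
  expect_error(simulate_panel(base, k = 1, disagreement = 0.2, rubric = r),
               "at least 2")
  expect_error(simulate_panel(base, k = 3, disagreement = 2, rubric = r),
               "\\[0, 1\\]")
  # at disagreement 1 a mid-level 3-level metric moves one level up or down
  # with equal probability: enumeration gives P(level 1) = P(level 3) = 1/2
  draws <- unlist(lapply(1:150, function(i) {
    p <- simulate_panel(base, k = 2, disagreement = 1, rubric = r, seed = i)
    vapply(p, function(s) as.integer(s$best[s$metric_id == "c4"]), integer(1))
  }))
  expect_true(all(draws %in% c(1L, 3L)))
  expect_gt(mean(draws == 1L), 0.40)
  expect_lt(mean(draws == 1L), 0.60)
})

test_that("expected panel spread grows with disagreement", {
  base <- make_sheet(r, baseline = rep(2, 10), climate = rep(2, 10))
  mean_spread <- function(p) {
    mean(vapply(1:60, function(i) {
      panel <- simulate_panel(base, k = 4, disagreement = p, rubric = r,
                              seed = 1000 + i)
      panel_spread(vapply(panel, total_best, numeric(1), r, "baseline"))
    }, numeric(1)))
  }
  spreads <- vapply(c(0, 0.2, 0.5), mean_spread, numeric(1))
  expect_true(all(diff(spreads) > 0))
})

test_that("the Klamath fixture carries the printed panel statistics", {
  fx <- klamath_fixture()
  expect_equal(nrow(fx), 40)
  expect_equal(sort(unique(fx$module)), c("baseline", "climate"))
  pl <- fx[fx$taxon == "Pacific lamprey" & fx$module == "baseline", ]
  expect_equal(pl$mean, 21.8)
  expect_equal(c(pl$min, pl$max), c(20, 24))
  expect_equal(pl$rating, "2")
  st <- fx[fx$taxon == "Klamath Mountains Province summer steelhead" &
             fx$module == "climate", ]
  expect_equal(st$mean, 13.0)
  expect_equal(c(st$min, st$max), c(11, 16))
  expect_equal(st$rating, "1")
  # ranges are internally consistent with the means
  expect_true(all(fx$min <= fx$mean & fx$mean <= fx$max))
})
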