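test_that("the control standard scores exactly 50% against itself", {
  ctl <- cq_rows("control", copies_short = 7575, copies_long = 3787.5)
  res <- contamination_score(ctl, ctl)
  expect_identical(res$delta_delta_cq, 0)
  expect_identical(res$rne, 1)
  expect_identical(res$percent_hmw, 50)
  expect_false(res$below_loq)
})

test_that("one extra cycle on the long amplicon halves the score", {
  ctl <- cq_rows("control", 1000, 500)
  smp <- cq_rows("sample", 1000, 250) # ddCq = +1 at efficiency 2
  res <- contamination_score(smp, ctl)
  expect_equal(res$delta_delta_cq, 1)
  expect_equal(res$rne, 0.5)
  expect_equal(res$percent_hmw, 25)
})

test_that("noiseless idealized panel recovers 1/5/25/50 percent exactly", {
  cq <- simulate_panel_cq(c(0.01, 0.05, 0.25, 0.50), noise_sd = 0, seed = 1,
                          idealized = TRUE)
  ctl <- dplyr::filter(cq, sample_id == "std_50pct")
  for (f in c(0.01, 0.05, 0.25, 0.50)) {
    smp <- dplyr::filter(cq, sample_id == sprintf("std_%gpct", 100 * f))
    res <- contamination_score(smp, ctl)
    expect_equal(res$percent_hmw, 100 * f, tolerance = 1e-9)
  }
})

test_that("the score increases strictly with the true HMW fraction", {
  fr <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.25, 0.5, 0.8)
  cq <- simulate_panel_cq(fr, noise_sd = 0, seed = 1, idealized = TRUE)
  ctl <- dplyr::filter(cq, sample_id == "std_50pct")
  percents <- vapply(fr, function(f) {
    contamination_score(
      dplyr::filter(cq, sample_id == sprintf("std_%gpct", 100 * f)),
      ctl)$percent_hmw
  }, numeric(1))
  expect_true(all(diff(percents) > 0))
})

test_that("length-containment detectability biases low fractions upward;
           the 50% control is exact by construction", {
  fr <- c(0.01, 0.05, 0.25, 0.50)
  cq <- simulate_panel_cq(fr, noise_sd = 0, seed = 4, idealized = FALSE,
                          n_fragments = 20000)
  ctl <- dplyr::filter(cq, sample_id == "std_50pct")
  rec <- vapply(fr, function(f) {
    contamination_score(
      dplyr::filter(cq, sample_id == sprintf("std_%gpct", 100 * f)),
      ctl)$percent_hmw
  }, numeric(1))
  expect_equal(rec[4], 50, tolerance = 1e-9)
  # upward bias at the low end of the panel, documented model behaviour
  expect_gt(rec[1], 1)
  expect_gt(rec[2], 5)
  # still monotone and within the right order of magnitude
  expect_true(all(diff(rec) > 0))
  expect_lt(rec[1], 5)
  expect_lt(rec[2], 15)
})

test_that("replicate noise of 0.2 cycles keeps score CVs under 25% at
           fractions >= 5%", {
  for (f in c(0.05, 0.25)) {
    percents <- vapply(seq_len(200), function(i) {
      cq <- simulate_panel_cq(c(f, 0.50), noise_sd = 0.2,
                              n_replicates = 2, seed = 3000 + i,
                              idealized = TRUE)
      ctl <- dplyr::filter(cq, sample_id == "std_50pct")
      smp <- dplyr::filter(cq, sample_id == sprintf("std_%gpct", 100 * f))
      contamination_score(smp, ctl)$percent_hmw
    }, numeric(1))
    expect_lt(sd(percents) / mean(percents), 0.25)
    expect_equal(mean(percents), 100 * f, tolerance = 0.1)
  }
})

test_that("all-non-detect long amplicons report a bounded sentinel,
           never zero", {
  ctl <- cq_rows("control", 1000, 500)
  smp <- tibble::tibble(
    sample_id = "clean", assay_name = c("short_106", "long_612"),
    replicate_id = 1L, cq = c(27, NA), efficiency = 2
  )
  res <- contamination_score(smp, ctl)
  expect_true(res$below_loq)
  expect_true(is.na(res$percent_hmw))
  expect_gt(res$percent_upper_bound, 0)

  # Cq at the last cycle is also a non-detect
  smp40 <- smp
  smp40$cq[2] <- 40
  expect_true(contamination_score(smp40, ctl)$below_loq)
})

test_that("Pfaffl per-assay efficiencies reduce to the single-efficiency
           form when both assays amplify at 2.0", {
  ctl <- cq_rows("control", 1000, 500)
  smp <- cq_rows("sample", 1000, 100)
  const <- contamination_score(smp, ctl, efficiency_mode = "constant")
  pfaffl <- contamination_score(smp, ctl, efficiency_mode = "per_assay")
  expect_equal(const$percent_hmw, pfaffl$percent_hmw, tolerance = 1e-12)

  # and diverges when the long assay underperforms
  smp_low_eff <- smp
  smp_low_eff$efficiency <- c(2, 1.8)
  ctl_low_eff <- ctl
  ctl_low_eff$efficiency <- c(2, 1.8)
  pf2 <- contamination_score(smp_low_eff, ctl_low_eff,
                             efficiency_mode = "per_assay")
  expect_false(isTRUE(all.equal(pf2$percent_hmw, const$percent_hmw)))
})

test_that("batch screening flags exactly the contaminated samples, in
           stable order", {
  # sixteen samples: two spiked at 40% HMW, the rest clean at 2%
  truth <- c(rep(0.40, 2), rep(0.02, 14))
  ids <- sprintf("S%02d", seq_along(truth))
  total <- 7575
  rows <- purrr::map2(ids, truth, function(id, f) {
    cq_rows(id, total, f * total)
  }) |> purrr::list_rbind()
  ctl <- cq_rows("ctl50", total, 0.5 * total)
  flagged <- screen_batch(dplyr::bind_rows(rows, ctl), "ctl50",
                          threshold_percent = 10)
  expect_identical(flagged$sample_id, c("S01", "S02"))
  expect_true(all(flagged$percent_hmw > 10))

  # samples identical to the control all score 50 and are all flagged
  same <- purrr::map(c("a", "b", "c"), function(id) {
    cq_rows(id, total, 0.5 * total)
  }) |> purrr::list_rbind()
  all_flagged <- screen_batch(dplyr::bind_rows(same, ctl), "ctl50",
                              threshold_percent = 10)
  expect_identical(all_flagged$sample_id, c("a", "b", "c"))
  expect_true(all(all_flagged$percent_hmw == 50))

  # empty table -> empty result
  empty <- screen_batch(rows[0, ], "ctl50")
  expect_identical(nrow(empty), 0L)
})

test_that("Cq CSVs load with non-detect handling", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,assay,replicate,cq,efficiency",
               "S1,short_106,1,26.5,2",
               "S1,long_612,1,ND,2"), csv)
  cq <- read_cq_csv(csv)
  expect_true(is.na(cq$cq[2]))
  expect_named(cq, c("sample_id", "assay_name", "replicate_id", "cq",
                     "efficiency"))
})
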