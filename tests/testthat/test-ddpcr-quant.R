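test_that("Poisson quantification closed forms", {
  # no positives -> zero copies with a zero lower bound
  res0 <- poisson_quantify(plate_row(20000, 0))
  expect_identical(res0$copies_per_ng, 0)
  expect_identical(res0$ci_low, 0)
  expect_false(res0$saturated_flag)

  # p = 1 - 1/e -> lambda = 1 -> 1/0.00085 copies/uL
  res1 <- poisson_quantify(plate_row(20000, 12642))
  expect_equal(res1$lambda, 1, tolerance = 1e-4)
  expect_equal(res1$copies_per_ul, 1 / 0.00085, tolerance = 1e-3)
  expect_equal(res1$copies_per_ng, res1$copies_per_ul * 20, tolerance = 1e-12)
})

test_that("saturated wells raise a flag and an infinite bound, never a
           silent number", {
  res <- poisson_quantify(plate_row(1000, 1000))
  expect_true(res$saturated_flag)
  expect_identical(res$copies_per_ng, Inf)
  expect_identical(res$ci_high, Inf)
  expect_true(is.finite(res$ci_low))
})

test_that("invariants: CI ordering, nonnegativity, low-droplet flag", {
  plate <- dplyr::bind_rows(
    plate_row(20000, 5000, "a"),
    plate_row(7000, 100, "b"),
    plate_row(15000, 14999, "c")
  )
  res <- poisson_quantify(plate)
  expect_true(all(res$ci_low <= res$copies_per_ng + 1e-12))
  expect_true(all(res$copies_per_ng <= res$ci_high))
  expect_true(all(res$ci_low >= 0))
  expect_identical(res$low_quality_flag, c(FALSE, TRUE, FALSE))
  expect_error(poisson_quantify(plate_row(1000, 1001)), "n_positive")
})

test_that("the simulate -> quantify pipeline recovers known copy loads
           within the 95% CI in >= 90% of replicates", {
  pop <- simulate_fragments(healthy_cfdna_spec(), 2000, seed = 5)
  assay <- amplicon_assay("short", 106)
  # copies/ng at 1 ng input equals the expected copies in the reaction
  truth <- expected_amplifiable_copies(pop, assay, 1)
  n_rep <- 200
  covered <- vapply(seq_len(n_rep), function(i) {
    well <- simulate_droplets(pop, assay, 1, n_droplets = 20000,
                              seed = 1000 + i)
    est <- poisson_quantify(well)
    est$ci_low <= truth && truth <= est$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("copy estimates are consistent across droplet counts, with
           shrinking sampling variance", {
  pop <- simulate_fragments(healthy_cfdna_spec(), 2000, seed = 5)
  assay <- amplicon_assay("short", 106)
  est_at <- function(n_droplets) {
    vapply(seq_len(50), function(i) {
      poisson_quantify(
        simulate_droplets(pop, assay, 1, n_droplets,
                          seed = 2000 + i)
      )$copies_per_ng
    }, numeric(1))
  }
  small <- est_at(8000)
  large <- est_at(32000)
  expect_equal(mean(small), mean(large), tolerance = 0.03)
  expect_lt(sd(large), sd(small))
})

test_that("fragmentation summary arithmetic and the undefined-ratio flag", {
  est <- tibble::tibble(
    sample_id = "S1",
    assay_name = c("OCR1_short", "OCR1_long", "CCR_short", "CCR_long"),
    copies_per_ng = c(150, 50, 80, 0)
  )
  sm <- fragmentation_summary(est)
  ocr1 <- sm[sm$region_label == "OCR1", ]
  expect_identical(ocr1$difference, 100)
  expect_identical(ocr1$ratio, 3)
  expect_false(ocr1$ratio_undefined)
  ccr <- sm[sm$region_label == "CCR", ]
  expect_identical(ccr$difference, 80)
  expect_true(is.na(ccr$ratio))
  expect_true(ccr$ratio_undefined)

  # short = long -> difference 0, ratio 1
  eq <- fragmentation_summary(tibble::tibble(
    sample_id = "S2", assay_name = c("CCR_short", "CCR_long"),
    copies_per_ng = c(42, 42)
  ))
  expect_identical(eq$difference, 0)
  expect_identical(eq$ratio, 1)
})

test_that("CRC-like cohorts show higher short/long ratios than healthy in
           all regions (rank-sum on 30 per arm)", {
  assays <- default_region_assays()
  regions <- c("OCR1", "OCR2", "CCR")
  input_ng <- 3 # enough template that long-amplicon wells are well counted
  simulate_arm <- function(spec, ids, seed0) {
    purrr::map(seq_along(ids), function(i) {
      pop <- simulate_fragments(spec, 2000, seed = seed0 + i,
                                sample_id = ids[i])
      purrr::map(seq_along(regions), function(j) {
        r <- regions[j]
        dplyr::bind_rows(
          simulate_droplets(pop, assays[[paste0(r, "_short")]], input_ng,
                            20000, seed = seed0 + 1000 * j + 2 * i),
          simulate_droplets(pop, assays[[paste0(r, "_long")]], input_ng,
                            20000, seed = seed0 + 1000 * j + 2 * i + 1)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }
  healthy <- simulate_arm(healthy_cfdna_spec(),
                          sprintf("H%02d", 1:30), 50000)
  crc <- simulate_arm(crc_cfdna_spec(), sprintf("C%02d", 1:30), 90000)
  sm <- fragmentation_summary(poisson_quantify(
    dplyr::bind_rows(healthy, crc)))
  sm$group <- ifelse(grepl("^H", sm$sample_id), "healthy", "CRC")
  for (r in regions) {
    sub <- sm[sm$region_label == r, ]
    res <- rank_sum_test(sub$ratio[sub$group == "CRC"],
                         sub$ratio[sub$group == "healthy"])
    expect_lt(res$p_value, 0.05)
    expect_gt(median(sub$ratio[sub$group == "CRC"]),
              median(sub$ratio[sub$group == "healthy"]))
  }
})

test_that("droplet CSVs load into the quantification layout", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,assay,n_total,n_positive,input_mass_ng",
               "S1,OCR1_short,20000,5000,1"), csv)
  plate <- read_droplet_csv(csv)
  expect_named(plate, c("sample_id", "assay_name", "n_total_droplets",
                        "n_positive", "input_mass_ng"))
  expect_equal(poisson_quantify(plate)$lambda, -log(1 - 0.25))
})
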