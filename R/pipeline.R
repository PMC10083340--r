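#' Run a complete synthetic experiment
#'
#' One call reproduces a whole computational experiment end-to-end on
#' synthetic data and writes its report bundle (tidy CSV tables and a
#' parameter log; figures optional) to `out_dir`. Four scenarios are
#' available:
#'
#' * `"fragmentation_cohort"`: a ddPCR cohort of healthy donors and
#'   colorectal-cancer (CRC) patients quantified with short/long assay
#'   pairs in two open-chromatin regions (OCR1, OCR2) and a closed
#'   pericentromeric region (CCR); reports copy estimates, short/long
#'   differences and ratios, Wilcoxon ratio comparisons per region, and
#'   Levene tests of difference variability across regions.
#' * `"contamination_panel"`: the 1/5/25/50% HMW standards panel scored by
#'   delta-delta-Cq against the 50% control under both the idealized and
#'   the length-containment forward models, plus electrophoresis molarity
#'   ratios per standard.
#' * `"storage_series"`: two donors' blood stored 2/4/7/10 days with
#'   rising HMW contamination and post-day-7 di-/tri-nucleosome
#'   degradation; reports qPCR scores, AEF ratios, their log-log Pearson
#'   correlation, and detected degradation peaks.
#' * `"batch_screen"`: a routine 16-sample screening batch with two
#'   heavily contaminated samples; reports all scores, the flagged
#'   samples at the screening threshold, and the score-vs-ratio
#'   correlation.
#'
#' Outputs are deterministic given `scenario` + `seed`: re-running writes
#' byte-identical CSVs.
#'
#' @param scenario One of the four scenario names above.
#' @param seed Integer seed for every random draw in the scenario.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and just returns the tables.
#' @param figures Also write PNG figures (default `FALSE`).
#' @param ... Scenario-specific overrides: `n_healthy` (32), `n_crc` (53),
#'   `n_fragments_per_sample`, `n_droplets`, `hmw_fractions`,
#'   `threshold_percent`, `noise_sd`.
#'
#' @return A named list of the scenario's result tibbles (also written as
#'   `<name>.csv` when `out_dir` is given), invisibly.
#' @export
run_experiment <- function(scenario = c("fragmentation_cohort",
                                        "contamination_panel",
                                        "storage_series", "batch_screen"),
                           seed = 1, out_dir = NULL, figures = FALSE, ...) {
  scenario <- match.arg(scenario)
  assert_scalar_number(seed, "seed")
  tables <- switch(scenario,
    fragmentation_cohort = experiment_fragmentation_cohort(seed, ...),
    contamination_panel = experiment_contamination_panel(seed, ...),
    storage_series = experiment_storage_series(seed, ...),
    batch_screen = experiment_batch_screen(seed, ...)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_lines <- c(
      sprintf("scenario: %s", scenario),
      sprintf("seed: %d", as.integer(seed)),
      sprintf("tables: %s", paste(names(tables), collapse = ", "))
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    for (nm in names(tables)) {
      tab <- tables[[nm]]
      tab <- tab[, !vapply(tab, is.list, logical(1)), drop = FALSE]
      readr::write_csv(tab, file.path(out_dir, paste0(nm, ".csv")))
    }
    if (figures) {
      write_experiment_figures(scenario, tables, out_dir)
    }
  }
  invisible(tables)
}

write_experiment_figures <- function(scenario, tables, out_dir) {
  try_save <- function(plot, name) {
    tryCatch(
      ggplot2::ggsave(file.path(out_dir, name), plot,
                      width = 6, height = 4, dpi = 120),
      error = function(e) invisible(NULL)
    )
  }
  if (scenario == "fragmentation_cohort" &&
      "fragmentation_summary" %in% names(tables)) {
    try_save(plot_copies_estimates(tables$fragmentation_summary),
             "copies_estimates.png")
  }
  if (!is.null(tables$score_vs_ratio)) {
    try_save(plot_score_vs_ratio(tables$score_vs_ratio),
             "score_vs_ratio.png")
  }
  invisible(NULL)
}

# ddPCR fragmentation cohort: healthy vs CRC, three regions. The effective
# per-locus cfDNA representation (amplifiable copies recovered per ng at a
# given locus) varies between subjects, and more so at the open-chromatin
# loci than over the rigidly nucleosome-covered pericentromere: a
# subject-by-region lognormal yield factor scales both amplicons of a
# region together. That makes the short-minus-long difference
# heteroscedastic across regions (the Levene comparison) while leaving the
# short/long ratio invariant, so the CRC-specific short-fragment component
# can raise the ratio in every region (the Wilcoxon comparison).
experiment_fragmentation_cohort <- function(seed, n_healthy = 32,
                                            n_crc = 53,
                                            n_fragments_per_sample = 4000,
                                            n_droplets = 20000,
                                            input_mass_ng = 1,
                                            region_yield_sdlog = c(
                                              OCR1 = 0.25, OCR2 = 0.25,
                                              CCR = 0.06
                                            )) {
  assays <- default_region_assays()
  subjects <- tibble(
    sample_id = c(sprintf("H%02d", seq_len(n_healthy)),
                  sprintf("C%02d", seq_len(n_crc))),
    group_label = rep(c("healthy", "CRC"), c(n_healthy, n_crc))
  )
  seeds <- derive_seeds(seed, nrow(subjects))
  regions <- names(region_yield_sdlog)

  plate <- purrr::map(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$sample_id[i]
    grp <- subjects$group_label[i]
    sub_seeds <- derive_seeds(seeds[i], 3 * length(regions))
    purrr::map(seq_along(regions), function(j) {
      r <- regions[j]
      yield <- local_seed(
        sub_seeds[3 * j - 2],
        exp(rnorm(1, 0, region_yield_sdlog[[r]]))
      )
      spec <- if (grp == "CRC") crc_cfdna_spec() else healthy_cfdna_spec()
      pop <- simulate_fragments(spec, n_fragments_per_sample,
                                seed = sub_seeds[3 * j - 1],
                                sample_id = sid, group_label = grp)
      dseeds <- derive_seeds(sub_seeds[3 * j], 2)
      # the yield factor acts on the amplifiable material of this locus,
      # not on the reported input mass, so copies/ng spread around the
      # theoretical genome-equivalent line as real per-locus yields do
      pl <- bind_rows(
        simulate_droplets(pop, assays[[paste0(r, "_short")]],
                          yield * input_mass_ng, n_droplets,
                          seed = dseeds[1]),
        simulate_droplets(pop, assays[[paste0(r, "_long")]],
                          yield * input_mass_ng, n_droplets,
                          seed = dseeds[2])
      )
      pl$input_mass_ng <- input_mass_ng
      pl
    }) |> list_rbind()
  }) |> list_rbind()

  estimates <- poisson_quantify(plate) |>
    left_join(subjects, by = "sample_id")
  summaries <- fragmentation_summary(estimates) |>
    left_join(subjects, by = "sample_id")

  wilcoxon <- purrr::map(regions, function(r) {
    sub <- filter(summaries, .data$region_label == r)
    res <- rank_sum_test(sub$ratio[sub$group_label == "CRC"],
                         sub$ratio[sub$group_label == "healthy"])
    mutate(res, region_label = r, comparison = "CRC vs healthy ratio",
           .before = 1)
  }) |> list_rbind()

  levene <- purrr::map(c("healthy", "CRC"), function(grp) {
    sub <- filter(summaries, .data$group_label == grp)
    res <- levene_test(sub, .data$difference, .data$region_label)
    mutate(res, group_label = grp,
           comparison = "difference variance across regions", .before = 1)
  }) |> list_rbind()

  list(
    droplet_plate = plate,
    copy_estimates = estimates,
    fragmentation_summary = summaries,
    wilcoxon_tests = wilcoxon,
    levene_tests = levene
  )
}

# Panel recovery under both forward models plus AEF cross-validation on a
# matched batch of panel replicates.
experiment_contamination_panel <- function(seed,
                                           hmw_fractions = c(0.01, 0.05,
                                                             0.25, 0.50),
                                           n_fragments = 20000,
                                           n_replicate_standards = 4,
                                           noise_sd = 0.2) {
  seeds <- derive_seeds(seed, 4)
  control_id <- sprintf("std_%gpct", 100 * max(hmw_fractions))

  ideal_cq <- simulate_panel_cq(hmw_fractions, seed = seeds[1],
                                idealized = TRUE)
  real_cq <- simulate_panel_cq(hmw_fractions, seed = seeds[2],
                               idealized = FALSE,
                               n_fragments = n_fragments)
  score_panel <- function(cq) {
    screen_batch(cq, control_id, flagged_only = FALSE) |>
      select("sample_id", "percent_hmw")
  }
  control_row <- tibble(sample_id = control_id,
                        percent_hmw = 50)

  recovery <- tibble(
    sample_id = sprintf("std_%gpct", 100 * hmw_fractions),
    true_percent = 100 * hmw_fractions
  ) |>
    left_join(
      bind_rows(score_panel(ideal_cq), control_row) |>
        rename(idealized_percent = "percent_hmw"),
      by = "sample_id") |>
    left_join(
      bind_rows(score_panel(real_cq), control_row) |>
        rename(containment_percent = "percent_hmw"),
      by = "sample_id")

  panel <- simulate_panel(hmw_fractions, n_fragments = n_fragments,
                          seed = seeds[3])
  ratios <- purrr::map(unique(panel$sample_id), function(id) {
    pop <- new_fragment_population(filter(panel, .data$sample_id == id))
    eg <- render_electropherogram(pop, size_grid = seq(50, 40000, by = 10))
    tibble(sample_id = id, molarity_ratio = molarity_ratio(eg))
  }) |> list_rbind()

  # matched batch: each panel fraction prepared in replicate and read out
  # by both qPCR (with replicate Cq noise, scored vs the 50% control) and
  # electrophoresis, for the cross-platform correlation
  assays <- default_multicopy_assays()
  grid <- tidyr::expand_grid(replicate = seq_len(n_replicate_standards),
                             hmw_fraction = hmw_fractions)
  mseeds <- derive_seeds(seeds[4], 4 * nrow(grid) + 3)
  hmw_pop <- simulate_fragments(hmw_dna_spec(), 2000,
                                seed = mseeds[1], sample_id = "hmw")
  sheared <- simulate_fragments(sheared_standard_spec(), n_fragments,
                                seed = mseeds[2], sample_id = "sheared")
  control_pop <- mix_by_mass(sheared, hmw_pop, 0.5,
                             n_fragments = n_fragments,
                             seed = mseeds[3], sample_id = "ctl50")
  ctl_seeds <- derive_seeds(mseeds[3], 2)
  control_cq <- bind_rows(
    simulate_cq(control_pop, assays$short_106, 1, noise_sd = noise_sd,
                seed = ctl_seeds[1], n_replicates = 2),
    simulate_cq(control_pop, assays$long_612, 1, noise_sd = noise_sd,
                seed = ctl_seeds[2], n_replicates = 2)
  )
  matched <- purrr::map(seq_len(nrow(grid)), function(i) {
    f <- grid$hmw_fraction[i]
    sid <- sprintf("std_%gpct_r%d", 100 * f, grid$replicate[i])
    s <- mseeds[3 + 4 * (i - 1) + 1:4]
    pop <- mix_by_mass(sheared, hmw_pop, f, n_fragments = n_fragments,
                       seed = s[1], sample_id = sid)
    cq <- bind_rows(
      simulate_cq(pop, assays$short_106, 1, noise_sd = noise_sd,
                  seed = s[2], n_replicates = 2),
      simulate_cq(pop, assays$long_612, 1, noise_sd = noise_sd,
                  seed = s[3], n_replicates = 2)
    )
    eg <- render_electropherogram(pop, size_grid = seq(50, 40000, by = 10))
    tibble(
      sample_id = sid, true_hmw_fraction = f,
      percent_hmw = contamination_score(cq, control_cq)$percent_hmw,
      molarity_ratio = molarity_ratio(eg)
    )
  }) |> list_rbind()
  matched_corr <- pearson_with_ci(log(matched$percent_hmw),
                                  log(matched$molarity_ratio))

  list(
    panel_cq_idealized = ideal_cq,
    panel_cq_containment = real_cq,
    panel_recovery = recovery,
    panel_aef_ratios = left_join(recovery, ratios, by = "sample_id"),
    score_vs_ratio = matched,
    matched_correlation = matched_corr
  )
}

# Storage time-course: HMW contamination and nucleosomal degradation grow
# with days in the tube; scored by qPCR and cross-validated against AEF.
experiment_storage_series <- function(seed, donors = c("D1", "D2"),
                                      days = c(2, 4, 7, 10),
                                      hmw_by_day = c(`2` = 0.02, `4` = 0.05,
                                                     `7` = 0.12,
                                                     `10` = 0.35),
                                      noise_sd = 0.1,
                                      n_fragments = 12000) {
  grid <- tidyr::expand_grid(donor = donors, day = days)
  seeds <- derive_seeds(seed, 4 * nrow(grid) + 4)
  assays <- default_multicopy_assays()

  hmw_pop <- simulate_fragments(hmw_dna_spec(), 2000, seed = seeds[1],
                                sample_id = "hmw")
  control_pop <- mix_by_mass(
    simulate_fragments(sheared_standard_spec(), n_fragments,
                       seed = seeds[2], sample_id = "sheared"),
    hmw_pop, mass_fraction_b = 0.5, n_fragments = n_fragments,
    seed = seeds[3], sample_id = "control_50pct"
  )
  cseeds <- derive_seeds(seeds[4], 2)
  control_cq <- bind_rows(
    simulate_cq(control_pop, assays$short_106, 1, noise_sd = noise_sd,
                seed = cseeds[1], n_replicates = 2),
    simulate_cq(control_pop, assays$long_612, 1, noise_sd = noise_sd,
                seed = cseeds[2], n_replicates = 2)
  )

  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    donor <- grid$donor[i]
    day <- grid$day[i]
    sid <- sprintf("%s_day%02d", donor, day)
    base_spec <- if (day >= 7) degraded_storage_spec() else
      healthy_cfdna_spec()
    s <- seeds[4 + 4 * (i - 1) + 1:4]
    base <- simulate_fragments(base_spec, n_fragments, seed = s[1],
                               sample_id = sid, group_label = "stored")
    pop <- mix_by_mass(base, hmw_pop,
                       mass_fraction_b = hmw_by_day[[as.character(day)]],
                       n_fragments = n_fragments, seed = s[2],
                       sample_id = sid)
    cq <- bind_rows(
      simulate_cq(pop, assays$short_106, 1, noise_sd = noise_sd,
                  seed = s[3], n_replicates = 2),
      simulate_cq(pop, assays$long_612, 1, noise_sd = noise_sd,
                  seed = s[4], n_replicates = 2)
    )
    eg <- render_electropherogram(pop, size_grid = seq(50, 40000, by = 10))
    peaks <- find_nucleosomal_peaks(eg)
    list(
      meta = tibble(sample_id = sid, donor = donor, day = day,
                    true_hmw_fraction =
                      hmw_by_day[[as.character(day)]],
                    molarity_ratio = molarity_ratio(eg),
                    n_degradation_peaks = nrow(peaks)),
      cq = cq
    )
  })
  meta <- list_rbind(purrr::map(rows, "meta"))
  cq_all <- list_rbind(purrr::map(rows, "cq"))

  scores <- purrr::map(meta$sample_id, function(id) {
    contamination_score(filter(cq_all, .data$sample_id == id), control_cq)
  }) |> list_rbind()
  matched <- left_join(meta, scores, by = "sample_id")

  corr <- pearson_with_ci(log(matched$percent_hmw),
                          log(matched$molarity_ratio))

  list(
    storage_cq = cq_all,
    score_vs_ratio = matched,
    storage_correlation = corr
  )
}

# Routine screening batch: mostly clean samples, two heavily contaminated.
experiment_batch_screen <- function(seed, n_samples = 16,
                                    n_spiked = 2, spiked_fraction = 0.40,
                                    clean_fraction_range = c(0.02, 0.02),
                                    threshold_percent = 10,
                                    noise_sd = 0.2,
                                    n_fragments = 10000) {
  seeds <- derive_seeds(seed, 4 * n_samples + 5)
  assays <- default_multicopy_assays()

  hmw_pop <- simulate_fragments(hmw_dna_spec(), 2000, seed = seeds[1],
                                sample_id = "hmw")
  control_pop <- mix_by_mass(
    simulate_fragments(sheared_standard_spec(), n_fragments,
                       seed = seeds[2], sample_id = "sheared"),
    hmw_pop, mass_fraction_b = 0.5, n_fragments = n_fragments,
    seed = seeds[3], sample_id = "control_50pct"
  )
  cseeds <- derive_seeds(seeds[4], 2)
  control_cq <- bind_rows(
    simulate_cq(control_pop, assays$short_106, 1, noise_sd = noise_sd,
                seed = cseeds[1], n_replicates = 2),
    simulate_cq(control_pop, assays$long_612, 1, noise_sd = noise_sd,
                seed = cseeds[2], n_replicates = 2)
  )

  clean_fracs <- local_seed(seeds[5], {
    stats::runif(n_samples - n_spiked, clean_fraction_range[1],
                 clean_fraction_range[2])
  })
  truth <- tibble(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    true_hmw_fraction = c(rep(spiked_fraction, n_spiked), clean_fracs),
    spiked = rep(c(TRUE, FALSE), c(n_spiked, n_samples - n_spiked))
  ) |>
    arrange(.data$sample_id)

  rows <- purrr::map(seq_len(n_samples), function(i) {
    sid <- truth$sample_id[i]
    s <- seeds[5 + 4 * (i - 1) + 1:4]
    base <- simulate_fragments(healthy_cfdna_spec(), n_fragments,
                               seed = s[1], sample_id = sid)
    pop <- mix_by_mass(base, hmw_pop,
                       mass_fraction_b = truth$true_hmw_fraction[i],
                       n_fragments = n_fragments, seed = s[2],
                       sample_id = sid)
    cq <- bind_rows(
      simulate_cq(pop, assays$short_106, 1, noise_sd = noise_sd,
                  seed = s[3], n_replicates = 2),
      simulate_cq(pop, assays$long_612, 1, noise_sd = noise_sd,
                  seed = s[4], n_replicates = 2)
    )
    eg <- render_electropherogram(pop, size_grid = seq(50, 40000, by = 10))
    list(cq = cq,
         ratio = tibble(sample_id = sid,
                        molarity_ratio = molarity_ratio(eg)))
  })
  cq_all <- list_rbind(purrr::map(rows, "cq"))
  ratios <- list_rbind(purrr::map(rows, "ratio"))

  scored <- screen_batch(bind_rows(cq_all, control_cq), "control_50pct",
                         threshold_percent = threshold_percent,
                         flagged_only = FALSE)
  matched <- truth |>
    left_join(scored, by = "sample_id") |>
    left_join(ratios, by = "sample_id")
  corr <- pearson_with_ci(log(matched$percent_hmw),
                          log(matched$molarity_ratio))

  list(
    batch_cq = cq_all,
    score_vs_ratio = matched,
    flagged_samples = filter(matched, .data$flagged),
    batch_correlation = corr
  )
}
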