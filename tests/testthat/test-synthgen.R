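test_that("mixture spec validation names the offending component", {
  expect_error(
    mixture_spec(weight = c(0.5, -0.5), family = c("gaussian", "gaussian"),
                 location_bp = c(170, 380), scale = c(20, 20)),
    "Component 2.*weight"
  )
  expect_error(
    mixture_spec(weight = c(0.6, 0.6), family = c("gaussian", "gaussian"),
                 location_bp = c(170, 380), scale = c(20, 20)),
    "sum to 1"
  )
  expect_error(
    mixture_spec(1, "weibull", 170, 20),
    "unknown family"
  )
  expect_error(
    mixture_spec(1, "gaussian", -170, 20),
    "non-positive location"
  )
})

test_that("zero-variance components give exact lengths", {
  pop <- simulate_fragments(mixture_spec(1, "gaussian", 170, 0),
                            n_fragments = 5, seed = 1)
  expect_identical(pop$length_bp, rep(170L, 5))
})

test_that("simulated draws are deterministic given the seed and leave the
           global RNG alone", {
  set.seed(99)
  before <- .Random.seed
  a <- simulate_fragments(healthy_cfdna_spec(), 500, seed = 42)
  expect_identical(.Random.seed, before)
  b <- simulate_fragments(healthy_cfdna_spec(), 500, seed = 42)
  c <- simulate_fragments(healthy_cfdna_spec(), 500, seed = 43)
  expect_identical(a$length_bp, b$length_bp)
  expect_false(identical(a$length_bp, c$length_bp))
})

test_that("default healthy mixture has a 170 bp median at n = 10,000", {
  pop <- simulate_fragments(healthy_cfdna_spec(), 10000, seed = 7)
  expect_lte(abs(median(pop$length_bp) - 170), 2)
})

test_that("sheared-standard generator has ~170 bp mean", {
  pop <- simulate_fragments(sheared_standard_spec(), 10000, seed = 7)
  expect_lte(abs(mean(pop$length_bp) - 170), 3)
})

test_that("mixture component weights are respected (binomial check)", {
  spec <- mixture_spec(weight = c(0.5, 0.5),
                       family = c("gaussian", "gaussian"),
                       location_bp = c(100, 300), scale = c(0, 0))
  n <- 10000
  pop <- simulate_fragments(spec, n, seed = 11)
  w_hat <- mean(pop$length_bp == 100L)
  expect_true(all(pop$length_bp %in% c(100L, 300L)))
  # within 3 binomial SDs of 0.5
  expect_lte(abs(w_hat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("mix_by_mass boundaries use a single source", {
  a <- uniform_pop(170, 200, "A")
  b <- uniform_pop(17000, 200, "B")
  only_a <- mix_by_mass(a, b, mass_fraction_b = 0, seed = 1)
  expect_true(all(only_a$source == "A"))
  expect_true(all(only_a$length_bp == 170L))
  only_b <- mix_by_mass(a, b, mass_fraction_b = 1, seed = 1)
  expect_true(all(only_b$source == "B"))
})

test_that("equal-mass mixing of 170 bp and 17 kb gives ~1:100 counts", {
  a <- uniform_pop(170, 5000, "A")
  b <- uniform_pop(17000, 5000, "B")
  mix <- mix_by_mass(a, b, mass_fraction_b = 0.5, n_fragments = 10100,
                     seed = 3)
  n_a <- sum(mix$source == "A")
  n_b <- sum(mix$source == "B")
  expect_equal(n_b / n_a, 1 / 100, tolerance = 0.02)
  # realized bp mass split in half
  mass_b <- sum(mix$length_bp[mix$source == "B"])
  expect_equal(mass_b / sum(mix$length_bp), 0.5, tolerance = 0.02)
})

test_that("panel standards carry their nominal HMW mass share", {
  fr <- c(0.01, 0.05, 0.25, 0.50)
  panel <- simulate_panel(fr, n_fragments = 20000, seed = 5)
  shares <- panel |>
    dplyr::group_by(sample_id, hmw_fraction) |>
    dplyr::summarise(
      share = sum(length_bp[source == "B"]) / sum(length_bp),
      .groups = "drop"
    )
  expect_setequal(shares$hmw_fraction, fr)
  # absolute deviation under 2 percentage points for every standard
  expect_true(all(abs(shares$share - shares$hmw_fraction) < 0.02))
})

test_that("panel fractions must be strictly increasing", {
  expect_error(simulate_panel(c(0.5, 0.25)), "strictly increasing")
})

test_that("droplet simulation obeys the Poisson occupancy law", {
  # fraction positive converges to 1 - exp(-lambda); checked at
  # lambda in {0.1, 1, 3} with 3-SD binomial bands
  n_droplets <- 20000
  pop <- uniform_pop(1e6, 50)
  assay <- amplicon_assay("unit", 106)
  for (lambda in c(0.1, 1, 3)) {
    # mass tuned so expected copies give the wanted per-droplet load
    p_contain <- (1e6 - 105) / 1e6
    copies_wanted <- lambda / (0.85 / 1000) * 20
    mass <- copies_wanted * 0.0033 / p_contain
    well <- simulate_droplets(pop, assay, mass, n_droplets, seed = 21)
    p_expect <- 1 - exp(-lambda)
    se <- sqrt(p_expect * (1 - p_expect) / n_droplets)
    expect_lte(abs(well$n_positive / n_droplets - p_expect), 3 * se)
  }
})

test_that("droplet wells with no amplifiable template are all-negative", {
  assay <- amplicon_assay("long", 612)
  short_pop <- uniform_pop(100, 500) # every fragment shorter than amplicon
  well <- simulate_droplets(short_pop, assay, input_mass_ng = 50,
                            n_droplets = 1000, seed = 2)
  expect_identical(well$n_positive, 0L)
  expect_error(simulate_droplets(short_pop, assay, 1, n_droplets = 0),
               "n_droplets")
})

test_that("Cq forward model follows the log-efficiency identities", {
  pop <- uniform_pop(170, 100)
  assay <- amplicon_assay("short", 106)
  cq1 <- simulate_cq(pop, assay, input_mass_ng = 1, efficiency = 2,
                     noise_sd = 0, seed = 1)
  cq2 <- simulate_cq(pop, assay, input_mass_ng = 2, efficiency = 2,
                     noise_sd = 0, seed = 1)
  cq10 <- simulate_cq(pop, assay, input_mass_ng = 10, efficiency = 2,
                      noise_sd = 0, seed = 1)
  # doubling copies removes exactly one cycle; 10x removes log2(10)
  expect_equal(cq1$cq - cq2$cq, 1)
  expect_equal(cq1$cq - cq10$cq, log2(10), tolerance = 1e-12)
  expect_error(simulate_cq(pop, assay, 1, efficiency = 1), "efficiency")
})

test_that("zero template is a non-detect, never a finite Cq", {
  assay <- amplicon_assay("long", 612)
  pop <- uniform_pop(100, 50)
  cq <- simulate_cq(pop, assay, input_mass_ng = 1, seed = 1,
                    n_replicates = 3)
  expect_true(all(is.na(cq$cq)))
  expect_identical(nrow(cq), 3L)
})

test_that("electropherogram rendering conserves mass and is linear", {
  pop <- uniform_pop(170, 300)
  eg <- render_electropherogram(pop, size_grid = seq(1, 600, by = 1),
                                bandwidth = 8)
  expect_true(all(eg$mass_density >= 0))
  expect_equal(eg$size_bp[which.max(eg$mass_density)], 170)
  total_mass <- sum(pop$length_bp)
  expect_equal(pracma::trapz(eg$size_bp, eg$mass_density), total_mass,
               tolerance = 1e-3)
  # doubling every fragment doubles the integrated mass
  pop2 <- fragment_population(rep(pop$length_bp, 2))
  eg2 <- render_electropherogram(pop2, size_grid = seq(1, 600, by = 1),
                                 bandwidth = 8)
  expect_equal(eg2$mass_density, 2 * eg$mass_density, tolerance = 1e-9)
})

test_that("storage-degraded traces show di- and tri-nucleosome peaks", {
  pop <- simulate_fragments(degraded_storage_spec(), 20000, seed = 13)
  eg <- render_electropherogram(pop, size_grid = seq(1, 800, by = 1))
  peaks <- find_nucleosomal_peaks(eg)
  expect_identical(nrow(peaks), 2L)
  expect_true(peaks$peak_bp[1] >= 360 && peaks$peak_bp[1] <= 400)
  expect_true(peaks$peak_bp[2] >= 540 && peaks$peak_bp[2] <= 600)
})

test_that("mixture specs round-trip through YAML and JSON configs", {
  spec <- degraded_storage_spec()
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(components = purrr::transpose(as.list(spec))), yml)
  expect_equal(as.data.frame(read_mixture_spec(yml)), as.data.frame(spec))
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(components = spec), js, auto_unbox = TRUE)
  expect_equal(as.data.frame(read_mixture_spec(js)), as.data.frame(spec))
})

test_that("population length tables round-trip through TSV", {
  pop <- simulate_fragments(healthy_cfdna_spec(), 500, seed = 3,
                            sample_id = "H1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_population_tsv(pop, tsv)
  back <- read_population_tsv(tsv, sample_id = "H1")
  expect_identical(sort(back$length_bp), sort(pop$length_bp))
})
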