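#' Construct a fragment population
#'
#' A fragment population is the package's representation of one sample's
#' cfDNA: a tibble with one row per DNA fragment, carrying the fragment
#' length in bp and sample metadata. Optional genomic coordinates
#' (`chrom`, `start`, `end`, 0-based half-open) may be present for
#' interval-based analyses.
#'
#' @param lengths Positive fragment lengths in bp (coerced to integer).
#' @param sample_id Sample identifier.
#' @param group_label Group label, e.g. `"healthy"`, `"CRC"`, `"standard"`.
#'
#' @return A tibble of class `fragment_population` with columns
#'   `length_bp`, `sample_id`, `group_label`.
#' @examples
#' fragment_population(c(166, 170, 171), sample_id = "H01",
#'                     group_label = "healthy")
#' @export
fragment_population <- function(lengths, sample_id = "sample",
                                group_label = NA_character_) {
  if (length(lengths) == 0) abort("A fragment population must be non-empty.")
  if (!is.numeric(lengths) || any(!is.finite(lengths)) || any(lengths < 1)) {
    abort("All fragment lengths must be finite and >= 1 bp.")
  }
  pop <- tibble(
    length_bp = as.integer(round(lengths)),
    sample_id = as.character(sample_id),
    group_label = as.character(group_label)
  )
  class(pop) <- c("fragment_population", class(pop))
  pop
}

new_fragment_population <- function(df) {
  class(df) <- unique(c("fragment_population", class(df)))
  df
}

draw_component_lengths <- function(n, family, location_bp, scale) {
  if (n == 0) return(integer(0))
  if (family == "gaussian") {
    if (scale == 0) {
      out <- rep(location_bp, n)
    } else {
      # truncation at 1 bp by rejection; negligible rejection rate for the
      # nucleosomal presets (location >> scale)
      out <- rnorm(n, location_bp, scale)
      bad <- which(out < 1)
      while (length(bad) > 0) {
        out[bad] <- rnorm(length(bad), location_bp, scale)
        bad <- bad[out[bad] < 1]
      }
    }
  } else {
    out <- rlnorm(n, meanlog = log(location_bp), sdlog = scale)
    out <- pmax(out, 1)
  }
  as.integer(pmax(1L, as.integer(round(out))))
}

#' Simulate cfDNA fragment lengths from a mixture
#'
#' Draws `n_fragments` i.i.d. fragment lengths from a [mixture_spec()].
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param spec A [mixture_spec()].
#' @param n_fragments Number of fragments to draw (>= 1).
#' @param seed Integer seed.
#' @inheritParams fragment_population
#'
#' @return A [fragment_population()] with exactly `n_fragments` rows.
#' @examples
#' simulate_fragments(healthy_cfdna_spec(), n_fragments = 1000, seed = 1)
#' @export
simulate_fragments <- function(spec, n_fragments, seed,
                               sample_id = "sample",
                               group_label = NA_character_) {
  validate_mixture_spec(spec)
  assert_scalar_number(n_fragments, "n_fragments", min = 1)
  n_fragments <- as.integer(n_fragments)
  lengths <- local_seed(seed, {
    comp <- sample.int(nrow(spec), n_fragments, replace = TRUE,
                       prob = spec$weight)
    out <- integer(n_fragments)
    for (k in seq_len(nrow(spec))) {
      idx <- which(comp == k)
      out[idx] <- draw_component_lengths(
        length(idx), spec$family[k], spec$location_bp[k], spec$scale[k]
      )
    }
    out
  })
  fragment_population(lengths, sample_id = sample_id,
                      group_label = group_label)
}

#' Mix two fragment populations by DNA mass
#'
#' Builds a mixture in which the expected share of total base-pair content
#' (mass is proportional to summed fragment length) contributed by `pop_b`
#' equals `mass_fraction_b`. Fragment lengths are resampled with replacement
#' from each source population, so both source length distributions are
#' preserved; only the fragment *counts* are adjusted. This emulates mixing
#' two DNA preparations gravimetrically, e.g. sheared 170 bp standard DNA
#' with intact high-molecular-weight DNA: at equal mass, a population of
#' 17 kb molecules contributes 100-fold fewer fragments than one of 170 bp
#' molecules.
#'
#' The number of B fragments is the solution of
#' `n_b * mean_len_b = f/(1-f) * n_a * mean_len_a` under
#' `n_a + n_b = n_fragments`, with stochastic rounding so the expectation is
#' exact even when the count is small.
#'
#' @param pop_a,pop_b Source [fragment_population()]s.
#' @param mass_fraction_b Target mass fraction of `pop_b` in `[0, 1]`.
#' @param total_mass_ng Total DNA mass of the mixture in ng (metadata,
#'   stored as the `total_mass_ng` attribute; default 1 ng).
#' @param n_fragments Number of fragments in the mixture; defaults to the
#'   summed size of the two sources.
#' @param seed Integer seed.
#' @param sample_id Sample identifier for the mixture.
#'
#' @return A [fragment_population()] with an additional `source` column
#'   (`"A"`/`"B"`) and attributes `total_mass_ng` and `hmw_mass_fraction`
#'   (= `mass_fraction_b`).
#' @export
mix_by_mass <- function(pop_a, pop_b, mass_fraction_b, total_mass_ng = 1,
                        n_fragments = NULL, seed = 1,
                        sample_id = "mixture") {
  for (p in list(pop_a, pop_b)) {
    assert_columns(p, "length_bp", "a fragment population")
    if (nrow(p) == 0) abort("Source populations must be non-empty.")
  }
  assert_scalar_number(mass_fraction_b, "mass_fraction_b", min = 0)
  if (mass_fraction_b > 1) abort("`mass_fraction_b` must be <= 1.")
  assert_scalar_number(total_mass_ng, "total_mass_ng", min = 0, strict = TRUE)
  n_fragments <- n_fragments %||% (nrow(pop_a) + nrow(pop_b))
  assert_scalar_number(n_fragments, "n_fragments", min = 1)
  n_fragments <- as.integer(n_fragments)

  mean_a <- mean(pop_a$length_bp)
  mean_b <- mean(pop_b$length_bp)
  f <- mass_fraction_b
  if (f >= 1) {
    n_b_exact <- n_fragments
  } else {
    # n_b/n_a ratio that puts fraction f of the bp mass in B
    r <- (f / (1 - f)) * (mean_a / mean_b)
    n_b_exact <- n_fragments * r / (1 + r)
  }

  out <- local_seed(seed, {
    n_b <- floor(n_b_exact) +
      rbinom(1, 1, n_b_exact - floor(n_b_exact))
    n_b <- min(n_b, n_fragments)
    n_a <- n_fragments - n_b
    len_a <- if (n_a > 0) {
      sample(pop_a$length_bp, n_a, replace = TRUE)
    } else integer(0)
    len_b <- if (n_b > 0) {
      sample(pop_b$length_bp, n_b, replace = TRUE)
    } else integer(0)
    tibble(
      length_bp = c(len_a, len_b),
      source = rep(c("A", "B"), c(n_a, n_b))
    )
  })
  mix <- fragment_population(out$length_bp, sample_id = sample_id,
                             group_label = "mixture")
  mix$source <- out$source
  attr(mix, "total_mass_ng") <- total_mass_ng
  attr(mix, "hmw_mass_fraction") <- mass_fraction_b
  mix
}

#' Simulate the HMW-contamination calibration panel
#'
#' Builds the panel of standard samples used to calibrate the contamination
#' assay: sheared ~170 bp DNA mixed with intact high-molecular-weight (HMW)
#' genomic DNA at known HMW mass fractions (default 1%, 5%, 25% and 50%).
#'
#' @param hmw_fractions Strictly increasing HMW mass fractions in `[0, 1]`.
#' @param n_fragments Fragments per standard.
#' @param total_mass_ng DNA mass per standard in ng.
#' @param seed Integer seed.
#'
#' @return A stacked [fragment_population()] tibble with one standard per
#'   `sample_id` (e.g. `"std_5pct"`) and a `hmw_fraction` column giving the
#'   true mass fraction of each row's sample.
#' @export
simulate_panel <- function(hmw_fractions = c(0.01, 0.05, 0.25, 0.50),
                           n_fragments = 20000, total_mass_ng = 1,
                           seed = 1) {
  if (length(hmw_fractions) < 1 || any(hmw_fractions < 0) ||
      any(hmw_fractions > 1) || is.unsorted(hmw_fractions, strictly = TRUE)) {
    abort("`hmw_fractions` must be strictly increasing fractions in [0, 1].")
  }
  seeds <- derive_seeds(seed, 2 + length(hmw_fractions))
  sheared <- simulate_fragments(sheared_standard_spec(), n_fragments,
                                seed = seeds[1], sample_id = "sheared",
                                group_label = "standard")
  hmw <- simulate_fragments(hmw_dna_spec(), max(200L, n_fragments %/% 20),
                            seed = seeds[2], sample_id = "hmw",
                            group_label = "standard")
  stds <- purrr::map2(hmw_fractions, seq_along(hmw_fractions), function(f, i) {
    id <- sprintf("std_%gpct", 100 * f)
    m <- mix_by_mass(sheared, hmw, mass_fraction_b = f,
                     total_mass_ng = total_mass_ng,
                     n_fragments = n_fragments,
                     seed = seeds[2 + i], sample_id = id)
    m$group_label <- "standard"
    m$hmw_fraction <- f
    m
  })
  out <- list_rbind(stds)
  attr(out, "total_mass_ng") <- total_mass_ng
  new_fragment_population(out)
}
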