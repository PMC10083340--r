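#' Simulate a droplet digital PCR well
#'
#' Forward model for droplet digital PCR: the expected number of amplifiable
#' target copies in the reaction is computed with
#' [expected_amplifiable_copies()], converted to a mean per-droplet load
#' using the droplet volume, and partitioned into droplets (each copy lands
#' in a uniformly chosen droplet, so droplet occupancy is Poisson). The
#' returned well carries total and positive droplet counts, ready for
#' [poisson_quantify()].
#'
#' @param pop A [fragment_population()].
#' @param assay An [amplicon_assay()].
#' @param input_mass_ng DNA mass loaded into the reaction, ng.
#' @param n_droplets Number of droplets generated (>= 1).
#' @param seed Integer seed.
#' @param droplet_volume_nl Droplet volume in nL.
#' @param reaction_volume_ul Reaction volume in uL; droplets sample the
#'   reaction at `droplet_volume_nl` each, so the mean load per droplet is
#'   `copies / reaction_volume * droplet_volume`.
#'
#' @return A one-row droplet-plate tibble with columns `sample_id`,
#'   `assay_name`, `n_total_droplets`, `n_positive`, `input_mass_ng`,
#'   `droplet_volume_nl`.
#' @export
simulate_droplets <- function(pop, assay, input_mass_ng, n_droplets = 20000,
                              seed = 1,
                              droplet_volume_nl = DEFAULT_DROPLET_VOLUME_NL,
                              reaction_volume_ul = DEFAULT_REACTION_VOLUME_UL) {
  assert_scalar_number(n_droplets, "n_droplets", min = 1)
  assert_scalar_number(droplet_volume_nl, "droplet_volume_nl", min = 0,
                       strict = TRUE)
  assert_scalar_number(reaction_volume_ul, "reaction_volume_ul", min = 0,
                       strict = TRUE)
  n_droplets <- as.integer(n_droplets)
  copies <- expected_amplifiable_copies(pop, assay, input_mass_ng)
  copies_per_ul <- copies / reaction_volume_ul
  lambda <- copies_per_ul * droplet_volume_nl / 1000
  n_positive <- local_seed(seed, {
    n_copies <- rpois(1, lambda * n_droplets)
    if (n_copies == 0) {
      0L
    } else {
      length(unique(sample.int(n_droplets, n_copies, replace = TRUE)))
    }
  })
  tibble(
    sample_id = pop$sample_id[1],
    assay_name = assay$name,
    n_total_droplets = n_droplets,
    n_positive = as.integer(n_positive),
    input_mass_ng = input_mass_ng,
    droplet_volume_nl = droplet_volume_nl
  )
}

#' Simulate qPCR quantification cycles
#'
#' Forward model for real-time PCR: `Cq = intercept - log_E(copies) + noise`
#' where `E` is the per-cycle amplification efficiency (2 = perfect
#' doubling) and copies are the expected amplifiable copies for the assay.
#' With zero copies the reaction never crosses threshold and the Cq is
#' reported as a non-detect (`NA`).
#'
#' @inheritParams simulate_droplets
#' @param efficiency Fold amplification per cycle, must be > 1.
#' @param noise_sd Replicate noise on Cq, in cycles.
#' @param n_replicates Number of technical replicates.
#' @param intercept_cq Cq of a single-copy reaction (calibration intercept).
#'
#' @return Cq-table rows: `sample_id`, `assay_name`, `replicate_id`, `cq`
#'   (`NA` = non-detect), `efficiency`.
#' @export
simulate_cq <- function(pop, assay, input_mass_ng, efficiency = 2,
                        noise_sd = 0, seed = 1, n_replicates = 1,
                        intercept_cq = 37) {
  if (!is.numeric(efficiency) || efficiency <= 1) {
    abort("`efficiency` must be > 1 fold per cycle.")
  }
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  copies <- expected_amplifiable_copies(pop, assay, input_mass_ng)
  cq_from_copies(copies, assay_name = assay$name,
                 sample_id = pop$sample_id[1], efficiency = efficiency,
                 noise_sd = noise_sd, seed = seed,
                 n_replicates = n_replicates, intercept_cq = intercept_cq)
}

# Shared Cq forward model on a known copy number; used by simulate_cq and
# by the idealized panel generator.
cq_from_copies <- function(copies, assay_name, sample_id, efficiency = 2,
                           noise_sd = 0, seed = 1, n_replicates = 1,
                           intercept_cq = 37) {
  n_replicates <- as.integer(n_replicates)
  cq0 <- if (copies <= 0) NA_real_ else {
    intercept_cq - log(copies) / log(efficiency)
  }
  noise <- if (noise_sd > 0) {
    local_seed(seed, rnorm(n_replicates, 0, noise_sd))
  } else {
    rep(0, n_replicates)
  }
  tibble(
    sample_id = sample_id,
    assay_name = assay_name,
    replicate_id = seq_len(n_replicates),
    cq = if (is.na(cq0)) rep(NA_real_, n_replicates) else cq0 + noise,
    efficiency = efficiency
  )
}

#' Simulate qPCR data for the calibration panel
#'
#' Generates Cq rows for the standards panel under one of two forward
#' models:
#'
#' * `idealized = TRUE`: the 106 bp amplicon amplifies from *all* DNA mass
#'   and the 612 bp amplicon only from the HMW (unfragmented) mass. Under
#'   this detectability assumption the delta-delta-Cq score recovers the
#'   panel mass fractions exactly (noiseless case), which is what makes the
#'   panel a calibration ladder.
#' * `idealized = FALSE`: amplifiable copies are computed from simulated
#'   panel fragment populations through the length-containment model; short
#'   fragments then contribute slightly to the 612 bp signal's denominator
#'   deficit, biasing recovered percentages upward at low fractions.
#'
#' @param hmw_fractions Strictly increasing HMW mass fractions.
#' @param efficiency Amplification efficiency (fold/cycle).
#' @param noise_sd Replicate Cq noise, cycles.
#' @param n_replicates Technical replicates per assay.
#' @param seed Integer seed.
#' @param idealized Use the idealized detectability model (see above).
#' @param total_mass_ng DNA input per reaction, ng.
#' @param assays Multicopy assay pair, as from [default_multicopy_assays()].
#' @param n_fragments Fragments per simulated standard
#'   (`idealized = FALSE` only).
#'
#' @return A Cq table covering all standards and both assays; sample ids are
#'   `std_<percent>pct`.
#' @export
simulate_panel_cq <- function(hmw_fractions = c(0.01, 0.05, 0.25, 0.50),
                              efficiency = 2, noise_sd = 0,
                              n_replicates = 2, seed = 1, idealized = TRUE,
                              total_mass_ng = 1,
                              assays = default_multicopy_assays(),
                              n_fragments = 20000) {
  if (is.unsorted(hmw_fractions, strictly = TRUE)) {
    abort("`hmw_fractions` must be strictly increasing.")
  }
  seeds <- derive_seeds(seed, 2 * length(hmw_fractions) + 1)
  short <- assays$short_106
  long <- assays$long_612
  if (idealized) {
    total_copies <- (total_mass_ng / HAPLOID_GENOME_MASS_NG) *
      short$copies_per_haploid_genome
    rows <- purrr::map(seq_along(hmw_fractions), function(i) {
      f <- hmw_fractions[i]
      id <- sprintf("std_%gpct", 100 * f)
      bind_rows(
        cq_from_copies(total_copies, short$name, id, efficiency, noise_sd,
                       seed = seeds[2 * i - 1], n_replicates = n_replicates),
        cq_from_copies(f * total_copies, long$name, id, efficiency, noise_sd,
                       seed = seeds[2 * i], n_replicates = n_replicates)
      )
    })
    out <- list_rbind(rows)
  } else {
    panel <- simulate_panel(hmw_fractions, n_fragments = n_fragments,
                            total_mass_ng = total_mass_ng,
                            seed = seeds[length(seeds)])
    rows <- purrr::map(seq_along(hmw_fractions), function(i) {
      f <- hmw_fractions[i]
      id <- sprintf("std_%gpct", 100 * f)
      std <- filter(panel, .data$sample_id == id)
      std <- new_fragment_population(std)
      bind_rows(
        simulate_cq(std, short, total_mass_ng, efficiency, noise_sd,
                    seed = seeds[2 * i - 1], n_replicates = n_replicates),
        simulate_cq(std, long, total_mass_ng, efficiency, noise_sd,
                    seed = seeds[2 * i], n_replicates = n_replicates)
      )
    })
    out <- list_rbind(rows)
  }
  out
}

#' Render a synthetic electropherogram from a fragment population
#'
#' Emulates an automated-electrophoresis size trace: each fragment
#' contributes mass proportional to its length, smeared over the size axis
#' with a gaussian kernel. The resulting `mass_density` integrates (over the
#' grid) to the population's total base-pair content, provided the grid
#' spans the fragment lengths.
#'
#' @param pop A [fragment_population()].
#' @param size_grid Ascending size grid in bp (default 1 bp resolution to
#'   1,000 bp).
#' @param bandwidth Gaussian kernel bandwidth in bp.
#' @return An electropherogram tibble (class `electropherogram`) with
#'   columns `size_bp`, `mass_density`, `sample_id`.
#' @export
render_electropherogram <- function(pop, size_grid = seq(1, 1000, by = 1),
                                    bandwidth = 8) {
  assert_columns(pop, "length_bp", "a fragment population")
  if (length(size_grid) < 2 || is.unsorted(size_grid, strictly = TRUE)) {
    abort("`size_grid` must be an ascending grid with at least 2 points.")
  }
  assert_scalar_number(bandwidth, "bandwidth", min = 0, strict = TRUE)
  counts <- pop |>
    count(.data$length_bp, name = "n_frag")
  # mass contributed at each unique length: count * length (bp units)
  mass <- counts$n_frag * counts$length_bp
  dens <- as.vector(
    outer(size_grid, counts$length_bp,
          function(x, l) dnorm(x, mean = l, sd = bandwidth)) %*% mass
  )
  eg <- tibble(
    size_bp = as.numeric(size_grid),
    mass_density = pmax(0, dens),
    sample_id = pop$sample_id[1]
  )
  class(eg) <- c("electropherogram", class(eg))
  eg
}
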