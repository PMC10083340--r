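# Small fixtures shared across test files; everything is built in code.

# A degenerate population: every fragment exactly `len` bp.
uniform_pop <- function(len, n = 100, sample_id = "uniform") {
  fragment_population(rep(len, n), sample_id = sample_id)
}

# Droplet-plate row shorthand.
plate_row <- function(n_total, n_positive, sample_id = "S1",
                      assay_name = "assay", input_mass_ng = 1,
                      droplet_volume_nl = 0.85) {
  tibble::tibble(
    sample_id = sample_id, assay_name = assay_name,
    n_total_droplets = n_total, n_positive = n_positive,
    input_mass_ng = input_mass_ng,
    droplet_volume_nl = droplet_volume_nl
  )
}

# Noiseless Cq rows for one sample at given short/long copy numbers
# (efficiency 2, single replicate).
cq_rows <- function(sample_id, copies_short, copies_long,
                    intercept = 37) {
  tibble::tibble(
    sample_id = sample_id,
    assay_name = c("short_106", "long_612"),
    replicate_id = 1L,
    cq = intercept - log2(c(copies_short, copies_long)),
    efficiency = 2
  )
}
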