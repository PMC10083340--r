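#' Define a PCR amplicon assay
#'
#' An assay is a named amplicon with its length, its genomic copy number per
#' haploid genome (multicopy targets such as non-coding RNA gene families
#' raise sensitivity), its reporter dye, and the chromatin-region label it
#' interrogates.
#'
#' @param name Assay name, e.g. `"OCR1_short"` or `"long_612"`.
#' @param amplicon_length Amplicon length in bp (>= 1).
#' @param copies_per_haploid_genome Target copies per haploid genome (>= 1).
#' @param dye Reporter dye, `"FAM"` or `"HEX"`.
#' @param region_label One of `"OCR1"`, `"OCR2"`, `"CCR"`, `"multicopy"`,
#'   or `NA`.
#'
#' @return An object of class `amplicon_assay`.
#' @examples
#' amplicon_assay("long_612", 612, copies_per_haploid_genome = 25,
#'                dye = "HEX", region_label = "multicopy")
#' @export
amplicon_assay <- function(name, amplicon_length,
                           copies_per_haploid_genome = 1,
                           dye = c("FAM", "HEX"),
                           region_label = NA_character_) {
  dye <- match.arg(dye)
  assert_scalar_number(amplicon_length, "amplicon_length", min = 1)
  assert_scalar_number(copies_per_haploid_genome,
                       "copies_per_haploid_genome", min = 1)
  if (!is.na(region_label) &&
      !region_label %in% c("OCR1", "OCR2", "CCR", "multicopy")) {
    abort("`region_label` must be OCR1, OCR2, CCR, multicopy or NA.")
  }
  structure(
    list(
      name = as.character(name),
      amplicon_length = as.integer(amplicon_length),
      copies_per_haploid_genome = as.numeric(copies_per_haploid_genome),
      dye = dye,
      region_label = region_label
    ),
    class = "amplicon_assay"
  )
}

#' @export
print.amplicon_assay <- function(x, ...) {
  cat(sprintf(
    "<amplicon_assay> %s: %d bp, %g copies/haploid genome, %s%s\n",
    x$name, x$amplicon_length, x$copies_per_haploid_genome, x$dye,
    if (is.na(x$region_label)) "" else paste0(", region ", x$region_label)
  ))
  invisible(x)
}

#' Default assay sets
#'
#' `default_region_assays()` returns the short/long assay pairs for the
#' three chromatin regions (OCR1, OCR2 open chromatin; CCR pericentromeric
#' closed chromatin). The designed short/long amplicon lengths are not
#' published in the main text; the defaults 70 bp ("short", < 80 bp) and
#' 160 bp ("long", > 150 bp) are placeholders in that spirit and can be
#' overridden. `default_multicopy_assays()` returns the 106 bp / 612 bp
#' multicopy qPCR pair used for HMW contamination screening (~25 primer
#' annealing sites per haploid genome).
#'
#' @param short_bp,long_bp Short/long amplicon lengths in bp.
#' @param copies Copies per haploid genome for the multicopy pair.
#' @return A named list of [amplicon_assay()] objects.
#' @name default_assays
NULL

#' @rdname default_assays
#' @export
default_region_assays <- function(short_bp = 70, long_bp = 160) {
  regions <- c("OCR1", "OCR2", "CCR")
  out <- list()
  for (r in regions) {
    out[[paste0(r, "_short")]] <- amplicon_assay(
      paste0(r, "_short"), short_bp, dye = "FAM", region_label = r)
    out[[paste0(r, "_long")]] <- amplicon_assay(
      paste0(r, "_long"), long_bp, dye = "HEX", region_label = r)
  }
  out
}

#' @rdname default_assays
#' @export
default_multicopy_assays <- function(copies = 25) {
  list(
    short_106 = amplicon_assay("short_106", 106,
                               copies_per_haploid_genome = copies,
                               dye = "FAM", region_label = "multicopy"),
    long_612 = amplicon_assay("long_612", 612,
                              copies_per_haploid_genome = copies,
                              dye = "HEX", region_label = "multicopy")
  )
}

#' Probability that a fragment contains an intact amplicon
#'
#' A fragment can template a PCR product only if it fully spans the
#' amplicon. Under uniform random placement of fragmentation breakpoints, a
#' fragment of length `L` that covers the amplicon's first base contains the
#' whole `A`-bp amplicon with probability `max(0, L - A + 1) / L`: of the
#' `L` placements of the fragment that cover the first amplicon base,
#' `L - A + 1` also cover the last. The probability is 0 when `L < A` and
#' tends to 1 as `L/A` grows, which is what makes short amplicons report
#' (nearly) total copies while long amplicons report only fragments of at
#' least mononucleosomal length.
#'
#' @param fragment_length Fragment length(s) `L` in bp (>= 1); vectorized.
#' @param amplicon_length Amplicon length `A` in bp (>= 1).
#' @return Containment probabilities in `[0, 1]`.
#' @examples
#' containment_probability(170, 106)  # 65/170
#' containment_probability(100, 612)  # 0
#' @export
containment_probability <- function(fragment_length, amplicon_length) {
  if (!is.numeric(fragment_length) || any(!is.finite(fragment_length)) ||
      any(fragment_length < 1)) {
    abort("`fragment_length` values must be finite and >= 1.")
  }
  assert_scalar_number(amplicon_length, "amplicon_length", min = 1)
  L <- fragment_length
  A <- amplicon_length
  pmax(0, L - A + 1) / L
}

#' Brute-force containment oracle
#'
#' Reference simulation for [containment_probability()]: a fragment of
#' length `L` is placed uniformly at random among the `L` positions that
#' cover the first base of a fixed `A`-bp window (the placements a uniform
#' random fragmentation of a long molecule induces, conditioned on covering
#' that base), and the fraction of placements containing the whole window is
#' returned. Kept exported as the independent check of the closed form.
#'
#' @param fragment_length Fragment length `L` in bp.
#' @param amplicon_length Amplicon length `A` in bp.
#' @param n_trials Monte-Carlo trials.
#' @param seed Integer seed.
#' @return Estimated containment probability.
#' @export
simulate_containment_probability <- function(fragment_length,
                                             amplicon_length,
                                             n_trials = 1e5, seed = 1) {
  assert_scalar_number(fragment_length, "fragment_length", min = 1)
  assert_scalar_number(amplicon_length, "amplicon_length", min = 1)
  L <- as.integer(fragment_length)
  A <- as.integer(amplicon_length)
  local_seed(seed, {
    # window occupies positions 1..A; the L fragment starts covering
    # position 1 are (2-L)..1; containment needs start + L - 1 >= A
    start <- sample.int(L, n_trials, replace = TRUE) - L + 1L
    mean(start + L - 1 >= A)
  })
}

#' Expected amplifiable copies in a sample
#'
#' Converts input DNA mass to haploid genome equivalents (3.3 pg per haploid
#' genome, ~303 copies per ng), scales by the assay's genomic copy number,
#' and weights by the probability that the fragment carrying a target locus
#' fully contains the amplicon. That probability is averaged over the
#' *length-biased* empirical distribution, `sum(L * f(L) * p(L)) /
#' sum(L * f(L))`: a genomic position falls on a fragment with probability
#' proportional to the fragment's length, so long molecules carry
#' correspondingly more target loci per fragment. (For a single fragment
#' length the two weightings coincide, e.g. 1 ng of uniformly 170 bp DNA
#' and a single-copy 106 bp assay give `303 * 65/170` copies.)
#'
#' @param pop A [fragment_population()] (its `length_bp` column provides the
#'   empirical length distribution).
#' @param assay An [amplicon_assay()].
#' @param input_mass_ng DNA mass in the reaction, ng.
#' @return Expected number of amplifiable target copies (non-negative).
#' @examples
#' pop <- fragment_population(rep(170, 100))
#' a106 <- amplicon_assay("a106", 106)
#' expected_amplifiable_copies(pop, a106, input_mass_ng = 1) # 303 * 65/170
#' @export
expected_amplifiable_copies <- function(pop, assay, input_mass_ng) {
  assert_columns(pop, "length_bp", "a fragment population")
  if (nrow(pop) == 0) abort("Population must be non-empty.")
  if (!inherits(assay, "amplicon_assay")) {
    abort("`assay` must be an amplicon_assay object.")
  }
  assert_scalar_number(input_mass_ng, "input_mass_ng", min = 0)
  genome_equivalents <- input_mass_ng / HAPLOID_GENOME_MASS_NG
  L <- as.numeric(pop$length_bp)
  p <- containment_probability(L, assay$amplicon_length)
  p_contain <- sum(L * p) / sum(L)
  genome_equivalents * assay$copies_per_haploid_genome * p_contain
}
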