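#' Coerce a size/concentration trace to an electropherogram
#'
#' @param df Data frame with a strictly increasing size column (bp) and a
#'   non-negative mass-concentration column.
#' @param size_col,density_col Column names holding sizes and mass density.
#' @param sample_id Sample identifier (used if the table has none).
#' @return A tibble of class `electropherogram` with columns `size_bp`,
#'   `mass_density`, `sample_id`.
#' @export
as_electropherogram <- function(df, size_col = "size_bp",
                                density_col = "mass_density",
                                sample_id = "sample") {
  assert_columns(df, c(size_col, density_col), "an electropherogram table")
  eg <- tibble(
    size_bp = as.numeric(df[[size_col]]),
    mass_density = as.numeric(df[[density_col]]),
    sample_id = if ("sample_id" %in% names(df)) {
      as.character(df$sample_id)
    } else {
      sample_id
    }
  )
  if (nrow(eg) < 2 || is.unsorted(eg$size_bp, strictly = TRUE)) {
    abort("The size grid must be strictly increasing with >= 2 points.")
  }
  if (any(!is.finite(eg$mass_density)) || any(eg$mass_density < 0)) {
    abort("Mass densities must be finite and non-negative.")
  }
  class(eg) <- c("electropherogram", class(eg))
  eg
}

#' Convert a mass-density trace to molar density
#'
#' Electrophoresis reports mass concentration per size; molarity weights
#' long fragments down because one mole of `L`-bp DNA weighs
#' `L * 650` g (650 g/mol per base pair). The molar density at size `L` is
#' `mass_density(L) / (L * mass_per_bp)`: a flat mass trace has molar
#' density proportional to `1/L`, and equal masses at 100 and 200 bp differ
#' two-fold in molarity.
#'
#' @param eg An electropherogram (see [as_electropherogram()]).
#' @param mass_per_bp Molar mass per base pair, g/mol/bp.
#' @return The electropherogram with an added `molar_density` column.
#' @export
molar_density <- function(eg, mass_per_bp = MASS_PER_BP_G_MOL) {
  eg <- as_electropherogram(eg)
  eg$molar_density <- eg$mass_density / (eg$size_bp * mass_per_bp)
  eg
}

# Trapezoidal integral of `y` over the part of the grid at or above `cut`,
# interpolating the trace at the cut point.
integral_above <- function(size_bp, y, cut) {
  if (cut <= size_bp[1]) return(pracma::trapz(size_bp, y))
  if (cut >= size_bp[length(size_bp)]) return(0)
  y_cut <- approx(size_bp, y, xout = cut)$y
  keep <- size_bp > cut
  pracma::trapz(c(cut, size_bp[keep]), c(y_cut, y[keep]))
}

#' Molarity ratio of fragments above two size cutoffs
#'
#' The cross-validation statistic for the qPCR contamination score: the
#' ratio of the molarity of fragments longer than `short_cut` (default
#' 106 bp, everything the short amplicon can report) to the molarity of
#' fragments longer than `long_cut` (default 612 bp, the HMW fraction the
#' long amplicon reports). Both integrals are above-cut trapezoids on the
#' molar-density trace, so the ratio is invariant to rescaling the whole
#' trace. A clean mononucleosomal sample has (numerically) no mass above
#' 612 bp; that no-HMW case is reported as the `Inf` sentinel rather than
#' an error.
#'
#' @param eg An electropherogram; [molar_density()] is applied if needed.
#' @param short_cut,long_cut Size cutoffs in bp, `short_cut < long_cut`,
#'   both inside the grid.
#' @param mass_per_bp Molar mass per base pair, g/mol/bp.
#' @return The scalar molarity ratio (>= 1), or `Inf` when no molarity lies
#'   above `long_cut`.
#' @export
molarity_ratio <- function(eg, short_cut = 106, long_cut = 612,
                           mass_per_bp = MASS_PER_BP_G_MOL) {
  if (!"molar_density" %in% names(eg)) {
    eg <- molar_density(eg, mass_per_bp = mass_per_bp)
  }
  if (short_cut >= long_cut) abort("`short_cut` must be < `long_cut`.")
  rng <- range(eg$size_bp)
  if (short_cut < rng[1] || long_cut > rng[2]) {
    abort("Both cutoffs must lie inside the size grid.")
  }
  num <- integral_above(eg$size_bp, eg$molar_density, short_cut)
  den <- integral_above(eg$size_bp, eg$molar_density, long_cut)
  if (den <= 0) return(Inf)
  num / den
}

#' Locate nucleosomal degradation peaks
#'
#' Searches smoothed density for local maxima inside the di- and
#' tri-nucleosome windows (defaults 360-400 bp and 540-600 bp). cfDNA from
#' blood stored past the protective window of collection tubes develops
#' peaks there, reflecting DNA wrapping two and three nucleosomes released
#' by apoptosing blood cells. Smoothing is a Savitzky-Golay filter
#' (quadratic, `smooth_window` points) before the maxima search, so peak
#' positions are invariant to rescaling the trace.
#'
#' @param eg An electropherogram.
#' @param windows List of `c(low, high)` size windows in bp.
#' @param smooth_window Savitzky-Golay window length in grid points (odd).
#' @param on Search the `"mass"` or `"molar"` density.
#' @return A tibble with one row per window in which a local maximum was
#'   found: `window_low`, `window_high`, `peak_bp`, `peak_density`. Windows
#'   without a local maximum are absent.
#' @export
find_nucleosomal_peaks <- function(eg,
                                   windows = list(c(360, 400), c(540, 600)),
                                   smooth_window = 15,
                                   on = c("mass", "molar")) {
  on <- match.arg(on)
  eg <- if (on == "molar") molar_density(eg) else as_electropherogram(eg)
  y <- if (on == "molar") eg$molar_density else eg$mass_density
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
  if (length(y) > smooth_window) {
    y <- signal::sgolayfilt(y, p = 2, n = smooth_window)
  }
  x <- eg$size_bp
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  out <- purrr::map(windows, function(w) {
    idx <- which(is_max & x >= w[1] & x <= w[2])
    if (length(idx) == 0) return(NULL)
    best <- idx[which.max(y[idx])]
    tibble(window_low = w[1], window_high = w[2],
           peak_bp = x[best], peak_density = y[best])
  })
  compact <- purrr::compact(out)
  if (length(compact) == 0) {
    return(tibble(window_low = numeric(), window_high = numeric(),
                  peak_bp = numeric(), peak_density = numeric()))
  }
  list_rbind(compact)
}

#' Read an electropherogram trace TSV
#'
#' Expected columns: `size_bp` and `concentration` (mass concentration per
#' size), tab-separated, matching common electropherogram exports.
#'
#' @param path TSV file path.
#' @param sample_id Sample identifier to attach.
#' @return An `electropherogram` tibble.
#' @export
read_trace_tsv <- function(path, sample_id = basename(path)) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  nm <- names(df)
  nm[nm == "concentration"] <- "mass_density"
  names(df) <- nm
  as_electropherogram(df, sample_id = sample_id)
}
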