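#' Absolute quantification from droplet counts
#'
#' Converts per-well droplet counts to absolute copy concentrations by the
#' Poisson occupancy relation: with a fraction `p` of positive droplets the
#' mean copies per droplet is `lambda = -ln(1 - p)`, so
#' `copies_per_ul = lambda / droplet_volume` and
#' `copies_per_ng = copies_per_ul * reaction_volume / input_mass_ng`.
#' The 95% confidence interval is a Wilson score interval on `p` propagated
#' through the (monotone) `-ln(1 - p)` transform; the Wilson interval is
#' used for its sane behaviour at `p` near 0 and 1.
#'
#' Saturated wells (every droplet positive) leave `lambda` undefined: the
#' estimate and upper bound are reported as `Inf` with `saturated_flag`
#' set, never as a silent number. Wells with fewer than `min_droplets`
#' accepted droplets are flagged low-quality but retained.
#'
#' @param plate Droplet-plate tibble with columns `sample_id`, `assay_name`,
#'   `n_total_droplets`, `n_positive`, `input_mass_ng`, and optionally
#'   `droplet_volume_nl` (default 0.85 nL).
#' @param reaction_volume_ul Reaction volume used to convert concentration
#'   to copies per ng of input.
#' @param conf_level Confidence level for the interval.
#' @param min_droplets Accepted-droplet threshold below which a well is
#'   flagged low-quality.
#'
#' @return A tibble with one row per well: `sample_id`, `assay_name`,
#'   `p_positive`, `lambda`, `copies_per_ul`, `copies_per_ng`, `ci_low`,
#'   `ci_high` (both on the copies-per-ng scale), `saturated_flag`,
#'   `low_quality_flag`.
#' @examples
#' plate <- tibble::tibble(sample_id = "S1", assay_name = "a",
#'                         n_total_droplets = 20000, n_positive = 12642,
#'                         input_mass_ng = 1)
#' poisson_quantify(plate)
#' @export
poisson_quantify <- function(plate,
                             reaction_volume_ul = DEFAULT_REACTION_VOLUME_UL,
                             conf_level = 0.95, min_droplets = 8000) {
  assert_columns(plate, c("sample_id", "assay_name", "n_total_droplets",
                          "n_positive", "input_mass_ng"), "a droplet plate")
  if (nrow(plate) == 0) return(empty_quant_result())
  if (!"droplet_volume_nl" %in% names(plate)) {
    plate$droplet_volume_nl <- DEFAULT_DROPLET_VOLUME_NL
  }
  with(plate, {
    if (any(n_total_droplets < 1)) abort("`n_total_droplets` must be >= 1.")
    if (any(n_positive < 0 | n_positive > n_total_droplets)) {
      abort("`n_positive` must lie in [0, n_total_droplets].")
    }
    if (any(input_mass_ng <= 0)) abort("`input_mass_ng` must be positive.")
  })

  z <- qnorm(1 - (1 - conf_level) / 2)
  n <- plate$n_total_droplets
  x <- plate$n_positive
  p <- x / n
  # Wilson score interval on the positive fraction
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  p_lo <- pmax(0, centre - half)
  p_hi <- pmin(1, centre + half)
  p_lo[x == 0] <- 0 # exact lower bound at zero positives

  lam <- ifelse(p < 1, -log1p(-p), Inf)
  lam_lo <- -log1p(-p_lo)
  lam_hi <- ifelse(p_hi < 1, -log1p(-p_hi), Inf)

  vol_ul <- plate$droplet_volume_nl / 1000
  to_per_ng <- reaction_volume_ul / plate$input_mass_ng
  tibble(
    sample_id = plate$sample_id,
    assay_name = plate$assay_name,
    p_positive = p,
    lambda = lam,
    copies_per_ul = lam / vol_ul,
    copies_per_ng = lam / vol_ul * to_per_ng,
    ci_low = lam_lo / vol_ul * to_per_ng,
    ci_high = lam_hi / vol_ul * to_per_ng,
    saturated_flag = x == n,
    low_quality_flag = n < min_droplets
  )
}

empty_quant_result <- function() {
  tibble(
    sample_id = character(), assay_name = character(),
    p_positive = numeric(), lambda = numeric(), copies_per_ul = numeric(),
    copies_per_ng = numeric(), ci_low = numeric(), ci_high = numeric(),
    saturated_flag = logical(), low_quality_flag = logical()
  )
}

#' Short/long fragmentation summary per region
#'
#' Pairs the short- and long-amplicon copy estimates for each sample and
#' region and derives the two fragmentation statistics: the difference
#' (short minus long copies per ng — how many fragments are long enough for
#' the short but not the long amplicon) and the ratio (short over long — a
#' unitless integrity index that rises with fragmentation).
#'
#' @param estimates A tibble as returned by [poisson_quantify()], with
#'   additional columns `region_label` and `target_class` (values `"short"`
#'   / `"long"`); alternatively supply `target_class` via
#'   `derive_target_class()` naming conventions (`*_short` / `*_long`
#'   assay names).
#'
#' @return A tibble with one row per sample x region: `sample_id`,
#'   `region_label`, `short_copies_per_ng`, `long_copies_per_ng`,
#'   `difference`, `ratio` (`NA` with `ratio_undefined = TRUE` when the long
#'   estimate is 0).
#' @export
fragmentation_summary <- function(estimates) {
  assert_columns(estimates, c("sample_id", "copies_per_ng"),
                 "an estimates table")
  if (!"target_class" %in% names(estimates)) {
    estimates <- derive_target_class(estimates)
  }
  if (!"region_label" %in% names(estimates)) {
    estimates$region_label <- sub("_(short|long)$", "",
                                  estimates$assay_name)
  }
  bad <- setdiff(unique(estimates$target_class), c("short", "long"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown target_class value(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  wide <- estimates |>
    select("sample_id", "region_label", "target_class", "copies_per_ng") |>
    tidyr::pivot_wider(names_from = "target_class",
                       values_from = "copies_per_ng")
  assert_columns(wide, c("short", "long"),
                 "the paired short/long estimates table")
  wide |>
    transmute(
      sample_id = .data$sample_id,
      region_label = .data$region_label,
      short_copies_per_ng = .data$short,
      long_copies_per_ng = .data$long,
      difference = .data$short - .data$long,
      ratio = ifelse(.data$long > 0, .data$short / .data$long, NA_real_),
      ratio_undefined = .data$long <= 0
    )
}

# Infer short/long target class from `*_short` / `*_long` assay names.
derive_target_class <- function(estimates) {
  assert_columns(estimates, "assay_name", "an estimates table")
  estimates |>
    mutate(target_class = dplyr::case_when(
      grepl("short", .data$assay_name) ~ "short",
      grepl("long", .data$assay_name) ~ "long",
      TRUE ~ NA_character_
    ))
}

#' Read a droplet-plate CSV
#'
#' Expected header: `sample_id,assay,n_total,n_positive,input_mass_ng`
#' (optionally `droplet_volume_nl`). Column names are normalised to the
#' package's droplet-plate layout.
#'
#' @param path CSV file path.
#' @return A droplet-plate tibble for [poisson_quantify()].
#' @export
read_droplet_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  nm <- names(df)
  nm[nm == "assay"] <- "assay_name"
  nm[nm == "n_total"] <- "n_total_droplets"
  names(df) <- nm
  assert_columns(df, c("sample_id", "assay_name", "n_total_droplets",
                       "n_positive", "input_mass_ng"),
                 sprintf("'%s'", path))
  df
}
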