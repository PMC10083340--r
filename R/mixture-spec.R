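#' Define a fragment-length mixture
#'
#' A mixture specification describes a cfDNA fragment-length distribution as
#' a weighted mixture of simple component families. Two families are
#' supported: `"gaussian"` (a normal distribution truncated at 1 bp, suitable
#' for nucleosome-protected peaks) and `"lognormal"` (suitable for
#' high-molecular-weight genomic DNA, where `location_bp` is the median
#' length in bp and `scale` is the log-space standard deviation).
#'
#' @param weight Numeric vector of non-negative component weights; they must
#'   sum to 1.
#' @param family Character vector, each `"gaussian"` or `"lognormal"`.
#' @param location_bp Component location in bp: the mean of the (untruncated)
#'   gaussian, or the median of the lognormal. Must be positive.
#' @param scale Component scale: standard deviation in bp for gaussian
#'   components (0 gives a point mass), log-space standard deviation for
#'   lognormal components. Must be non-negative.
#'
#' @return A tibble of class `mixture_spec` with one row per component.
#' @examples
#' mixture_spec(weight = 1, family = "gaussian",
#'              location_bp = 170, scale = 20)
#' @export
mixture_spec <- function(weight, family, location_bp, scale) {
  spec <- tibble(
    weight = as.numeric(weight),
    family = as.character(family),
    location_bp = as.numeric(location_bp),
    scale = as.numeric(scale)
  )
  validate_mixture_spec(spec)
  class(spec) <- c("mixture_spec", class(spec))
  spec
}

validate_mixture_spec <- function(spec) {
  assert_columns(spec, c("weight", "family", "location_bp", "scale"),
                 "a mixture spec")
  if (nrow(spec) == 0) abort("A mixture spec needs at least one component.")
  bad_w <- which(!is.finite(spec$weight) | spec$weight < 0)
  if (length(bad_w) > 0) {
    abort(sprintf("Component %d has an invalid weight (%s); weights must be non-negative.",
                  bad_w[1], format(spec$weight[bad_w[1]])))
  }
  if (abs(sum(spec$weight) - 1) > 1e-8) {
    abort(sprintf("Component weights must sum to 1 (they sum to %s).",
                  format(sum(spec$weight))))
  }
  bad_fam <- which(!spec$family %in% c("gaussian", "lognormal"))
  if (length(bad_fam) > 0) {
    abort(sprintf("Component %d has unknown family '%s'.",
                  bad_fam[1], spec$family[bad_fam[1]]))
  }
  bad_loc <- which(!is.finite(spec$location_bp) | spec$location_bp <= 0)
  if (length(bad_loc) > 0) {
    abort(sprintf("Component %d has non-positive location_bp.", bad_loc[1]))
  }
  bad_sc <- which(!is.finite(spec$scale) | spec$scale < 0)
  if (length(bad_sc) > 0) {
    abort(sprintf("Component %d has a negative scale.", bad_sc[1]))
  }
  invisible(spec)
}

#' Preset fragment-length mixtures
#'
#' Ready-made mixture specifications for the sample types the package
#' simulates:
#'
#' * `healthy_cfdna_spec()`: a single mononucleosomal peak (gaussian,
#'   170 bp location, 20 bp scale), matching the ~170 bp median length of
#'   plasma cfDNA from healthy donors.
#' * `crc_cfdna_spec()`: adds a shorter sub-mononucleosomal component at
#'   145 bp with weight `short_weight`, emulating the increased abundance of
#'   short cfDNA fragments in colorectal cancer patients.
#' * `degraded_storage_spec()`: a mono/di/tri-nucleosome ladder at
#'   170/380/570 bp with weights 0.5/0.3/0.2, emulating cfDNA from blood
#'   stored past the protective window of collection tubes, where peaks
#'   appear at 360-400 bp and 540-600 bp.
#' * `sheared_standard_spec()`: ultrasonically sheared genomic DNA used as
#'   the fragmented calibration standard (mean length ~170 bp).
#' * `hmw_dna_spec()`: intact high-molecular-weight genomic DNA
#'   (lognormal, median 15 kb) released from lysed blood cells.
#'
#' @param short_weight Weight of the short-fragment component in the CRC
#'   preset (default 0.3).
#' @return A [mixture_spec()].
#' @name mixture_presets
NULL

#' @rdname mixture_presets
#' @export
healthy_cfdna_spec <- function() {
  mixture_spec(weight = 1, family = "gaussian", location_bp = 170, scale = 20)
}

#' @rdname mixture_presets
#' @export
crc_cfdna_spec <- function(short_weight = 0.3) {
  assert_scalar_number(short_weight, "short_weight", min = 0)
  if (short_weight >= 1) abort("`short_weight` must be < 1.")
  mixture_spec(
    weight = c(short_weight, 1 - short_weight),
    family = c("gaussian", "gaussian"),
    location_bp = c(145, 170),
    scale = c(20, 20)
  )
}

#' @rdname mixture_presets
#' @export
degraded_storage_spec <- function() {
  mixture_spec(
    weight = c(0.5, 0.3, 0.2),
    family = rep("gaussian", 3),
    location_bp = c(170, 380, 570),
    scale = c(20, 35, 45)
  )
}

#' @rdname mixture_presets
#' @export
sheared_standard_spec <- function() {
  mixture_spec(weight = 1, family = "gaussian", location_bp = 170, scale = 35)
}

#' @rdname mixture_presets
#' @export
hmw_dna_spec <- function() {
  mixture_spec(weight = 1, family = "lognormal", location_bp = 15000,
               scale = 0.5)
}

#' Read a mixture spec from a YAML or JSON config file
#'
#' The file must contain a `components` list, each entry with fields
#' `weight`, `family`, `location_bp` and `scale`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [mixture_spec()].
#' @export
read_mixture_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: '%s'.", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$components)) {
    abort("Config must contain a `components` list.")
  }
  comp <- cfg$components
  if (is.data.frame(comp)) {
    comp_df <- as_tibble(comp)
  } else {
    comp_df <- purrr::map(comp, as_tibble) |> list_rbind()
  }
  assert_columns(comp_df, c("weight", "family", "location_bp", "scale"),
                 sprintf("config '%s'", path))
  mixture_spec(comp_df$weight, comp_df$family, comp_df$location_bp,
               comp_df$scale)
}
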