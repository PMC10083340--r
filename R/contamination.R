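#' Score a sample for HMW DNA contamination
#'
#' Implements the delta-delta-Cq contamination score: the 612 bp amplicon
#' only amplifies from long (high-molecular-weight, HMW) DNA while the
#' 106 bp amplicon reports (nearly) total DNA, so the long/short ratio
#' tracks the HMW mass fraction. With the 106 bp amplicon as the reference,
#' `dCq = mean Cq(long) - mean Cq(short)` per sample,
#' `ddCq = dCq(sample) - dCq(control)`, the relative normalized expression
#' is `RNE = E^(-ddCq)`, and the contamination percentage is
#' `RNE * 50` because the calibration control is the 50%-HMW standard.
#' Scoring the control against itself therefore returns exactly 50%.
#'
#' Efficiency handling: with `efficiency_mode = "constant"` a single
#' efficiency (default 2, i.e. perfect doubling) is used; with
#' `"per_assay"` the per-assay efficiencies in the table are applied
#' Pfaffl-style, `RNE = E_long^(Cq_long,ctrl - Cq_long,sample) /
#' E_short^(Cq_short,ctrl - Cq_short,sample)`.
#'
#' Replicates are aggregated by the arithmetic mean of detected Cq values.
#' A Cq at or beyond `nondetect_cq` cycles (or `NA`) is a non-detect. When
#' the long amplicon is a non-detect in all replicates the score is below
#' the quantification limit: `percent_hmw` is `NA`, `below_loq` is set and
#' `percent_upper_bound` reports the score a Cq at the last cycle would
#' give — never a silent 0.
#'
#' @param sample_rows Cq rows for the sample: columns `sample_id`,
#'   `assay_name`, `cq`, optionally `efficiency` and `replicate_id`.
#' @param control_rows Cq rows for the 50%-HMW control standard, same
#'   layout.
#' @param efficiency_mode `"constant"` (one efficiency for both assays) or
#'   `"per_assay"` (Pfaffl).
#' @param efficiency Efficiency used in `"constant"` mode.
#' @param control_percent HMW percentage of the control standard.
#' @param nondetect_cq Cq at/beyond which a reaction is a non-detect.
#' @param assay_names Length-2 named character vector mapping the
#'   reference/target roles to assay names
#'   (default `c(short = "short_106", long = "long_612")`).
#'
#' @return One-row tibble: `sample_id`, `delta_cq`, `delta_delta_cq`,
#'   `rne`, `percent_hmw`, `below_loq`, `percent_upper_bound`.
#' @export
contamination_score <- function(sample_rows, control_rows,
                                efficiency_mode = c("constant", "per_assay"),
                                efficiency = 2, control_percent = 50,
                                nondetect_cq = NONDETECT_CQ,
                                assay_names = c(short = "short_106",
                                                long = "long_612")) {
  efficiency_mode <- match.arg(efficiency_mode)
  s <- summarize_cq(sample_rows, assay_names, nondetect_cq)
  ctl <- summarize_cq(control_rows, assay_names, nondetect_cq)
  if (is.na(ctl$cq_short) || is.na(ctl$cq_long)) {
    abort("The control standard must have detected Cq values for both assays.")
  }
  if (is.na(s$cq_short)) {
    abort(sprintf(
      "Sample '%s' has no detected short-amplicon replicate; cannot score.",
      s$sample_id))
  }

  below_loq <- is.na(s$cq_long)
  cq_long_eff <- if (below_loq) nondetect_cq else s$cq_long

  score_at <- function(cq_long) {
    d_s <- cq_long - s$cq_short
    d_c <- ctl$cq_long - ctl$cq_short
    dd <- d_s - d_c
    rne <- if (efficiency_mode == "constant") {
      efficiency^(-dd)
    } else {
      s$eff_long^(ctl$cq_long - cq_long) /
        s$eff_short^(ctl$cq_short - s$cq_short)
    }
    list(delta_cq = d_s, delta_delta_cq = dd, rne = rne,
         percent = rne * control_percent)
  }

  at <- score_at(cq_long_eff)
  tibble(
    sample_id = s$sample_id,
    delta_cq = at$delta_cq,
    delta_delta_cq = at$delta_delta_cq,
    rne = if (below_loq) NA_real_ else at$rne,
    percent_hmw = if (below_loq) NA_real_ else at$percent,
    below_loq = below_loq,
    percent_upper_bound = if (below_loq) at$percent else NA_real_
  )
}

# Mean detected Cq and mean efficiency per assay role (short/long).
summarize_cq <- function(rows, assay_names, nondetect_cq) {
  assert_columns(rows, c("sample_id", "assay_name", "cq"), "a Cq table")
  if (nrow(rows) == 0) abort("Cq rows must be non-empty.")
  if (!"efficiency" %in% names(rows)) rows$efficiency <- 2
  if (any(rows$efficiency <= 1 | rows$efficiency > 2.2, na.rm = TRUE)) {
    abort("Efficiencies must lie in (1, 2.2] fold per cycle.")
  }
  if (any(!is.na(rows$cq) & rows$cq <= 0)) {
    abort("Detected Cq values must be positive.")
  }
  one <- function(role) {
    sub <- rows |>
      filter(.data$assay_name == assay_names[[role]],
             !is.na(.data$cq), .data$cq < nondetect_cq)
    list(cq = if (nrow(sub) == 0) NA_real_ else mean(sub$cq),
         eff = if (nrow(sub) == 0) NA_real_ else mean(sub$efficiency))
  }
  short <- one("short")
  long <- one("long")
  list(sample_id = rows$sample_id[1],
       cq_short = short$cq, cq_long = long$cq,
       eff_short = short$eff, eff_long = long$eff)
}

#' Screen a batch of samples for HMW contamination
#'
#' Scores every sample in a Cq table against a control standard with
#' [contamination_score()] and reports those whose contamination percentage
#' exceeds the threshold. Results are ordered by `sample_id`; samples below
#' the quantification limit are never flagged.
#'
#' @param cq_table Cq rows for all samples (the control's rows may be
#'   included; they are used as the calibrator and not screened).
#' @param control_id `sample_id` of the 50%-HMW control standard, which must
#'   be present in `cq_table`.
#' @param threshold_percent Flagging threshold on `percent_hmw`.
#' @param flagged_only If `TRUE` (default) return only flagged samples;
#'   otherwise return all screened samples with a `flagged` column.
#' @inheritParams contamination_score
#'
#' @return A tibble of [contamination_score()] rows (plus `flagged`),
#'   ordered by `sample_id`. Empty input gives an empty tibble.
#' @export
screen_batch <- function(cq_table, control_id, threshold_percent = 10,
                         flagged_only = TRUE,
                         efficiency_mode = c("constant", "per_assay"),
                         efficiency = 2, control_percent = 50,
                         nondetect_cq = NONDETECT_CQ,
                         assay_names = c(short = "short_106",
                                         long = "long_612")) {
  efficiency_mode <- match.arg(efficiency_mode)
  if (nrow(cq_table) == 0) {
    out <- tibble(sample_id = character(), delta_cq = numeric(),
                  delta_delta_cq = numeric(), rne = numeric(),
                  percent_hmw = numeric(), below_loq = logical(),
                  percent_upper_bound = numeric(), flagged = logical())
    return(out)
  }
  assert_columns(cq_table, c("sample_id", "assay_name", "cq"), "a Cq table")
  control_rows <- filter(cq_table, .data$sample_id == control_id)
  if (nrow(control_rows) == 0) {
    abort(sprintf("Control sample '%s' not found in the table.", control_id))
  }
  ids <- sort(setdiff(unique(cq_table$sample_id), control_id))
  scored <- purrr::map(ids, function(id) {
    contamination_score(
      filter(cq_table, .data$sample_id == id), control_rows,
      efficiency_mode = efficiency_mode, efficiency = efficiency,
      control_percent = control_percent, nondetect_cq = nondetect_cq,
      assay_names = assay_names
    )
  }) |>
    list_rbind() |>
    mutate(flagged = !is.na(.data$percent_hmw) &
             .data$percent_hmw > threshold_percent) |>
    arrange(.data$sample_id)
  if (flagged_only) filter(scored, .data$flagged) else scored
}

#' Read a Cq CSV
#'
#' Expected header: `sample_id,assay,replicate,cq,efficiency` (efficiency
#' optional; empty/`NA`/`"ND"` Cq entries are non-detects).
#'
#' @param path CSV file path.
#' @return A Cq tibble for [contamination_score()] / [screen_batch()].
#' @export
read_cq_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        na = c("", "NA", "ND"))
  nm <- names(df)
  nm[nm == "assay"] <- "assay_name"
  nm[nm == "replicate"] <- "replicate_id"
  names(df) <- nm
  assert_columns(df, c("sample_id", "assay_name", "cq"),
                 sprintf("'%s'", path))
  df$cq <- as.numeric(df$cq)
  df
}
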