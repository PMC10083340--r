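#' Read a BED file of genomic intervals
#'
#' Minimal BED reader with per-line validation: tab-separated, at least
#' three fields (`chrom`, `start`, `end`, 0-based half-open), optional
#' fourth name field. Malformed lines raise an error naming the line
#' number, which vendor-grade parsers tend to swallow.
#'
#' @param path BED file path.
#' @param name_col Name for the optional fourth column (default `"name"`;
#'   use `"label"` for region files, `"sample_id"` for fragment files).
#' @return A tibble with columns `chrom`, `start`, `end` and, if present,
#'   the named fourth column.
#' @export
read_bed <- function(path, name_col = "name") {
  if (!file.exists(path)) abort(sprintf("No such BED file: '%s'.", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- purrr::map(which(keep), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("Malformed BED line %d: fewer than 3 fields.", i))
    }
    start <- suppressWarnings(as.numeric(fields[2]))
    end <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("Malformed BED line %d: non-numeric coordinates.", i))
    }
    if (start < 0 || end <= start) {
      abort(sprintf(
        "Malformed BED line %d: need 0 <= start < end (got %s, %s).",
        i, fields[2], fields[3]))
    }
    tibble(chrom = fields[1], start = start, end = end,
           name = if (length(fields) >= 4) fields[4] else NA_character_)
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character())
  }
  names(out)[names(out) == "name"] <- name_col
  out
}

#' Define a region set
#'
#' Validates target regions (e.g. the two open-chromatin loci OCR1/OCR2 and
#' the closed pericentromeric CCR locus): 0-based half-open intervals with
#' unique labels.
#'
#' @param df Tibble with columns `chrom`, `start`, `end`, `label`.
#' @return The validated tibble, classed `region_set`.
#' @export
region_set <- function(df) {
  assert_columns(df, c("chrom", "start", "end", "label"), "a region set")
  if (any(df$start >= df$end)) {
    abort("All regions must satisfy start < end.")
  }
  if (anyDuplicated(df$label)) abort("Region labels must be unique.")
  out <- as_tibble(df)
  class(out) <- unique(c("region_set", class(out)))
  out
}

#' Assign cfDNA fragments to regions by midpoint
#'
#' A fragment belongs to a region when its midpoint falls inside the region
#' interval (`region_start <= midpoint < region_end`, 0-based half-open;
#' the midpoint of `[start, end)` is `floor((start + end) / 2)`). Midpoint
#' assignment makes the result a partition for disjoint regions — a
#' fragment straddling a boundary is counted once, unlike any-overlap
#' assignment. Strand is ignored (cfDNA fragments are double-stranded).
#' Fragment length is `end - start`.
#'
#' @param fragments Tibble of fragment intervals: `chrom`, `start`, `end`,
#'   optionally `sample_id` (as from `read_bed(path, "sample_id")`).
#' @param regions A [region_set()] (or tibble with `chrom`, `start`, `end`,
#'   `label`).
#' @return The assigned fragments: one row per fragment x containing
#'   region, with columns `chrom`, `start`, `end`, `midpoint`, `length_bp`,
#'   `label` (plus `sample_id` if supplied). Fragments whose midpoint lies
#'   in no region are dropped.
#' @export
assign_fragments <- function(fragments, regions) {
  assert_columns(fragments, c("chrom", "start", "end"), "a fragment table")
  regions <- region_set(as_tibble(regions))
  if (any(fragments$start >= fragments$end)) {
    abort("All fragments must satisfy start < end.")
  }
  frg <- as_tibble(fragments) |>
    mutate(
      midpoint = floor((.data$start + .data$end) / 2),
      length_bp = .data$end - .data$start
    )
  reg <- regions |>
    select(chrom = "chrom", region_start = "start", region_end = "end",
           label = "label")
  frg |>
    inner_join(reg, by = "chrom", relationship = "many-to-many") |>
    filter(.data$region_start <= .data$midpoint,
           .data$midpoint < .data$region_end) |>
    select(-"region_start", -"region_end")
}

#' Summarize fragment lengths per region
#'
#' Median and interquartile range of fragment lengths per region label
#' (linear-interpolation quantiles, the convention behind
#' median/IQR dot-and-line summaries). Regions with no assigned fragments
#' are reported with `n_fragments = 0` and `NA` summaries when the full
#' region set is supplied.
#'
#' @param assigned Output of [assign_fragments()] (needs `label` and
#'   `length_bp`).
#' @param regions Optional [region_set()] used to report empty regions.
#' @return A tibble with one row per label: `label`, `n_fragments`,
#'   `median_bp`, `iqr_low_bp`, `iqr_high_bp`.
#' @export
summarize_regions <- function(assigned, regions = NULL) {
  assert_columns(assigned, c("label", "length_bp"), "an assignment table")
  sm <- assigned |>
    group_by(.data$label) |>
    summarise(
      n_fragments = dplyr::n(),
      median_bp = median(.data$length_bp),
      iqr_low_bp = quantile(.data$length_bp, 0.25, names = FALSE),
      iqr_high_bp = quantile(.data$length_bp, 0.75, names = FALSE),
      .groups = "drop"
    )
  if (!is.null(regions)) {
    all_labels <- tibble(label = as_tibble(regions)$label)
    sm <- all_labels |>
      left_join(sm, by = "label") |>
      mutate(n_fragments = tidyr::replace_na(.data$n_fragments, 0L))
  }
  arrange(sm, .data$label)
}

#' Scatter a fragment population across genomic regions
#'
#' Places each simulated fragment at a uniformly random position centred in
#' one of the given regions (regions chosen uniformly), producing the BED
#' layout [assign_fragments()] consumes. Convenience for building
#' interval-level fixtures out of length-level simulations.
#'
#' @param pop A [fragment_population()].
#' @param regions A [region_set()].
#' @param seed Integer seed.
#' @return A tibble of fragment intervals (`chrom`, `start`, `end`,
#'   `sample_id`).
#' @export
scatter_fragments <- function(pop, regions, seed = 1) {
  regions <- region_set(as_tibble(regions))
  assert_columns(pop, "length_bp", "a fragment population")
  n <- nrow(pop)
  local_seed(seed, {
    ridx <- sample.int(nrow(regions), n, replace = TRUE)
    r <- regions[ridx, ]
    # uniform midpoint inside the region, fragment centred on it
    mid <- r$start + floor(runif(n) * (r$end - r$start))
    half <- pop$length_bp %/% 2
    start <- pmax(0, mid - half)
    tibble(
      chrom = r$chrom,
      start = start,
      end = start + pop$length_bp,
      sample_id = pop$sample_id
    )
  })
}

#' Write fragment intervals as BED
#'
#' 0-based half-open coordinates, four columns
#' (`chrom`, `start`, `end`, `sample_id`), no header.
#'
#' @param fragments Tibble with `chrom`, `start`, `end`, optional
#'   `sample_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(fragments, path) {
  assert_columns(fragments, c("chrom", "start", "end"), "a fragment table")
  df <- as_tibble(fragments)
  if (!"sample_id" %in% names(df)) df$sample_id <- "."
  readr::write_tsv(
    df |>
      transmute(.data$chrom, start = format(.data$start, scientific = FALSE,
                                            trim = TRUE),
                end = format(.data$end, scientific = FALSE, trim = TRUE),
                .data$sample_id),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Write and read a fragment-length table
#'
#' Two-column TSV (`length_bp`, `count`) holding the aggregated length
#' histogram of a population; `read_population_tsv()` expands it back into
#' a [fragment_population()].
#'
#' @param pop A [fragment_population()].
#' @param path TSV path.
#' @param sample_id,group_label Metadata restored on read.
#' @return `write_population_tsv()`: `path` invisibly;
#'   `read_population_tsv()`: a [fragment_population()].
#' @export
write_population_tsv <- function(pop, path) {
  assert_columns(pop, "length_bp", "a fragment population")
  pop |>
    count(.data$length_bp, name = "count") |>
    arrange(.data$length_bp) |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_population_tsv
#' @export
read_population_tsv <- function(path, sample_id = basename(path),
                                group_label = NA_character_) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(df, c("length_bp", "count"), sprintf("'%s'", path))
  fragment_population(rep(df$length_bp, df$count), sample_id = sample_id,
                      group_label = group_label)
}
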