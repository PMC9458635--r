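#' Bin mean herbicide injury into a resistance category
#'
#' Injury is visible tissue damage on a 0-100% scale (0 = no injury,
#' 100 = dead plant). Bins follow the printed integer ranges: 0-32 High
#' resistance, 33-67 Moderate, 68-100 Susceptible. Non-integer means are
#' floor-compared by default so that the printed inclusive boundaries apply
#' unchanged.
#'
#' @param mean_injury mean percent injury, in `[0, 100]` (vectorized).
#' @param floor_means floor non-integer means before comparison (default
#'   `TRUE`).
#' @return character vector in `{"High", "Moderate", "Susceptible"}`.
#' @export
bin_injury <- function(mean_injury, floor_means = TRUE) {
  if (any(mean_injury < 0 | mean_injury > 100))
    stop("injury outside [0, 100]")
  m <- if (floor_means) floor(mean_injury) else mean_injury
  ifelse(m <= 32, "High", ifelse(m <= 67, "Moderate", "Susceptible"))
}

#' Classify a sample's resistance from its per-plant injury scores
#'
#' A sample whose individual plants fall in both a resistant bin
#' (High/Moderate) and the Susceptible bin is `Segregating` (resistance
#' segregating among that maternal plant's offspring); otherwise the
#' across-plant mean injury is binned with [bin_injury()].
#'
#' @param scores numeric vector of per-plant injury percentages (>= 1
#'   plant).
#' @return one of `"High"`, `"Moderate"`, `"Susceptible"`, `"Segregating"`.
#' @export
classify_resistance <- function(scores) {
  if (!length(scores)) stop("need at least one plant score")
  bins <- bin_injury(scores)
  if (any(bins == "Susceptible") && any(bins != "Susceptible"))
    return("Segregating")
  bin_injury(mean(scores))
}

#' @noRd
round_half_up <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

#' Tabulate resistance categories by field cropping history
#'
#' Counts samples per field type and resistance category and reports
#' column percentages (half-up rounding to one decimal, matching the
#' printed style) alongside the exact fractions. Field types follow the
#' cropping-history labels CHY / HYB / CLF (Clearfield hybrid,
#' non-Clearfield hybrid, Clearfield inbred).
#'
#' @param records data.frame with columns `sample_id`, `field_type`,
#'   `injury` (one row per plant).
#' @param field_levels allowed field-type labels, in output column order.
#' @return list with `counts` (category x field-type matrix incl. `Total`
#'   column), `percent` (rounded column percentages), `exact` (unrounded),
#'   and `table` (formatted `"count (pct)"` strings).
#' @export
tabulate_resistance <- function(records,
                                field_levels = c("CHY", "HYB", "CLF")) {
  stopifnot(all(c("sample_id", "field_type", "injury") %in% names(records)))
  bad <- setdiff(unique(records$field_type), field_levels)
  if (length(bad)) stop("unknown field type(s): ", paste(bad, collapse = ", "))
  per_sample <- do.call(rbind, lapply(split(records, records$sample_id),
    function(d) data.frame(sample_id = d$sample_id[1],
                           field_type = d$field_type[1],
                           category = classify_resistance(d$injury))))
  cats <- c("High", "Moderate", "Susceptible", "Segregating")
  counts <- table(factor(per_sample$category, levels = cats),
                  factor(per_sample$field_type, levels = field_levels))
  counts <- cbind(counts, Total = rowSums(counts))
  exact <- sweep(counts, 2, colSums(counts), "/") * 100
  percent <- round_half_up(exact, 1)
  fmt <- matrix(sprintf("%d (%s)", counts, percent), nrow(counts),
                dimnames = dimnames(counts))
  list(counts = counts, percent = percent, exact = exact, table = fmt)
}

#' Read a per-plant herbicide injury table
#'
#' @param path TSV with header `sample_id`, `field_type`, `plant`,
#'   `injury`.
#' @return data.frame of injury records.
#' @export
read_injury_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "field_type", "injury") %in% names(d)))
  if (any(d$injury < 0 | d$injury > 100)) stop("injury outside [0, 100]")
  d
}
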