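# Germination-trial data model: treatment coding, table I/O and the species
# inclusion filter.

#' Day-length treatment levels
#'
#' The three incubator photoperiod treatments. `"equal"` (12 h light / 12 h
#' dark) is the reference level for treatment contrasts; `"long"` is
#' 18 h light / 6 h dark and `"short"` is 6 h light / 18 h dark.
#'
#' @return Character vector of the three levels, reference first.
#' @export
treatment_levels <- function() c("equal", "long", "short")

#' Parse day-length treatment codes
#'
#' Maps the treatment spellings used in germination tables onto the three
#' canonical levels: `"6L/18D"` or `"short"` to short-day, `"12L/12D"` or
#' `"equal"` to the equal-day reference, `"18L/6D"` or `"long"` to long-day.
#' Matching is case-insensitive and ignores whitespace; any other code is an
#' error (no guessing).
#'
#' @param x Character vector of treatment codes.
#' @return Factor with levels `treatment_levels()` (reference `"equal"` first).
#' @examples
#' parse_treatment(c("6L/18D", "12L/12D", "18l/6d"))
#' @export
parse_treatment <- function(x) {
  if (length(x) == 0) abort("no treatment codes supplied")
  key <- toupper(gsub("\\s+", "", as.character(x)))
  map <- c(
    "6L/18D" = "short", "SHORT" = "short",
    "12L/12D" = "equal", "EQUAL" = "equal",
    "18L/6D" = "long", "LONG" = "long"
  )
  out <- unname(map[key])
  bad <- which(is.na(out) | is.na(x) | !nzchar(trimws(as.character(x))))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown treatment code(s): %s (entry %s); expected 6L/18D, 12L/12D, 18L/6D or short/equal/long",
      paste(sQuote(x[bad]), collapse = ", "),
      paste(bad, collapse = ", ")
    ))
  }
  factor(out, levels = treatment_levels())
}

# Validate a germination records data frame built in code; returns it with a
# canonical treatment factor. `where` labels error messages.
validate_germination <- function(records, where = "records") {
  req <- c("species", "treatment", "n_sown", "n_germinated")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", where,
                  paste(missing_cols, collapse = ", ")))
  }
  records <- as_tibble(records)
  if (!is.factor(records$treatment) ||
      !identical(levels(records$treatment), treatment_levels())) {
    records$treatment <- parse_treatment(as.character(records$treatment))
  }
  for (col in c("n_sown", "n_germinated")) {
    v <- records[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      abort(sprintf("%s: column %s must hold non-negative integers (row %s)",
                    where, col, paste(bad, collapse = ", ")))
    }
  }
  over <- which(records$n_germinated > records$n_sown)
  if (length(over) > 0) {
    abort(sprintf("%s: n_germinated exceeds n_sown in row %s", where,
                  paste(over, collapse = ", ")))
  }
  records
}

# Sum duplicate species-by-treatment rows (records are summable counts).
aggregate_records <- function(records) {
  records |>
    group_by(.data$species, .data$treatment) |>
    summarise(
      n_sown = sum(.data$n_sown),
      n_germinated = sum(.data$n_germinated),
      .groups = "drop"
    ) |>
    arrange(.data$species, .data$treatment)
}

#' Read a germination trial table
#'
#' Reads a CSV with columns `species, treatment, n_sown, n_germinated`,
#' validates counts (non-negative integers, germinated no greater than sown,
#' known treatment codes; offending row numbers are reported) and sums
#' duplicate species-by-treatment rows.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated, aggregated germination records with columns
#'   `species`, `treatment` (factor, reference `"equal"`), `n_sown`,
#'   `n_germinated`.
#' @seealso [write_germination_table()], [apply_inclusion_filter()]
#' @export
read_germination_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("species", "treatment", "n_sown", "n_germinated")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in c("n_sown", "n_germinated")) {
    bad <- which(!grepl("^\\s*[0-9]+\\s*$", raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: column %s is not a non-negative integer in row %s",
                    path, col, paste(bad, collapse = ", ")))
    }
  }
  rec <- tibble(
    species = raw$species,
    treatment = parse_treatment(raw$treatment),
    n_sown = as.integer(raw$n_sown),
    n_germinated = as.integer(raw$n_germinated)
  )
  rec <- validate_germination(rec, where = path)
  aggregate_records(rec)
}

#' Write a germination trial table
#'
#' Writes records in the same CSV dialect [read_germination_table()] consumes,
#' so a read-write-read round trip is the identity.
#'
#' @param records Germination records tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_germination_table <- function(records, path) {
  records <- validate_germination(records)
  out <- records |>
    mutate(treatment = as.character(.data$treatment))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Species inclusion filter for sensitivity estimation
#'
#' Applies the study's exclusion rule to each species: a species is dropped
#' when germination is strictly below 5% in every one of the three treatments
#' (`low_percent_all_treatments`, which takes precedence), or when fewer than
#' five seeds germinated in total across the three treatments
#' (`fewer_than_five_germinants`). Ties — exactly 5% or exactly five seeds —
#' retain the species (both inequalities are strict). Percentages are computed
#' from counts aggregated per treatment.
#'
#' @param records Germination records tibble covering one or more species; all
#'   three treatments must be present for every species.
#' @return A tibble with one row per species: `species`, `retained` (logical)
#'   and `reason` (`"ok"`, `"low_percent_all_treatments"` or
#'   `"fewer_than_five_germinants"`).
#' @examples
#' rec <- simulate_germination(
#'   tibble::tibble(species = "sp1", p_long = 0.6, p_equal = 0.5,
#'                  p_short = 0.4, n_per_treatment = 30), seed = 1)
#' apply_inclusion_filter(rec)
#' @export
apply_inclusion_filter <- function(records) {
  records <- aggregate_records(validate_germination(records))
  coverage <- records |>
    group_by(.data$species) |>
    summarise(k = dplyr::n_distinct(.data$treatment), .groups = "drop") |>
    filter(.data$k < 3)
  if (nrow(coverage) > 0) {
    abort(sprintf("species missing treatment level(s): %s",
                  paste(coverage$species, collapse = ", ")))
  }
  records |>
    group_by(.data$species) |>
    summarise(
      all_low = all(.data$n_germinated / pmax(.data$n_sown, 1L) < 0.05),
      total_germ = sum(.data$n_germinated),
      .groups = "drop"
    ) |>
    mutate(
      reason = case_when(
        .data$all_low ~ "low_percent_all_treatments",
        .data$total_germ < 5 ~ "fewer_than_five_germinants",
        TRUE ~ "ok"
      ),
      retained = .data$reason == "ok"
    ) |>
    select("species", "retained", "reason")
}
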