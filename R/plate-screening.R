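# Bookkeeping for plate-based growth/distortion screens and for the
# taxonomic composition of isolate collections.

#' Read a plate-reader OD matrix or long table
#'
#' Two CSV dialects are accepted: a plate matrix whose first column holds
#' row letters (A, B, ...) and whose header holds column numbers, or a long
#' table with columns `well` and `od600`. Well ids use the letter-row /
#' zero-padded-column convention (A01 ... P24).
#'
#' @param path path to a CSV file.
#' @return A data frame with columns `well` and `od600`.
#' @export
read_plate_od <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("well", "od600") %in% names(df)))
    return(validate_od_long(df[c("well", "od600")]))
  rows <- as.character(df[[1]])
  if (!all(grepl("^[A-Z]$", rows)) || anyDuplicated(rows))
    stop("malformed plate matrix: first column must hold unique row ",
         "letters A-Z (or provide long-format columns `well`, `od600`)",
         call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat))
    stop("malformed plate matrix: OD body must be numeric and complete",
         call. = FALSE)
  cols <- suppressWarnings(as.integer(colnames(mat)))
  if (anyNA(cols))
    stop("malformed plate matrix: header must hold column numbers",
         call. = FALSE)
  long <- data.frame(
    well = sprintf("%s%02d", rep(rows, times = ncol(mat)),
                   rep(cols, each = nrow(mat))),
    od600 = as.vector(mat),
    stringsAsFactors = FALSE)
  validate_od_long(long[order(long$well), , drop = FALSE])
}

validate_od_long <- function(df) {
  if (!is.numeric(df$od600) || anyNA(df$od600) || any(df$od600 < 0))
    stop("OD600 values must be non-negative numbers", call. = FALSE)
  if (anyDuplicated(df$well))
    stop("malformed plate layout: duplicated well ids", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Call growth from blank-corrected OD600
#'
#' A well is called grown when its OD600 exceeds the blank reference by at
#' least `threshold`. The default threshold of 0.1 blank-corrected OD600 is
#' a conventional turbidity floor; adjust it to the reader and medium.
#'
#' @param od a data frame with columns `well` and `od600` (as from
#'   [read_plate_od()]), or a bare numeric vector of ODs.
#' @param blank_od reference OD600 of an uninoculated well.
#' @param threshold minimum blank-corrected OD600 called as growth (> 0).
#' @return A `well_records` data frame with columns `well`, `od600`,
#'   `growth` and `distortion` (initialised `NA`; see [well_records()]).
#' @export
call_growth <- function(od, blank_od, threshold = 0.1) {
  stop_if_not_scalar_number(blank_od, "blank_od", min = 0)
  stop_if_not_scalar_number(threshold, "threshold", min = 0,
                            strict_min = TRUE)
  if (is.numeric(od))
    od <- data.frame(well = sprintf("W%03d", seq_along(od)), od600 = od,
                     stringsAsFactors = FALSE)
  od <- validate_od_long(od)
  well_records(od$well, od$od600,
               growth = (od$od600 - blank_od) >= threshold)
}

#' Per-well screen records
#'
#' Builds and validates the per-well record table used by the screen
#' summaries: OD, growth call, and the manual optical-distortion call (the
#' surfactant-activity readout, scored by eye on turbid wells only, so
#' `distortion = TRUE` is invalid on a non-growth well).
#'
#' @param well well ids.
#' @param od600 non-negative OD600 values.
#' @param growth logical growth calls.
#' @param distortion optional logical distortion calls (`NA` = not scored).
#' @return A data frame of class `well_records`.
#' @export
well_records <- function(well, od600, growth, distortion = NA) {
  well <- as.character(well)
  df <- data.frame(well = well, od600 = as.numeric(od600),
                   growth = as.logical(growth),
                   distortion = rep_len(as.logical(distortion),
                                        length(well)),
                   stringsAsFactors = FALSE)
  if (any(df$od600 < 0, na.rm = TRUE))
    stop("od600 must be non-negative", call. = FALSE)
  if (anyNA(df$growth))
    stop("growth calls must be TRUE/FALSE", call. = FALSE)
  bad <- !is.na(df$distortion) & df$distortion & !df$growth
  if (any(bad))
    stop("distortion = TRUE on non-growth well(s): ",
         paste(df$well[bad], collapse = ", "),
         " (the distortion screen applies to turbid wells only)",
         call. = FALSE)
  class(df) <- c("well_records", "data.frame")
  df
}

#' Summarise a plate screen
#'
#' Totals for a screened plate: wells, growth wells, blanks, distortion
#' positives, and the blank fraction (the quantity fed to
#' [calibrate_lambda()] to recalibrate the dilution level).
#'
#' @param records a `well_records` data frame ([well_records()] or
#'   [call_growth()]).
#' @return An object of class `screen_summary`.
#' @export
summarize_screen <- function(records) {
  if (!inherits(records, "well_records"))
    records <- well_records(records$well, records$od600, records$growth,
                            records$distortion %||% NA)
  n <- nrow(records)
  n_growth <- sum(records$growth)
  structure(list(
    n_wells = n,
    n_growth = n_growth,
    n_blank = n - n_growth,
    n_distortion = sum(records$distortion, na.rm = TRUE),
    blank_fraction = if (n > 0) (n - n_growth) / n else NA_real_
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf(paste0("<screen_summary> %d wells: %d grown, %d blank ",
                     "(blank fraction %.4f), %d distortion-positive\n"),
              x$n_wells, x$n_growth, x$n_blank, x$blank_fraction,
              x$n_distortion))
  invisible(x)
}

#' Shannon diversity and Pielou evenness of an isolate collection
#'
#' Shannon index H (nats) and Pielou evenness J = H / log(S) over per-genus
#' isolate counts, where S is the number of genera present. J is 1 for a
#' perfectly even collection over more than one genus, and defined as 0 for
#' a single genus. Used to compare the taxonomic evenness of isolate sets
#' obtained by different cultivation routes.
#'
#' @param counts non-negative per-genus counts, at least one positive;
#'   names, if present, are kept.
#' @return An object of class `composition_summary`: list with `counts`,
#'   `richness`, `shannon`, `pielou`.
#' @examples
#' evenness(c(Pseudomonas = 10, Bacillus = 10, Lysobacter = 10))
#' @export
evenness <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 1L || anyNA(counts) ||
      any(counts < 0))
    stop("`counts` must be non-negative numbers", call. = FALSE)
  if (sum(counts) == 0)
    stop("all counts are zero: evenness is undefined", call. = FALSE)
  s <- sum(counts > 0)
  h <- as.numeric(vegan::diversity(counts, index = "shannon"))
  structure(list(counts = counts, richness = s, shannon = h,
                 pielou = if (s > 1) h / log(s) else 0),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("<composition_summary> %d taxa, %g isolates: H = %.4f, J = %.4f\n",
              x$richness, sum(x$counts), x$shannon, x$pielou))
  invisible(x)
}

#' Bin 16S similarities around the species threshold
#'
#' Partitions isolates by % identity of their 16S rRNA gene to the nearest
#' validly published sequence into three exhaustive, disjoint bins:
#' above `high_threshold` (confident species match), between
#' `species_threshold` and `high_threshold` inclusive (near-threshold), and
#' below `species_threshold` (candidate novel species). The default species
#' threshold 98.65% is the conventional cutoff for bacterial species-level
#' identification.
#'
#' @param similarity numeric % identities in `[0, 100]`, or a data frame
#'   with a `similarity` column (e.g. `isolate_id,genus,similarity`).
#' @param species_threshold species-level cutoff (default 98.65); values
#'   exactly at the threshold fall in the middle bin.
#' @param high_threshold upper cutoff (default 99); values exactly at it
#'   fall in the middle bin.
#' @return Named integer vector of three bin counts summing to the input
#'   size, with the thresholds recorded as an attribute.
#' @examples
#' bin_similarity(c(99.5, 98.7, 97.0))
#' @export
bin_similarity <- function(similarity, species_threshold = 98.65,
                           high_threshold = 99) {
  if (is.data.frame(similarity)) similarity <- similarity$similarity
  if (!is.numeric(similarity) || anyNA(similarity) ||
      any(similarity < 0) || any(similarity > 100))
    stop("similarities must lie in [0, 100]", call. = FALSE)
  if (!(species_threshold < high_threshold))
    stop("`species_threshold` must be below `high_threshold`", call. = FALSE)
  counts <- c(sum(similarity > high_threshold),
              sum(similarity >= species_threshold &
                    similarity <= high_threshold),
              sum(similarity < species_threshold))
  names(counts) <- c(sprintf(">%g", high_threshold),
                     sprintf("%g-%g", species_threshold, high_threshold),
                     sprintf("<%g", species_threshold))
  attr(counts, "thresholds") <- c(species = species_threshold,
                                  high = high_threshold)
  counts
}
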