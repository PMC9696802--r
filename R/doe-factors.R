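# Factor definitions and coded-variable transforms shared by the screening
# (Plackett-Burman) and response-surface (Box-Behnken) designs.
#
# A coded variable x relates to its natural level u through
#   u = center + x * step,   x = (u - center) / step,
# so that -1/+1 are the low/high design levels and 0 the centre.

#' Define design factors
#'
#' Builds the factor table used by the design generators. Factors may be
#' given by their low/high design levels (the centre and step are derived)
#' or directly by centre and step.
#'
#' @param name factor names.
#' @param low,high natural-unit levels coded -1 and +1 (`low < high`).
#' @param center,step alternative parametrisation: natural level at code 0
#'   and natural-unit change per coded unit (`step > 0`).
#' @param units optional unit strings, for printing only.
#' @return A data frame of class `factor_def` with columns `name`, `low`,
#'   `high`, `center`, `step`, `units`.
#' @examples
#' factor_def(c("NaNO3", "time"), low = c(1, 108), high = c(3, 132),
#'            units = c("g/L", "h"))
#' @export
factor_def <- function(name, low = NULL, high = NULL,
                       center = NULL, step = NULL, units = NA_character_) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("factor names must be unique", call. = FALSE)
  if (is.null(center) != is.null(step))
    stop("supply `center` and `step` together", call. = FALSE)
  if (!is.null(center)) {
    if (any(step <= 0)) stop("`step` must be positive", call. = FALSE)
    low <- center - step
    high <- center + step
  } else {
    if (is.null(low) || is.null(high))
      stop("supply either low/high or center/step", call. = FALSE)
    if (any(!(low < high)))
      stop("each `low` must be strictly below its `high`", call. = FALSE)
    center <- (low + high) / 2
    step <- (high - low) / 2
  }
  df <- data.frame(name = name, low = low, high = high,
                   center = center, step = step,
                   units = rep_len(as.character(units), length(name)),
                   stringsAsFactors = FALSE)
  class(df) <- c("factor_def", "data.frame")
  df
}

#' Coded to natural levels and back
#'
#' @param factors a `factor_def` table (or a design's `factors` element).
#' @param x matrix (or vector) of coded levels, columns in factor order.
#' @param u matrix (or vector) of natural levels, columns in factor order.
#' @return A matrix of the same shape in the other scale, with factor names
#'   as column names.
#' @examples
#' f <- factor_def(c("NaNO3", "PO4", "time"),
#'                 center = c(2.5, 23.75, 126), step = c(0.5, 1.25, 6))
#' decode_levels(f, c(0, 0, 1))
#' @export
decode_levels <- function(factors, x) {
  factors <- as_factor_def(factors)
  x <- coerce_level_matrix(x, nrow(factors))
  u <- sweep(sweep(x, 2, factors$step, "*"), 2, factors$center, "+")
  colnames(u) <- factors$name
  u
}

#' @rdname decode_levels
#' @export
encode_levels <- function(factors, u) {
  factors <- as_factor_def(factors)
  u <- coerce_level_matrix(u, nrow(factors))
  x <- sweep(sweep(u, 2, factors$center, "-"), 2, factors$step, "/")
  colnames(x) <- factors$name
  x
}

as_factor_def <- function(factors) {
  if (inherits(factors, "design_matrix")) factors <- factors$factors
  if (!inherits(factors, "factor_def"))
    stop("`factors` must be a factor_def table (see factor_def())",
         call. = FALSE)
  factors
}

coerce_level_matrix <- function(x, k) {
  if (is.null(dim(x))) {
    x <- matrix(x, ncol = k, byrow = TRUE)
  } else {
    x <- as.matrix(x)
    if (ncol(x) == 1L && k > 1L && nrow(x) == k) x <- t(x)
  }
  if (ncol(x) != k)
    stop("level matrix must have one column per factor", call. = FALSE)
  x
}

#' Construct a design matrix object
#'
#' Container tying a coded run matrix to its factor metadata. Normally
#' produced by [generate_pb12()] or [generate_bbd()].
#'
#' @param coded runs x factors matrix with entries in -1/0/+1.
#' @param factors a [factor_def()] table matching the columns.
#' @param kind `"pb"` or `"bbd"`.
#' @return An object of class `design_matrix`.
#' @export
design_matrix <- function(coded, factors, kind = c("pb", "bbd")) {
  kind <- match.arg(kind)
  factors <- as_factor_def(factors)
  coded <- as.matrix(coded)
  if (ncol(coded) != nrow(factors))
    stop("coded matrix and factor table disagree on factor count",
         call. = FALSE)
  if (!all(coded %in% c(-1, 0, 1)))
    stop("coded entries must be -1, 0 or +1", call. = FALSE)
  if (kind == "pb" && !all(coded %in% c(-1, 1)))
    stop("a Plackett-Burman design is two-level: entries must be -1/+1",
         call. = FALSE)
  colnames(coded) <- factors$name
  rownames(coded) <- NULL
  structure(list(coded = coded, factors = factors, kind = kind),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %s, %d runs x %d factors\n",
              toupper(x$kind), nrow(x$coded), ncol(x$coded)))
  print(utils::head(as.data.frame(x), n = 12))
  if (nrow(x$coded) > 12) cat("  ...\n")
  invisible(x)
}

#' Run sheet with coded and natural columns
#'
#' @param x a `design_matrix`.
#' @param ... unused.
#' @return Data frame with `run`, one coded column per factor, and one
#'   natural-unit column per factor (suffix `_natural`); suitable for
#'   `write.csv()` run-sheet export.
#' @export
as.data.frame.design_matrix <- function(x, ...) {
  nat <- decode_levels(x$factors, x$coded)
  colnames(nat) <- paste0(x$factors$name, "_natural")
  data.frame(run = seq_len(nrow(x$coded)), x$coded, nat,
             check.names = FALSE)
}
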