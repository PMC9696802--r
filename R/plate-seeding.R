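# Poisson occupancy planning for limiting-dilution single-cell inoculation.
#
# Under limiting dilution the number of cells deposited in a well is
# Poisson(lambda), where lambda is the mean number of cells per well
# (cell density x well volume). The blank (no-growth) fraction of a plate
# estimates exp(-lambda), which is the lever used both to plan the dilution
# and to calibrate it from an observed plate.

#' Microplate geometry
#'
#' Describes the plate used for limiting-dilution inoculation: the number of
#' wells and the inoculated volume per well.
#'
#' @param n_wells number of wells (any positive integer; standard formats are
#'   6, 24, 96, 384 and 1536).
#' @param well_volume_ul inoculated volume per well, in microlitres (> 0).
#' @return An object of class `plate_spec`.
#' @examples
#' plate_spec(384, 60)
#' @export
plate_spec <- function(n_wells = 384, well_volume_ul = 60) {
  n_wells <- stop_if_not_count(n_wells, "n_wells", min = 1L)
  stop_if_not_scalar_number(well_volume_ul, "well_volume_ul",
                            min = 0, strict_min = TRUE)
  structure(list(n_wells = n_wells, well_volume_ul = well_volume_ul),
            class = "plate_spec")
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf("<plate_spec> %d wells, %g uL/well\n",
              x$n_wells, x$well_volume_ul))
  invisible(x)
}

#' Poisson occupancy model for well seeding
#'
#' `lambda` is the expected number of cells per well, i.e. the ratio of the
#' total number of inoculated cells to the number of wells. The probability
#' that a well receives k cells is the Poisson pmf at k.
#'
#' @param lambda expected cells per well (>= 0).
#' @param ci optional confidence interval on lambda (length-2 numeric), as
#'   attached by [calibrate_lambda()].
#' @param conf_level confidence level associated with `ci`.
#' @return An object of class `occupancy_model`.
#' @seealso [occupancy_pmf()], [calibrate_lambda()]
#' @export
occupancy_model <- function(lambda, ci = NULL, conf_level = NULL) {
  stop_if_not_scalar_number(lambda, "lambda", min = 0)
  if (!is.null(ci)) stopifnot(is.numeric(ci), length(ci) == 2L)
  structure(list(lambda = lambda, ci = ci, conf_level = conf_level),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf("<occupancy_model> lambda = %.4g (blank fraction %.4g)\n",
              x$lambda, exp(-x$lambda)))
  if (!is.null(x$ci))
    cat(sprintf("  %g%% CI: [%.4g, %.4g]\n",
                100 * (x$conf_level %||% 0.95), x$ci[1], x$ci[2]))
  invisible(x)
}

#' Probability that a well receives k cells
#'
#' Poisson pmf of the occupancy model: `exp(-lambda) * lambda^k / k!`.
#'
#' @param model an [occupancy_model()] (or a bare non-negative lambda).
#' @param k non-negative integer cell count(s); vectorised.
#' @return Probabilities in `[0, 1]`, one per element of `k`.
#' @examples
#' occupancy_pmf(occupancy_model(1.44), 0)  # expected blank fraction
#' @export
occupancy_pmf <- function(model, k) {
  lam <- if (inherits(model, "occupancy_model")) model$lambda else model
  stop_if_not_scalar_number(lam, "lambda", min = 0)
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0) ||
      any(k != floor(k)))
    stop("`k` must contain non-negative integers", call. = FALSE)
  stats::dpois(k, lam)
}

#' Cell density achieving a target blank fraction
#'
#' Inverts the occupancy model at k = 0: a target blank fraction `p0` fixes
#' `lambda = -log(p0)` and hence the cell density `lambda / V` for the
#' plate's well volume V. This is the dilution target for single-cell
#' inoculation (e.g. a 24.3% blank target in 60 uL wells calls for
#' ~23.6, in practice 24, CFU/mL).
#'
#' @param p0 target blank (empty-well) fraction, strictly between 0 and 1.
#' @param plate a [plate_spec()].
#' @return Cell density in CFU/mL.
#' @examples
#' density_for_blank_fraction(0.243, plate_spec(384, 60))
#' @export
density_for_blank_fraction <- function(p0, plate = plate_spec()) {
  stop_if_not_scalar_number(p0, "p0", min = 0, max = 1,
                            strict_min = TRUE, strict_max = TRUE)
  stopifnot(inherits(plate, "plate_spec"))
  -log(p0) / (plate$well_volume_ul / 1000)
}

#' Calibrate lambda from an observed plate census
#'
#' Estimates the seeding intensity from the observed number of blank wells:
#' `lambda_hat = -log(n_blank / n_wells)`. The confidence interval is the
#' exact Clopper-Pearson interval on the blank fraction, transformed through
#' `-log` (exact rather than asymptotic, because single plates give small
#' counts).
#'
#' @param n_blank number of blank (clear) wells; must be >= 1, since a plate
#'   with no blanks leaves lambda unidentifiable.
#' @param n_wells total wells inoculated.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An [occupancy_model()] with `ci` and `conf_level` set.
#' @examples
#' calibrate_lambda(96, 384)
#' @export
calibrate_lambda <- function(n_blank, n_wells, conf_level = 0.95) {
  n_wells <- stop_if_not_count(n_wells, "n_wells", min = 1L)
  n_blank <- stop_if_not_count(n_blank, "n_blank", min = 0L)
  stop_if_not_scalar_number(conf_level, "conf_level", min = 0, max = 1,
                            strict_min = TRUE, strict_max = TRUE)
  if (n_blank == 0L)
    stop("no blank wells observed: lambda is unidentifiable ",
         "(the plate is saturated); dilute further and re-plate",
         call. = FALSE)
  if (n_blank > n_wells)
    stop("`n_blank` cannot exceed `n_wells`", call. = FALSE)
  lam_hat <- -log(n_blank / n_wells)
  ci_p <- stats::binom.test(n_blank, n_wells,
                            conf.level = conf_level)$conf.int
  # low blank fraction <-> high lambda, so the interval flips
  occupancy_model(lam_hat, ci = rev(-log(ci_p)), conf_level = conf_level)
}

#' Is an observed blank fraction inside the acceptance band?
#'
#' Bench rule for judging a dilution level after incubation: the plate is
#' accepted when the clear-well fraction falls in a band (default 24-30%,
#' inclusive at both ends) chosen so that most occupied wells received one
#' or two cells.
#'
#' @param blank_fraction observed blank fraction in `[0, 1]`; vectorised.
#' @param band lower and upper bounds of the acceptance band.
#' @return Logical, `TRUE` where the dilution is acceptable.
#' @export
dilution_acceptable <- function(blank_fraction, band = c(0.24, 0.30)) {
  if (!is.numeric(blank_fraction) || any(!is.finite(blank_fraction)) ||
      any(blank_fraction < 0) || any(blank_fraction > 1))
    stop("`blank_fraction` must lie in [0, 1]", call. = FALSE)
  stopifnot(is.numeric(band), length(band) == 2L, band[1] <= band[2])
  blank_fraction >= band[1] & blank_fraction <= band[2]
}

#' Relative strain abundances in the inoculum
#'
#' @param proportions non-negative relative abundances, summing to 1
#'   (within 1e-9); unnormalised weights are accepted and normalised with a
#'   message suppressible via `normalise = TRUE`.
#' @param labels optional strain/taxon identifiers.
#' @param normalise divide by the total instead of insisting on sum 1.
#' @return An object of class `abundance_profile` (named numeric vector).
#' @export
abundance_profile <- function(proportions, labels = NULL, normalise = FALSE) {
  if (!is.numeric(proportions) || length(proportions) < 1L ||
      any(!is.finite(proportions)) || any(proportions < 0))
    stop("`proportions` must be non-negative finite numbers", call. = FALSE)
  tot <- sum(proportions)
  if (tot <= 0) stop("`proportions` must not all be zero", call. = FALSE)
  if (normalise) {
    proportions <- proportions / tot
  } else if (abs(tot - 1) > 1e-9) {
    stop("`proportions` must sum to 1 (got ", format(tot),
         "); use normalise = TRUE for raw weights", call. = FALSE)
  }
  labels <- labels %||% names(proportions) %||%
    paste0("strain", seq_along(proportions))
  stopifnot(length(labels) == length(proportions))
  structure(stats::setNames(as.numeric(proportions), labels),
            class = "abundance_profile")
}

#' Probability that an occupied well is a pure culture
#'
#' Conditional on a well showing growth (>= 1 cell), the probability that
#' every cell it received belongs to the same strain, for Poisson seeding at
#' intensity lambda over a community with the given relative abundances:
#' `sum_{k>=1} pmf(k) * sum_i p_i^k / (1 - pmf(0))`. The series is summed
#' until the retained Poisson mass exceeds 1 - 1e-12, which bounds the
#' truncation error explicitly.
#'
#' This predicts, e.g., the fraction of pure wells observed when a mixed
#' community is plated by limiting dilution; it decreases in lambda and
#' increases with community unevenness.
#'
#' @param model an [occupancy_model()] (or bare lambda > 0).
#' @param profile an [abundance_profile()] (or a bare proportion vector
#'   summing to 1).
#' @return Probability in `(0, 1]`.
#' @examples
#' purity_given_growth(occupancy_model(1.44), abundance_profile(c(0.5, 0.5)))
#' @export
purity_given_growth <- function(model, profile) {
  lam <- if (inherits(model, "occupancy_model")) model$lambda else model
  stop_if_not_scalar_number(lam, "lambda", min = 0)
  if (lam == 0)
    stop("lambda = 0: no wells are occupied, purity is undefined",
         call. = FALSE)
  if (!inherits(profile, "abundance_profile"))
    profile <- abundance_profile(profile)
  p <- as.numeric(profile)
  # truncate when cumulative Poisson mass exceeds 1 - 1e-12
  kmax <- 1L
  while (stats::ppois(kmax, lam) < 1 - 1e-12) kmax <- kmax + 1L
  k <- seq_len(kmax)
  pure_k <- vapply(k, function(kk) sum(p^kk), numeric(1))
  sum(stats::dpois(k, lam) * pure_k) / (1 - exp(-lam))
}

#' Plan a serial dilution series down to a target density
#'
#' Decomposes the total dilution ratio `stock / target` into an ordered
#' series of per-step dilution factors, greedy largest-step-first (coarse
#' steps then a fine remainder, matching bench serial-dilution practice),
#' with every step bounded by `max_step`.
#'
#' @param stock_cfu_ml stock culturable-cell density, CFU/mL.
#' @param target_cfu_ml target density after dilution, CFU/mL (<= stock).
#' @param max_step largest admissible per-step dilution factor (> 1;
#'   default 10, i.e. decimal series).
#' @param plate optional [plate_spec()]; when given, the returned plan also
#'   records the implied lambda and expected blank fraction.
#' @return An object of class `seeding_plan`: list with `dilution_steps`
#'   (possibly empty), `stock_cfu_ml`, `target_cfu_ml`, and when a plate is
#'   supplied `lambda` and `target_blank_fraction`.
#' @examples
#' plan_dilution_series(2.4e6, 24)
#' plan_dilution_series(240, 24, max_step = 5)
#' @export
plan_dilution_series <- function(stock_cfu_ml, target_cfu_ml, max_step = 10,
                                 plate = NULL) {
  stop_if_not_scalar_number(stock_cfu_ml, "stock_cfu_ml", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(target_cfu_ml, "target_cfu_ml", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(max_step, "max_step", min = 1, strict_min = TRUE)
  if (target_cfu_ml > stock_cfu_ml)
    stop("`target_cfu_ml` exceeds the stock density; cannot dilute upward",
         call. = FALSE)
  ratio <- stock_cfu_ml / target_cfu_ml
  steps <- numeric(0)
  while (ratio > max_step * (1 + 1e-12)) {
    steps <- c(steps, max_step)
    ratio <- ratio / max_step
  }
  if (ratio > 1 + 1e-12) steps <- c(steps, ratio)
  plan <- list(dilution_steps = steps,
               stock_cfu_ml = stock_cfu_ml,
               target_cfu_ml = target_cfu_ml)
  if (!is.null(plate)) {
    stopifnot(inherits(plate, "plate_spec"))
    plan$lambda <- target_cfu_ml * plate$well_volume_ul / 1000
    plan$target_blank_fraction <- exp(-plan$lambda)
  }
  structure(plan, class = "seeding_plan")
}

#' @export
print.seeding_plan <- function(x, ...) {
  cat("<seeding_plan>\n")
  cat(sprintf("  stock:  %g CFU/mL\n  target: %g CFU/mL\n",
              x$stock_cfu_ml, x$target_cfu_ml))
  if (length(x$dilution_steps) == 0) {
    cat("  no dilution needed\n")
  } else {
    cat("  steps:  ", paste0(format(x$dilution_steps, digits = 4), "x",
                             collapse = " -> "), "\n")
  }
  if (!is.null(x$lambda))
    cat(sprintf("  lambda = %.4g cells/well, expected blanks = %.1f%%\n",
                x$lambda, 100 * x$target_blank_fraction))
  invisible(x)
}
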