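# Surfactant-activity statistics: tension-reduction calls against a
# control, and CMC estimation from tension-vs-concentration curves.

#' Flag surfactant activity from replicate surface tensions
#'
#' Equal-variance two-sample (Student's) t-test of sample vs control
#' replicate tensions, two-tailed. A sample is called active only when the
#' difference is significant at `alpha` AND the sample mean is below the
#' control mean: an activity call requires a tension *reduction*, not any
#' difference.
#'
#' @param sample,control numeric replicate surface tensions (mN/m), at
#'   least 2 each (a variance estimate is needed).
#' @param alpha significance level (default 0.05).
#' @return List of class `activity_call`: `active`, `p`, `t`,
#'   `mean_sample`, `mean_control`, `reduction` (control - sample means).
#' @examples
#' flag_active(c(28.4, 28.6, 28.8), c(72.8, 72.5, 73.0))
#' @export
flag_active <- function(sample, control, alpha = 0.05) {
  check_tension <- function(x, name) {
    if (!is.numeric(x) || length(x) < 2L || anyNA(x))
      stop("`", name, "` needs >= 2 finite replicate tensions", call. = FALSE)
    if (any(x <= 0) || any(x >= 100))
      stop("`", name, "` tensions must lie in (0, 100) mN/m", call. = FALSE)
  }
  check_tension(sample, "sample"); check_tension(control, "control")
  stop_if_not_scalar_number(alpha, "alpha", min = 0, max = 1,
                            strict_min = TRUE)
  if (stats::sd(c(sample, control)) == 0) {
    # degenerate: all replicates identical, no evidence of any difference
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(sample, control, var.equal = TRUE)
  }
  p <- unname(tt$p.value)
  structure(list(active = p <= alpha && mean(sample) < mean(control),
                 p = p, t = unname(tt$statistic),
                 mean_sample = mean(sample), mean_control = mean(control),
                 reduction = mean(control) - mean(sample)),
            class = "activity_call")
}

#' @export
print.activity_call <- function(x, ...) {
  cat(sprintf(paste0("<activity_call> %s: sample %.2f vs control %.2f mN/m ",
                     "(reduction %.2f), p = %.3g\n"),
              if (x$active) "ACTIVE" else "not active",
              x$mean_sample, x$mean_control, x$reduction, x$p))
  invisible(x)
}

#' Estimate the critical micelle concentration from a tension curve
#'
#' Above the CMC added surfactant forms micelles and the surface tension
#' plateaus, so tension vs log10(concentration) is modelled as a continuous
#' two-segment line: a decreasing segment joined to a flat plateau at the
#' breakpoint. The breakpoint is chosen by least squares over an exhaustive
#' grid of `grid_size` candidates between the 2nd and (n-1)th observed
#' log-concentrations (deterministic, no initialisation sensitivity); the
#' decoded breakpoint is the CMC. A fit whose pre-break slope is not
#' negative means the curve never descends to a plateau and is reported as
#' "no CMC detected". A sustained tension *rise* before the breakpoint
#' (beyond residual noise) triggers a warning.
#'
#' @param concentration surfactant concentrations, mg/mL, strictly
#'   increasing, length >= 5; alternatively a data frame with columns
#'   `concentration` and `tension`.
#' @param tension surface tensions, mN/m, same length.
#' @param grid_size number of candidate breakpoints (default 200).
#' @return An object of class `cmc_estimate`: `detected`, `cmc` (mg/mL,
#'   `NA` when not detected), `plateau_tension` (mN/m), `slope` (mN/m per
#'   log10 mg/mL, negative), `sse`, and the fitted values.
#' @examples
#' cv <- simulate_tension_curve(cmc = 0.75, slope = -25, plateau = 28.6)
#' estimate_cmc(cv)
#' @export
estimate_cmc <- function(concentration, tension = NULL, grid_size = 200) {
  if (is.data.frame(concentration)) {
    tension <- concentration$tension
    concentration <- concentration$concentration
  }
  n <- length(concentration)
  if (n < 5L || length(tension) != n)
    stop("need >= 5 (concentration, tension) pairs", call. = FALSE)
  if (any(concentration <= 0) || any(diff(concentration) <= 0))
    stop("`concentration` must be positive and strictly increasing",
         call. = FALSE)
  grid_size <- stop_if_not_count(grid_size, "grid_size", min = 2L)
  if (stats::sd(tension) == 0)
    return(no_cmc(tension, reason = "tension curve is flat"))
  lx <- log10(concentration)
  bps <- seq(lx[2], lx[n - 1], length.out = grid_size)
  best <- list(sse = Inf)
  for (bp in bps) {
    z <- pmin(lx - bp, 0)           # ramp basis: slope before bp, 0 after
    vz <- sum((z - mean(z))^2)
    if (vz == 0) next
    slope <- sum((z - mean(z)) * (tension - mean(tension))) / vz
    a <- mean(tension) - slope * mean(z)   # plateau level
    sse <- sum((a + slope * z - tension)^2)
    if (slope < 0 && sse < best$sse)
      best <- list(sse = sse, bp = bp, slope = slope, plateau = a)
  }
  if (!is.finite(best$sse))
    return(no_cmc(tension, reason = "no decreasing segment found"))
  z <- pmin(lx - best$bp, 0)
  fitted <- best$plateau + best$slope * z
  # robust residual scale so a single aberrant point cannot mask itself
  scale_rob <- 1.4826 * stats::median(abs(tension - fitted))
  pre <- lx < best$bp
  if (sum(pre) >= 2 && any(diff(tension[pre]) > 3 * scale_rob + 1e-9))
    warning("tension rises before the breakpoint: the pre-CMC segment is ",
            "not monotone decreasing", call. = FALSE)
  structure(list(detected = TRUE, cmc = 10^best$bp,
                 plateau_tension = best$plateau, slope = best$slope,
                 sse = best$sse, fitted = fitted,
                 grid = range(10^bps)),
            class = "cmc_estimate")
}

no_cmc <- function(tension, reason) {
  structure(list(detected = FALSE, cmc = NA_real_,
                 plateau_tension = mean(tension), slope = NA_real_,
                 sse = sum((tension - mean(tension))^2), fitted = NULL,
                 reason = reason),
            class = "cmc_estimate")
}

#' @export
print.cmc_estimate <- function(x, ...) {
  if (!x$detected) {
    cat("<cmc_estimate> no CMC detected:", x$reason, "\n")
  } else {
    cat(sprintf(paste0("<cmc_estimate> CMC = %.4g mg/mL, plateau %.2f mN/m, ",
                       "pre-break slope %.3g mN/m per log10(mg/mL)\n"),
                x$cmc, x$plateau_tension, x$slope))
  }
  invisible(x)
}
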