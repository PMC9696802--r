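# Published optimization experiment for the glycolipid producer
# Pseudomonas sp. L01, shipped as plain-R constructors: the five-factor
# screening table, the steepest-ascent run sheet, and the fitted quadratic
# yield surface with its coded-variable transform. These are the worked
# inputs for the examples, tests and the reproduction script.

#' Screening table for the L01 glycolipid yield study
#'
#' Five-factor two-level screen of crude-glycolipid yield for
#' *Pseudomonas* sp. L01: factor levels, main effects (g/L), t statistics
#' and two-sided p-values at 6 residual degrees of freedom (12-run
#' Plackett-Burman screen, intercept + 5 main effects). NaNO3
#' concentration and cultivation time screen as significant, both with
#' positive effects.
#'
#' @return Data frame with columns `factor`, `units`, `low`, `high`,
#'   `effect`, `t`, `p`, plus `residual_df` as an attribute (6).
#' @export
l01_pb_screen <- function() {
  out <- data.frame(
    factor = c("glucose", "NaNO3", "PO4", "pH", "time"),
    units = c("g/L", "g/L", "g/L", "", "h"),
    low = c(20, 1, 20, 6.8, 108),
    high = c(30, 3, 25, 7.2, 132),
    effect = c(0.1120, 1.0537, 0.1637, -0.1480, 0.2520),
    t = c(1.19, 11.15, 1.73, -1.57, 2.67),
    p = c(0.281, 0.000, 0.134, 0.168, 0.037),
    stringsAsFactors = FALSE)
  attr(out, "residual_df") <- 6L
  out
}

#' Steepest-ascent run sheet for the L01 yield study
#'
#' Five trials moving NaNO3 (g/L), PO4^3- (g/L) and cultivation time (h)
#' in uniform increments (0.5, 1.25, 6) from the screening low levels to
#' the high levels, with the measured crude-glycolipid yields (g/L). The
#' yield peaks at trial 4, whose levels centre the follow-up Box-Behnken
#' design.
#'
#' @return Data frame with columns `trial`, `NaNO3`, `PO4`, `time`,
#'   `yield`.
#' @export
l01_ascent <- function() {
  data.frame(
    trial = 1:5,
    NaNO3 = c(1.0, 1.5, 2.0, 2.5, 3.0),
    PO4 = c(20, 21.25, 22.5, 23.75, 25),
    time = c(108, 114, 120, 126, 132),
    yield = c(3.55, 6.09, 6.97, 8.23, 6.06))
}

#' Coded-variable transform of the L01 Box-Behnken design
#'
#' Factor table for the response-surface stage: centres are the
#' steepest-ascent trial-4 levels (2.5 g/L NaNO3, 23.75 g/L PO4^3-, 126 h)
#' and steps are the ascent increments (0.5 g/L, 1.25 g/L, 6 h), so coded
#' -1/+1 spans one ascent step either side of the best trial.
#'
#' @return A [factor_def()] with factors `NaNO3`, `PO4`, `time`.
#' @export
l01_bbd_factors <- function() {
  factor_def(c("NaNO3", "PO4", "time"),
             center = c(2.5, 23.75, 126), step = c(0.5, 1.25, 6),
             units = c("g/L", "g/L", "h"))
}

#' Fitted quadratic yield surface for L01
#'
#' The second-order polynomial for crude-glycolipid yield (g/L) on coded
#' variables B (NaNO3), C (PO4^3-) and E (time), fitted to the centerless
#' 3-factor Box-Behnken design centred on ascent trial 4:
#' `Y = 8.21 - 0.4175 B - 0.125 C + 0.03 E + 0.0325 BC - 0.0075 BE
#'  - 0.0075 CE - 1.15 B^2 - 0.18 C^2`.
#' The E^2 term is aliased with the intercept on the centerless design and
#' is absent (it contributes 0). The model is linear in E, so its
#' box-constrained maximiser puts time on the +1 boundary (132 h).
#'
#' @return A [quadratic_model()] carrying the [l01_bbd_factors()] coding,
#'   with factors named `NaNO3` (B), `PO4` (C), `time` (E).
#' @examples
#' m <- l01_yield_model()
#' predict(m, c(0, 0, 0))  # yield at the design centre
#' optimize_box(m)         # optimal medium and predicted yield
#' @export
l01_yield_model <- function() {
  quadratic_model(
    intercept = 8.21,
    linear = c(NaNO3 = -0.4175, PO4 = -0.125, time = 0.03),
    interaction = c("NaNO3:PO4" = 0.0325, "NaNO3:time" = -0.0075,
                    "PO4:time" = -0.0075),
    quadratic = c(NaNO3 = -1.15, PO4 = -0.18),
    factors = l01_bbd_factors())
}

#' Response-surface ANOVA table for the L01 yield model
#'
#' The published partial-SS ANOVA of the quadratic yield fit on the
#' centerless Box-Behnken design: per-term sums of squares, df, mean
#' squares and F statistics against the 3-df residual. The aliased time
#' quadratic (`time^2`) carries 0 df; the corrected total df is 11
#' (12 runs).
#'
#' @return Data frame of class `rsm_anova` with columns `source`, `ss`,
#'   `df`, `ms`, `f`, `p` (p as printed, 4 decimals).
#' @export
l01_bbd_anova <- function() {
  out <- data.frame(
    source = c("Model", "NaNO3", "PO4", "time", "NaNO3:PO4", "NaNO3:time",
               "PO4:time", "NaNO3^2", "PO4^2", "time^2", "Residual",
               "Cor Total"),
    ss = c(4.58, 1.39, 0.0841, 0.0072, 0.0042, 0.0002, 0.0002, 2.67,
           0.0648, 0, 0.0150, 4.59),
    df = c(8L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 3L, 11L),
    ms = c(0.5725, 1.39, 0.0841, 0.0072, 0.0042, 0.0002, 0.0002, 2.67,
           0.0648, NA, 0.0050, NA),
    f = c(114.11, 277.96, 16.75, 1.44, 0.8422, 0.0449, 0.0449, 531.84,
          12.92, NA, NA, NA),
    p = c(0.0012, 0.0005, 0.0264, 0.3169, 0.4264, 0.8459, 0.8459, 0.0002,
          0.0369, NA, NA, NA),
    stringsAsFactors = FALSE)
  class(out) <- c("rsm_anova", "data.frame")
  out
}
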