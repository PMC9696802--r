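# Synthetic-data generators: Poisson-seeded plates from a strain abundance
# profile, response-surface runs from a known quadratic surface, and
# tension curves with a known breakpoint. Every generator takes an explicit
# seed and records its configuration, so all downstream stages are testable
# without laboratory data.

#' Simulate a Poisson-seeded microplate
#'
#' Cell counts per well are Poisson(`lambda`); each deposited cell's strain
#' is drawn independently from the abundance profile; each cell then founds
#' a culture with probability `growth_prob` (Bernoulli thinning, so the
#' effective seeding intensity of grown cells is `lambda * growth_prob`).
#' OD600 is a two-level signal: `blank_od` for wells with no grown cell,
#' `blank_od + signal_od` otherwise (sufficient for growth-call testing; no
#' growth kinetics are modelled).
#'
#' @param n_wells number of wells (or a [plate_spec()]).
#' @param lambda expected cells per well (>= 0), or an [occupancy_model()].
#' @param profile an [abundance_profile()]; default a single strain.
#' @param growth_prob per-cell probability of founding a culture, in
#'   `[0, 1]`.
#' @param blank_od,signal_od OD600 baseline and added growth signal.
#' @param seed RNG seed; the simulation uses one global stream seeded here.
#' @return List of class `plate_sim`: `wells` (data frame: `well`,
#'   `n_seeded`, `n_grown`, `n_strains`, `pure` (`NA` for blanks), `od600`,
#'   `growth`), `cells` (data frame: `well`, `strain` for every grown
#'   cell), and `config` (inputs incl. seed).
#' @examples
#' sim <- simulate_plate(384, lambda = 1.44,
#'                       profile = abundance_profile(c(0.5, 0.5)), seed = 1)
#' mean(!sim$wells$growth)  # blank fraction near exp(-1.44)
#' @export
simulate_plate <- function(n_wells, lambda, profile = NULL, growth_prob = 1,
                           blank_od = 0.04, signal_od = 0.5, seed = NULL) {
  if (inherits(n_wells, "plate_spec")) n_wells <- n_wells$n_wells
  n_wells <- stop_if_not_count(n_wells, "n_wells", min = 1L)
  if (inherits(lambda, "occupancy_model")) lambda <- lambda$lambda
  stop_if_not_scalar_number(lambda, "lambda", min = 0)
  stop_if_not_scalar_number(growth_prob, "growth_prob", min = 0, max = 1)
  profile <- if (is.null(profile)) abundance_profile(1) else
    if (inherits(profile, "abundance_profile")) profile else
      abundance_profile(profile)
  if (!is.null(seed)) set.seed(seed)

  n_seeded <- stats::rpois(n_wells, lambda)
  n_grown <- stats::rbinom(n_wells, n_seeded, growth_prob)
  total <- sum(n_grown)
  strains <- sample.int(length(profile), total, replace = TRUE,
                        prob = as.numeric(profile))
  well_of <- rep.int(seq_len(n_wells), n_grown)
  # a well is pure iff all its grown cells carry the first cell's strain
  occ <- which(n_grown > 0L)
  starts <- cumsum(n_grown)[occ] - n_grown[occ] + 1L
  first <- strains[starts]
  mism <- strains != rep.int(first, n_grown[occ])
  impure <- rowsum(as.integer(mism), well_of) > 0L
  pure <- rep(NA, n_wells)
  pure[occ] <- !impure[, 1]
  # distinct strains per occupied well via numeric (well, strain) keys
  key <- as.numeric(well_of) * (length(profile) + 1) + strains
  n_strains <- integer(n_wells)
  n_strains[occ] <- rowsum(as.integer(!duplicated(key)), well_of)[, 1]
  growth <- n_grown > 0L
  wells <- data.frame(well = seq_len(n_wells), n_seeded = n_seeded,
                      n_grown = n_grown, n_strains = n_strains,
                      pure = pure,
                      od600 = blank_od + signal_od * growth,
                      growth = growth)
  structure(list(
    wells = wells,
    cells = data.frame(well = well_of,
                       strain = names(profile)[strains]),
    config = list(n_wells = n_wells, lambda = lambda,
                  profile = as.numeric(profile),
                  labels = names(profile), growth_prob = growth_prob,
                  blank_od = blank_od, signal_od = signal_od, seed = seed)
  ), class = "plate_sim")
}

#' @export
print.plate_sim <- function(x, ...) {
  w <- x$wells
  cat(sprintf(paste0("<plate_sim> %d wells, lambda = %g: %.1f%% blank, ",
                     "%.1f%% of grown wells pure (seed %s)\n"),
              nrow(w), x$config$lambda, 100 * mean(!w$growth),
              100 * mean(w$pure[w$growth]),
              x$config$seed %||% "unset"))
  invisible(x)
}

#' Simulate response-surface run responses
#'
#' Responses are the true surface evaluated at each design run plus iid
#' Gaussian noise: `y = predict(model, run) + N(0, noise_sd^2)`.
#'
#' @param model the true [quadratic_model()].
#' @param design a [design_matrix()] whose factors match the model.
#' @param noise_sd response-unit noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return Numeric response vector, one per run, with the configuration in
#'   `attr(, "config")`.
#' @export
simulate_responses <- function(model, design, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "quadratic_model"),
            inherits(design, "design_matrix"))
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(model, design$coded)
  y <- mu + stats::rnorm(length(mu), 0, noise_sd)
  attr(y, "config") <- list(noise_sd = noise_sd, seed = seed)
  y
}

#' Simulate a surface-tension vs concentration curve
#'
#' Log-spaced concentrations spanning `conc_range`; tension is linear and
#' decreasing in log10(concentration) down to the breakpoint (the CMC),
#' flat at `plateau` beyond it, plus iid Gaussian noise.
#'
#' @param cmc true breakpoint concentration, mg/mL; must lie inside
#'   `conc_range`.
#' @param slope pre-break slope, mN/m per log10(mg/mL); must be negative
#'   (tension falls as surfactant is added below the CMC).
#' @param plateau post-break tension, mN/m (> 0).
#' @param n_points number of concentrations (>= 5).
#' @param noise_sd tension noise SD, mN/m (>= 0).
#' @param conc_range low/high concentration bounds, mg/mL.
#' @param seed RNG seed.
#' @return A data frame of class `tension_curve` with columns
#'   `concentration`, `tension`; generator parameters in
#'   `attr(, "config")`.
#' @examples
#' simulate_tension_curve(cmc = 0.75, slope = -25, plateau = 28.6, seed = 1)
#' @export
simulate_tension_curve <- function(cmc, slope, plateau, n_points = 12,
                                   noise_sd = 0,
                                   conc_range = c(cmc / 50, cmc * 20),
                                   seed = NULL) {
  stop_if_not_scalar_number(cmc, "cmc", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(slope, "slope", max = 0, strict_max = TRUE)
  stop_if_not_scalar_number(plateau, "plateau", min = 0, strict_min = TRUE)
  n_points <- stop_if_not_count(n_points, "n_points", min = 5L)
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot(length(conc_range) == 2L, conc_range[1] > 0,
            conc_range[1] < conc_range[2])
  if (cmc < conc_range[1] || cmc > conc_range[2])
    stop("`cmc` must lie inside `conc_range`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  conc <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                 length.out = n_points)
  tension <- plateau + slope * pmin(log10(conc) - log10(cmc), 0) +
    stats::rnorm(n_points, 0, noise_sd)
  out <- data.frame(concentration = conc, tension = tension)
  attr(out, "config") <- list(cmc = cmc, slope = slope, plateau = plateau,
                              n_points = n_points, noise_sd = noise_sd,
                              conc_range = conc_range, seed = seed)
  class(out) <- c("tension_curve", "data.frame")
  out
}
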