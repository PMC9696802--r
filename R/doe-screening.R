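# Plackett-Burman screening: 12-run design generation, main-effect
# inference, and the steepest-ascent path that follows screening.

# standard first row of the cyclic 12-run construction
pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

#' Generate the 12-run Plackett-Burman screening design
#'
#' Builds the standard cyclic 12-run two-level design: eleven rows are the
#' cyclic shifts of the generator row (+ + - + + + - - - + -) and the
#' twelfth is all -1. The first k of the 11 columns carry the supplied
#' factors; every column is balanced (six +1, six -1) and any two columns
#' are orthogonal, so all main effects are estimated independently and with
#' equal precision.
#'
#' @param factors a [factor_def()] table with 1 to 11 rows, or a character
#'   vector of names (levels then default to -1/+1 coded units).
#' @return A [design_matrix()] of kind `"pb"`.
#' @examples
#' generate_pb12(factor_def(c("glucose", "NaNO3", "PO4", "pH", "time"),
#'                          low  = c(20, 1, 20, 6.8, 108),
#'                          high = c(30, 3, 25, 7.2, 132)))
#' @export
generate_pb12 <- function(factors) {
  if (is.character(factors))
    factors <- factor_def(factors, low = rep(-1, length(factors)),
                          high = rep(1, length(factors)))
  factors <- as_factor_def(factors)
  k <- nrow(factors)
  if (k < 1L || k > 11L)
    stop("the 12-run Plackett-Burman design screens 1 to 11 factors",
         call. = FALSE)
  full <- t(vapply(0:10, function(s) {
    idx <- ((seq_len(11) - 1 + s) %% 11) + 1
    pb12_generator[idx]
  }, numeric(11)))
  full <- rbind(full, rep(-1, 11))
  design_matrix(full[, seq_len(k), drop = FALSE], factors, kind = "pb")
}

#' Fit main effects to a Plackett-Burman screen
#'
#' Least-squares fit of intercept plus the k main effects on the coded
#' design. The effect of a factor is the mean response at its high level
#' minus the mean at its low level (twice the coded regression
#' coefficient). Orthogonality makes the standard error identical across
#' factors: `se(effect) = 2 * sqrt(MSE / n)`. Each effect is tested with a
#' two-sided t-test on the residual degrees of freedom `n - k - 1`.
#'
#' @param design a PB [design_matrix()].
#' @param responses numeric response vector, one value per run.
#' @return An object of class `pb_fit`: data frame `effects` with columns
#'   `factor`, `effect`, `se`, `t`, `p`, plus `residual_df`, `sigma2`
#'   (residual mean square) and `intercept`.
#' @export
fit_pb <- function(design, responses) {
  stopifnot(inherits(design, "design_matrix"))
  if (design$kind != "pb")
    stop("`design` must be a Plackett-Burman design", call. = FALSE)
  n <- nrow(design$coded)
  if (length(responses) != n || anyNA(responses))
    stop("`responses` must supply one finite value per run (", n, ")",
         call. = FALSE)
  k <- ncol(design$coded)
  df_res <- n - k - 1L
  if (df_res <= 0L)
    stop("no residual degrees of freedom: fewer factors are needed",
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1, design$coded)
  fit <- stats::lm.fit(X, responses)
  mse <- sum(fit$residuals^2) / df_res
  effect <- 2 * fit$coefficients[-1]
  # numerically exact fit (e.g. constant responses): zero out rounding
  # residue so that null effects report t = 0, p = 1
  zero_tol <- 1e-10 * max(1, sqrt(mean(responses^2)))
  if (sqrt(mse) < zero_tol) {
    mse <- 0
    effect[abs(effect) < zero_tol] <- 0
  }
  se <- 2 * sqrt(mse / n)
  t <- if (se == 0) ifelse(effect == 0, 0, sign(effect) * Inf) else
    effect / se
  structure(list(
    effects = data.frame(factor = design$factors$name,
                         effect = unname(effect), se = se, t = unname(t),
                         p = pvalue_from_t(t, df_res),
                         stringsAsFactors = FALSE),
    residual_df = df_res, sigma2 = mse,
    intercept = unname(fit$coefficients[1])
  ), class = "pb_fit")
}

#' Two-sided p-value for a main-effect t statistic
#'
#' The tail mapping used in screening-design tables: `2 * P(T_df > |t|)`.
#'
#' @param t t statistic(s).
#' @param df residual degrees of freedom.
#' @return Two-sided p-value(s).
#' @export
pvalue_from_t <- function(t, df) {
  unname(2 * stats::pt(-abs(t), df))
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("<pb_fit> %d factors, residual df = %d, MSE = %.4g\n",
              nrow(x$effects), x$residual_df, x$sigma2))
  print(format(x$effects, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Select significant screening factors
#'
#' Factors whose two-sided p-value is at or below `alpha`, annotated with
#' the sign of their effect (the direction a steepest-ascent path should
#' move them).
#'
#' @param result a [fit_pb()] result, or any data frame with columns
#'   `factor` (or `name`), `effect` and `p` — e.g. a published screening
#'   table.
#' @param alpha significance level (default 0.05).
#' @return Data frame with columns `factor`, `effect`, `p`, `sign`
#'   (`"+"`/`"-"`); zero rows when nothing reaches `alpha`.
#' @export
significant_factors <- function(result, alpha = 0.05) {
  stop_if_not_scalar_number(alpha, "alpha", min = 0, max = 1,
                            strict_min = TRUE)
  tab <- if (inherits(result, "pb_fit")) result$effects else
    as.data.frame(result)
  if (is.null(tab$factor)) tab$factor <- tab$name
  if (is.null(tab$factor) || is.null(tab$effect) || is.null(tab$p))
    stop("`result` must provide factor, effect and p columns", call. = FALSE)
  hit <- tab$p <= alpha
  data.frame(factor = tab$factor[hit], effect = tab$effect[hit],
             p = tab$p[hit],
             sign = ifelse(tab$effect[hit] >= 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Build a steepest-ascent experiment path
#'
#' A sequence of `n_trials` experiments moving each factor in uniform
#' natural-unit increments from `start` to `end`:
#' `trial_j = start + (j - 1) * (end - start) / (n_trials - 1)`.
#' By default the path spans the screening-design range of each carried
#' factor in the direction of its (positive) effect; pass a reversed
#' start/end pair for factors with negative effects.
#'
#' @param start,end named numeric vectors of natural levels (same names,
#'   same order); at least one factor must actually move.
#' @param n_trials number of trials on the path (>= 2).
#' @return An object of class `ascent_path`: data frame with column `trial`
#'   and one column per factor; increments stored in
#'   `attr(, "increments")`.
#' @examples
#' build_ascent_path(c(NaNO3 = 1, PO4 = 20, time = 108),
#'                   c(NaNO3 = 3, PO4 = 25, time = 132), n_trials = 5)
#' @export
build_ascent_path <- function(start, end, n_trials) {
  n_trials <- stop_if_not_count(n_trials, "n_trials", min = 2L)
  if (length(start) != length(end))
    stop("`start` and `end` must have the same length", call. = FALSE)
  if (!is.null(names(start)) && !is.null(names(end)) &&
      !identical(names(start), names(end)))
    stop("`start` and `end` must name the same factors in the same order",
         call. = FALSE)
  if (all(end == start))
    stop("`start` equals `end` for every factor: no direction to ascend",
         call. = FALSE)
  inc <- (end - start) / (n_trials - 1)
  j <- seq_len(n_trials)
  trials <- outer(j - 1, inc) + rep(start, each = n_trials)
  colnames(trials) <- names(start) %||% paste0("x", seq_along(start))
  path <- data.frame(trial = j, trials, check.names = FALSE)
  attr(path, "increments") <- inc
  class(path) <- c("ascent_path", "data.frame")
  path
}

#' Select the ascent trial to centre the follow-up design on
#'
#' Picks the trial with the maximal yield (the first such trial on ties)
#' and returns its factor levels for use as the centre point of a
#' response-surface design. Warns when the maximum sits on the last trial
#' (the optimum may lie beyond the path) and on ties.
#'
#' @param path an [build_ascent_path()] result, or any data frame whose
#'   first column is `trial` and remaining non-yield columns are factor
#'   levels.
#' @param yields response values, one per trial; taken from a `yield`
#'   column of `path` when present.
#' @return List with `trial`, `levels` (named numeric vector) and `yield`.
#' @export
select_center <- function(path, yields = NULL) {
  path <- as.data.frame(path)
  if (is.null(yields)) yields <- path$yield
  if (is.null(yields) || length(yields) != nrow(path) || anyNA(yields))
    stop("yields must be supplied for every trial", call. = FALSE)
  best <- which.max(yields)  # first maximal index
  if (sum(yields == yields[best]) > 1L)
    warning("tied maximal yields; taking the earliest trial", call. = FALSE)
  if (best == nrow(path))
    warning("maximum yield sits on the last trial: the optimum may lie ",
            "beyond the explored path", call. = FALSE)
  lev_cols <- setdiff(names(path), c("trial", "yield"))
  list(trial = path$trial[best] %||% best,
       levels = unlist(path[best, lev_cols]),
       yield = yields[best])
}
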