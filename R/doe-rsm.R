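# Box-Behnken response-surface stage: design generation (including the
# centerless 3-factor variant, whose three quadratic columns are collinear
# with the intercept), quadratic model fitting, partial-SS ANOVA, and exact
# box-constrained maximisation of the fitted surface.

#' Generate a 3-factor Box-Behnken design
#'
#' The 12 edge-midpoint runs of the factor cube,
#' (+-1, +-1, 0), (+-1, 0, +-1), (0, +-1, +-1), plus `n_center` centre
#' replicates. With `n_center = 0` the design has 12 runs and corrected
#' total df 11; every run then satisfies x1^2 + x2^2 + x3^2 = 2, so the
#' three quadratic columns are collinear with the intercept and only two of
#' the three quadratic coefficients are estimable (see
#' [detect_aliasing()]).
#'
#' @param factors a [factor_def()] table with exactly 3 rows, or a
#'   character vector of 3 names.
#' @param n_center number of centre-point replicates (>= 0; default 0).
#' @return A [design_matrix()] of kind `"bbd"`.
#' @export
generate_bbd <- function(factors, n_center = 0) {
  if (is.character(factors))
    factors <- factor_def(factors, low = rep(-1, length(factors)),
                          high = rep(1, length(factors)))
  factors <- as_factor_def(factors)
  if (nrow(factors) != 3L)
    stop("only the 3-factor Box-Behnken design is supported", call. = FALSE)
  n_center <- stop_if_not_count(n_center, "n_center", min = 0L)
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  edge <- rbind(cbind(pm[, 1], pm[, 2], 0),
                cbind(pm[, 1], 0, pm[, 2]),
                cbind(0, pm[, 1], pm[, 2]))
  coded <- rbind(edge, matrix(0, nrow = n_center, ncol = 3))
  design_matrix(coded, factors, kind = "bbd")
}

# canonical term strings: factor names, "A:B" interactions, "A^2" quadratics
full_quadratic_terms <- function(fnames) {
  pairs <- if (length(fnames) > 1) utils::combn(fnames, 2, paste,
                                                collapse = ":") else character(0)
  c(fnames, pairs, paste0(fnames, "^2"))
}

# model matrix (with intercept) for a coded run matrix and term strings
build_model_matrix <- function(coded, terms) {
  fnames <- colnames(coded)
  cols <- lapply(terms, function(tm) {
    if (tm %in% fnames) return(coded[, tm])
    if (grepl(":", tm, fixed = TRUE)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (!all(parts %in% fnames))
        stop("unknown factor in term `", tm, "`", call. = FALSE)
      return(coded[, parts[1]] * coded[, parts[2]])
    }
    if (grepl("\\^2$", tm)) {
      f <- sub("\\^2$", "", tm)
      if (!f %in% fnames)
        stop("unknown factor in term `", tm, "`", call. = FALSE)
      return(coded[, f]^2)
    }
    stop("unparseable model term `", tm, "`", call. = FALSE)
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  X
}

#' Report which quadratic-model terms a design can estimate
#'
#' Rank analysis of the model matrix for the candidate terms. When the
#' columns are linearly dependent — on the centerless 3-factor Box-Behnken
#' design the three quadratic columns sum to twice the intercept column —
#' quadratic terms are dropped, last declared factor first (configurable
#' via `prefer_drop`), until the matrix has full column rank. Dropped terms
#' are reported with zero degrees of freedom.
#'
#' @param design a [design_matrix()].
#' @param terms candidate term strings (factor names, `"A:B"`, `"A^2"`);
#'   default full quadratic. The intercept is implicit and never droppable.
#' @param prefer_drop term names to drop first when rank-deficient.
#' @return List with `estimable` (term strings), `dropped` (term strings,
#'   possibly empty) and `rank` of the full candidate matrix including the
#'   intercept.
#' @export
detect_aliasing <- function(design, terms = NULL, prefer_drop = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  terms <- terms %||% full_quadratic_terms(design$factors$name)
  X <- build_model_matrix(design$coded, terms)
  full_rank <- qr(X)$rank
  dropped <- character(0)
  # drop order: preferred names first, then quadratics of later factors
  quad <- terms[grepl("\\^2$", terms)]
  order_drop <- c(intersect(prefer_drop %||% character(0), terms),
                  rev(quad))
  keep <- terms
  while (qr(build_model_matrix(design$coded, keep))$rank <
         length(keep) + 1L) {
    cand <- order_drop[order_drop %in% keep][1]
    if (is.na(cand))
      stop("model matrix is rank-deficient but no droppable quadratic ",
           "term remains; reduce the candidate terms", call. = FALSE)
    dropped <- c(dropped, cand)
    keep <- setdiff(keep, cand)
  }
  list(estimable = keep, dropped = dropped, rank = full_rank)
}

#' Quadratic response-surface model on coded variables
#'
#' Container for a second-order polynomial
#' `Y = b0 + sum b_i x_i + sum b_ij x_i x_j + sum b_ii x_i^2` on coded
#' variables. Terms absent from `interaction`/`quadratic` (e.g. a quadratic
#' aliased out on a centerless design) contribute exactly 0.
#'
#' @param intercept response at the coded origin.
#' @param linear named coefficient per factor (names fix the factor order).
#' @param interaction named coefficients, names `"A:B"` (may be empty).
#' @param quadratic named coefficients per factor (subset allowed).
#' @param factors optional [factor_def()] carrying the coding
#'   (centre/step) for [decode_levels()] of optima.
#' @return An object of class `quadratic_model`.
#' @examples
#' quadratic_model(8.21, c(B = -0.4175, C = -0.125, E = 0.03),
#'                 interaction = c("B:C" = 0.0325),
#'                 quadratic = c(B = -1.15, C = -0.18))
#' @export
quadratic_model <- function(intercept, linear, interaction = numeric(0),
                            quadratic = numeric(0), factors = NULL) {
  stop_if_not_scalar_number(intercept, "intercept")
  if (is.null(names(linear)))
    stop("`linear` must be a named coefficient vector", call. = FALSE)
  fnames <- names(linear)
  if (length(quadratic) && !all(names(quadratic) %in% fnames))
    stop("quadratic terms name unknown factors", call. = FALSE)
  if (length(interaction)) {
    parts <- strsplit(names(interaction), ":", fixed = TRUE)
    if (!all(vapply(parts, length, 1L) == 2L) ||
        !all(unlist(parts) %in% fnames))
      stop("interaction names must be `A:B` over the linear factors",
           call. = FALSE)
  }
  if (!is.null(factors)) {
    factors <- as_factor_def(factors)
    stopifnot(identical(factors$name, fnames))
  }
  structure(list(intercept = intercept, linear = linear,
                 interaction = interaction, quadratic = quadratic,
                 factors = factors),
            class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  co <- c(x$linear, x$interaction,
          if (length(x$quadratic))
            stats::setNames(x$quadratic, paste0(names(x$quadratic), "^2")))
  terms <- sprintf("%+.4g*%s", co, names(co))
  cat("<quadratic_model> Y =", format(x$intercept, digits = 6),
      paste(terms, collapse = " "), "\n")
  invisible(x)
}

# symmetric matrix Q and vector b so that Y = b0 + b'x + x'Qx
model_qb <- function(model) {
  fn <- names(model$linear)
  k <- length(fn)
  Q <- matrix(0, k, k, dimnames = list(fn, fn))
  if (length(model$quadratic))
    diag(Q)[names(model$quadratic)] <- model$quadratic
  for (nm in names(model$interaction)) {
    ij <- strsplit(nm, ":", fixed = TRUE)[[1]]
    Q[ij[1], ij[2]] <- Q[ij[1], ij[2]] + model$interaction[[nm]] / 2
    Q[ij[2], ij[1]] <- Q[ij[2], ij[1]] + model$interaction[[nm]] / 2
  }
  list(b0 = model$intercept, b = unname(model$linear), Q = Q, fnames = fn)
}

#' Evaluate a quadratic model at coded points
#'
#' @param object a [quadratic_model()] (or the `model` element of a
#'   [fit_quadratic()] result).
#' @param newdata coded point(s): vector of length k, or a matrix/data
#'   frame with one column per factor in model order.
#' @param ... unused.
#' @return Numeric predictions, one per row of `newdata`.
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  qb <- model_qb(object)
  X <- coerce_level_matrix(newdata, length(qb$b))
  drop(qb$b0 + X %*% qb$b + rowSums((X %*% qb$Q) * X))
}

#' Fit a quadratic model to response-surface runs
#'
#' Ordinary least squares of the responses on the coded model terms.
#' Aliasing is resolved first ([detect_aliasing()]): on the centerless
#' 3-factor Box-Behnken design the default drops the last factor's
#' quadratic term, which is then reported with 0 df by [anova_partial()].
#' With zero residual df the fit interpolates the runs exactly (and ANOVA
#' is unavailable).
#'
#' @param design a [design_matrix()].
#' @param responses numeric response vector, one per run.
#' @param terms candidate term strings; default full quadratic.
#' @param prefer_drop passed to [detect_aliasing()].
#' @return An object of class `quadratic_fit`: list with `model` (a
#'   [quadratic_model()]), `dropped`, `terms`, `fitted`, `residuals`,
#'   `df_residual`, `sigma2`, `r_squared`, and the design.
#' @export
fit_quadratic <- function(design, responses, terms = NULL,
                          prefer_drop = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  n <- nrow(design$coded)
  if (length(responses) != n || anyNA(responses))
    stop("`responses` must supply one finite value per run (", n, ")",
         call. = FALSE)
  al <- detect_aliasing(design, terms, prefer_drop)
  X <- build_model_matrix(design$coded, al$estimable)
  if (qr(X)$rank < ncol(X))
    stop("model matrix still rank-deficient after aliasing removal",
         call. = FALSE)
  fit <- stats::lm.fit(X, responses)
  co <- fit$coefficients
  fn <- design$factors$name
  linear <- stats::setNames(rep(0, length(fn)), fn)
  linear[intersect(fn, al$estimable)] <- co[intersect(fn, al$estimable)]
  inter <- co[grepl(":", names(co), fixed = TRUE)]
  quad_terms <- al$estimable[grepl("\\^2$", al$estimable)]
  quad <- stats::setNames(unname(co[quad_terms]),
                          sub("\\^2$", "", quad_terms))
  df_res <- n - ncol(X)
  sse <- sum(fit$residuals^2)
  sst <- sum((responses - mean(responses))^2)
  structure(list(
    model = quadratic_model(unname(co[1]), linear, inter, quad,
                            factors = design$factors),
    dropped = al$dropped, terms = al$estimable,
    fitted = fit$fitted.values %||% drop(X %*% co),
    residuals = unname(fit$residuals), df_residual = df_res,
    sigma2 = if (df_res > 0) sse / df_res else NA_real_,
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
    design = design, responses = responses
  ), class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  residual df = %d, R^2 = %.4f%s\n", x$df_residual,
              x$r_squared,
              if (length(x$dropped))
                paste0(", aliased: ", paste(x$dropped, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
predict.quadratic_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Upper-tail p-value for an ANOVA F statistic
#'
#' The tail mapping used in response-surface ANOVA tables:
#' `P(F_{df1, df2} > f)`.
#'
#' @param f F statistic(s).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Upper-tail p-value(s).
#' @export
pvalue_from_f <- function(f, df1, df2) {
  unname(stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Partial (extra) sum-of-squares ANOVA for a quadratic fit
#'
#' Each term's SS is the increase in residual SS when that term alone is
#' removed from the full model (partial, Type-III-style SS, the convention
#' of DOE software ANOVA tables — per-term SS need not sum to the model
#' SS). The model row tests all terms jointly:
#' `SS_model = SS_total - SS_residual` on the model df. F statistics use
#' the full-model residual mean square; aliased terms appear with SS 0,
#' df 0 and blank F/p.
#'
#' @param fit a [fit_quadratic()] result with at least 1 residual df.
#' @return A data frame of class `rsm_anova` with columns `source`, `ss`,
#'   `df`, `ms`, `f`, `p`; rows: Model, each term, aliased terms, Residual,
#'   Cor Total.
#' @export
anova_partial <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  if (fit$df_residual < 1L)
    stop("residual df = 0: the model interpolates the runs and ANOVA is ",
         "undefined (add centre replicates or drop terms)", call. = FALSE)
  y <- fit$responses
  coded <- fit$design$coded
  sse_full <- sum(fit$residuals^2)
  mse <- fit$sigma2
  sst <- sum((y - mean(y))^2)
  term_ss <- vapply(fit$terms, function(tm) {
    Xr <- build_model_matrix(coded, setdiff(fit$terms, tm))
    sum(stats::lm.fit(Xr, y)$residuals^2) - sse_full
  }, numeric(1))
  df_model <- length(fit$terms)
  ss_model <- sst - sse_full
  rows <- data.frame(
    source = c("Model", fit$terms, fit$dropped, "Residual", "Cor Total"),
    ss = c(ss_model, unname(term_ss), rep(0, length(fit$dropped)),
           sse_full, sst),
    df = c(df_model, rep(1L, length(fit$terms)),
           rep(0L, length(fit$dropped)), fit$df_residual,
           length(y) - 1L),
    stringsAsFactors = FALSE)
  rows$ms <- ifelse(rows$df > 0, rows$ss / rows$df, NA_real_)
  testable <- rows$source != "Cor Total" & rows$source != "Residual" &
    rows$df > 0
  rows$f <- ifelse(testable, rows$ms / mse, NA_real_)
  rows$p <- ifelse(testable,
                   pvalue_from_f(rows$f, rows$df, fit$df_residual),
                   NA_real_)
  class(rows) <- c("rsm_anova", "data.frame")
  rows
}

#' @export
print.rsm_anova <- function(x, ...) {
  out <- as.data.frame(x)
  out$ss <- signif(out$ss, 4); out$ms <- signif(out$ms, 4)
  out$f <- signif(out$f, 5); out$p <- signif(out$p, 4)
  print(out, row.names = FALSE, na.print = "")
  invisible(x)
}

#' Maximise a quadratic model over the coded box
#'
#' Exact maximisation of the fitted surface over the cube
#' `[-1, 1]^k` by face enumeration: every face of the cube fixes a subset
#' of coordinates at +-1; on each face the stationary point of the
#' restricted quadratic is solved in closed form and kept if feasible, and
#' all vertices are always candidates. Deterministic, with no iterative
#' tolerance; faces whose restricted quadratic is singular (e.g. a factor
#' that enters only linearly) contribute through their boundary
#' sub-faces. Coordinates on the boundary are flagged — a factor whose
#' optimum sits at +-1 may pay off beyond the explored range.
#'
#' @param model a [quadratic_model()] or [fit_quadratic()] result.
#' @param lower,upper box bounds per factor (recycled; default -1, +1).
#' @return An object of class `box_optimum`: list with `coded` (named
#'   vector), `natural` (decoded levels when the model carries a coding,
#'   else `NULL`), `predicted`, and `at_boundary` (named logical).
#' @examples
#' m <- quadratic_model(0, c(B = 0), quadratic = c(B = -1))
#' optimize_box(m)  # maximum of -B^2 at B = 0
#' @export
optimize_box <- function(model, lower = -1, upper = 1) {
  if (inherits(model, "quadratic_fit")) model <- model$model
  stopifnot(inherits(model, "quadratic_model"))
  qb <- model_qb(model)
  k <- length(qb$b)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  stopifnot(all(lower < upper))
  # each coordinate: 1 = at lower, 2 = at upper, 3 = free
  states <- as.matrix(expand.grid(rep(list(1:3), k)))
  best_x <- NULL
  best_y <- -Inf
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    free <- which(st == 3L)
    x <- ifelse(st == 1L, lower, upper)
    if (length(free)) {
      fixed <- setdiff(seq_len(k), free)
      A <- 2 * qb$Q[free, free, drop = FALSE]
      rhs <- -(qb$b[free] +
                 if (length(fixed))
                   2 * drop(qb$Q[free, fixed, drop = FALSE] %*% x[fixed])
                 else 0)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next  # singular face: its boundary is covered
      if (any(sol < lower[free] - 1e-9) || any(sol > upper[free] + 1e-9))
        next
      x[free] <- pmin(pmax(sol, lower[free]), upper[free])
    }
    y <- predict(model, x)
    if (y > best_y) { best_y <- y; best_x <- x }
  }
  names(best_x) <- qb$fnames
  at_bound <- best_x <= lower + 1e-9 | best_x >= upper - 1e-9
  names(at_bound) <- qb$fnames
  natural <- if (!is.null(model$factors))
    drop(decode_levels(model$factors, best_x)) else NULL
  structure(list(coded = best_x, natural = natural, predicted = best_y,
                 at_boundary = at_bound),
            class = "box_optimum")
}

#' @export
print.box_optimum <- function(x, ...) {
  cat("<box_optimum>\n  coded:  ",
      paste(sprintf("%s = %.4g%s", names(x$coded), x$coded,
                    ifelse(x$at_boundary, "*", "")), collapse = ", "),
      "\n")
  if (!is.null(x$natural))
    cat("  natural:", paste(sprintf("%s = %.6g", names(x$natural),
                                    x$natural), collapse = ", "), "\n")
  cat(sprintf("  predicted response: %.6g\n", x$predicted))
  if (any(x$at_boundary))
    cat("  (* at box boundary: the optimum may lie beyond the design range)\n")
  invisible(x)
}
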