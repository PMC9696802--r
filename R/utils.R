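# internal input checks -------------------------------------------------

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stop("`", name, "` = ", x, " is outside the admissible range ",
         if (strict_min) "(" else "[", min, ", ", max,
         if (strict_max) ")" else "]", call. = FALSE)
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min)
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
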