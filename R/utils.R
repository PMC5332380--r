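#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor p.adjust phyper pt rlnorm rnbinom rnorm runif
#' @importFrom utils head modifyList read.delim write.table
NULL

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("configuration error: `%s` must be a single finite number", name),
         call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("configuration error: `%s` = %s is outside its valid range",
                 name, format(x)), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("configuration error: `%s` must be an integer", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Render a Monte Carlo p-value for display
#'
#' A nominal p of exactly zero from `B` simulations is reported as
#' `"<1/B"` (e.g. `"<0.0001"` at B = 10,000) because zero only means the
#' observed statistic exceeded every simulated one.
#'
#' @param p Numeric vector of nominal p-values.
#' @param B Number of Monte Carlo simulations behind each p-value.
#' @return Character vector.
#' @export
format_nominal_p <- function(p, B) {
  out <- format(p, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  zero <- !is.na(p) & p == 0
  out[zero] <- paste0("<", format(1 / B, scientific = FALSE, trim = TRUE))
  out
}
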