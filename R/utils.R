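# Shared helpers: rounding and validation used across the model.

#' Fracture type categories
#'
#' The model distinguishes three fracture categories: hip, vertebral and
#' non-hip non-vertebral (`nhnv`). Every per-type quantity in the package
#' (distribution shares, relative risks, unit costs, risks, counts) is total
#' over these three, in this order.
#'
#' @return Character vector `c("hip", "vertebral", "nhnv")`.
#' @export
#' @examples
#' fracture_types()
fracture_types <- function() {
  c("hip", "vertebral", "nhnv")
}

#' Round half away from zero
#'
#' Commercial rounding used at all reporting boundaries (counts, per-100k
#' rates). Base `round()` rounds half to even, which would not reproduce
#' published tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Internal validators ---------------------------------------------------------

check_fraction <- function(x, name, where = NULL) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    loc <- if (is.null(where)) "" else paste0(" (", where[bad][1], ")")
    stop(sprintf("`%s` must be a fraction in [0, 1]%s; got %s",
                 name, loc, format(x[bad][1])), call. = FALSE)
  }
  invisible(x)
}

check_rr <- function(x, name, where = NULL) {
  bad <- !is.finite(x) | x <= 0 | x > 1
  if (any(bad)) {
    loc <- if (is.null(where)) "" else paste0(" (", where[bad][1], ")")
    stop(sprintf("`%s` must be a relative risk in (0, 1]%s; got %s",
                 name, loc, format(x[bad][1])), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name, where = NULL) {
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    loc <- if (is.null(where)) "" else paste0(" (", where[bad][1], ")")
    stop(sprintf("`%s` must be non-negative%s", name, loc), call. = FALSE)
  }
  invisible(x)
}
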