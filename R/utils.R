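#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (the convention used
#' for reporting clinical summary statistics), unlike [round()] which rounds
#' half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.5)      # 1
#' round_half_up(26.5625, 1)  # 26.6
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared argument checks
check_scalar_num <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (x < lower || (!allow_zero && x == lower))
    stop(sprintf("'%s' must be %s %g", name,
                 if (allow_zero) ">=" else ">", lower), call. = FALSE)
  invisible(as.numeric(x))
}

as_spacing3 <- function(x, name = "spacing") {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L || anyNA(x) || any(x <= 0))
    stop(sprintf("'%s' must be one or three positive numbers (mm)", name),
         call. = FALSE)
  x
}
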