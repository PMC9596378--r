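#' Censored assay quantities
#'
#' Many panel measurements are reported only as a bound (for example an IC50
#' of "> 100" µM when the top dose did not reach 50% inhibition). A
#' `censored_qty` carries the numeric bound together with its direction so
#' that downstream arithmetic (fold-selectivity ratios, CRC ratios) always
#' propagates a correctly directed bound instead of a bare number.
#'
#' @param value numeric value or bound (in the caller's units).
#' @param censor one of `"none"` (an ordinary number), `">"` (true value
#'   exceeds `value`), `"<"` (true value is below `value`), or
#'   `"indeterminate"` (no usable bound; `value` is `NA`).
#' @return an object of class `censored_qty`.
#' @examples
#' censored_qty(21)
#' censored_qty(100, ">")
#' @export
censored_qty <- function(value, censor = c("none", ">", "<", "indeterminate")) {
  censor <- match.arg(censor)
  if (censor == "indeterminate") value <- NA_real_
  else {
    if (!is.numeric(value) || length(value) != 1L || is.na(value))
      stop("`value` must be a single number", call. = FALSE)
    value <- as.numeric(value)
  }
  structure(list(value = value, censor = censor), class = "censored_qty")
}

#' @export
print.censored_qty <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.censored_qty <- function(x, digits = NULL, ...) {
  if (x$censor == "indeterminate") return("indeterminate")
  v <- if (is.null(digits)) x$value else signif(x$value, digits)
  v <- format(v, big.mark = ",", scientific = FALSE, trim = TRUE)
  if (x$censor == "none") v else paste0(x$censor, " ", v)
}

#' Test whether a quantity is censored
#' @param x a `censored_qty` (bare numbers count as uncensored).
#' @return logical.
#' @export
is_censored <- function(x) {
  if (!inherits(x, "censored_qty")) return(FALSE)
  x$censor != "none"
}

as_censored_qty <- function(x) {
  if (inherits(x, "censored_qty")) return(x)
  censored_qty(x, "none")
}

#' Ratio of two possibly-censored quantities
#'
#' Computes `num / den` with bound propagation: a lower-bounded (`">"`)
#' numerator or upper-bounded (`"<"`) denominator yields a lower-bounded
#' ratio and vice versa. When both operands are censored no direction can be
#' asserted and the result is `"indeterminate"`.
#'
#' @param num,den `censored_qty` objects or bare positive numbers.
#' @return a `censored_qty`.
#' @export
censored_ratio <- function(num, den) {
  num <- as_censored_qty(num)
  den <- as_censored_qty(den)
  if (num$censor == "indeterminate" || den$censor == "indeterminate")
    return(censored_qty(NA, "indeterminate"))
  if (num$censor != "none" && den$censor != "none")
    return(censored_qty(NA, "indeterminate"))
  if (!is.na(den$value) && den$value <= 0)
    stop("denominator bound must be positive", call. = FALSE)
  ratio <- num$value / den$value
  censor <- if (num$censor == ">" || den$censor == "<") ">"
  else if (num$censor == "<" || den$censor == ">") "<"
  else "none"
  censored_qty(ratio, censor)
}

#' Round a fold value the way panel papers report it
#'
#' Fold claims are conventionally quoted to one or two significant figures
#' (a 2 / 0.013 µM shift is "150-fold" at two figures). Censoring is
#' preserved: rounding a `"> 10,400"` bound gives `"> 10,000"`.
#'
#' @param x a `censored_qty` or number.
#' @param sig significant figures (default 2).
#' @return a `censored_qty` with the rounded value.
#' @export
round_fold <- function(x, sig = 2) {
  x <- as_censored_qty(x)
  if (x$censor == "indeterminate") return(x)
  censored_qty(signif(x$value, sig), x$censor)
}
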