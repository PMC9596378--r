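# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so generators are pure functions of (config, seed) without side
#' effects on the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# centred moving average with partial windows at the edges; w odd
moving_average <- function(x, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  if (w == 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop(sprintf("`%s` must be a single %s number", name,
                        if (strict) "positive" else "non-negative"),
                call. = FALSE)
  invisible(x)
}

# Levenberg-Marquardt least squares on a residual function. Returns NULL on
# hard failure; otherwise the solution with a convergence flag (nls.lm info
# codes 1-3; 4 is accepted because bound-constrained optima can report it).
# The residual interface (rather than a model formula) keeps zero-residual
# noiseless fits well-defined.
nls_lm_fit <- function(par, resid_fn, lower = NULL, upper = NULL,
                       maxiter = 500) {
  if (is.null(lower)) lower <- rep(-Inf, length(par))
  if (is.null(upper)) upper <- rep(Inf, length(par))
  res <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = resid_fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(res)) return(NULL)
  list(par = res$par, info = res$info, deviance = res$deviance,
       ok = res$info %in% 1:4 && all(is.finite(res$par)))
}

# coefficient of determination against a fitted vector
r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}
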