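#' Morrison tight-binding bound-enzyme concentration
#'
#' Exact equilibrium concentration of the enzyme-inhibitor complex when
#' inhibitor is not in large excess over enzyme (the tight-binding regime,
#' relevant here because the isomerase is assayed at 5 nM while inhibition
#' constants reach low-nM):
#' `EI = ((E + I + Ki) - sqrt((E + I + Ki)^2 - 4 E I)) / 2`.
#' All three arguments must share one concentration unit.
#'
#' @param E_total total enzyme concentration.
#' @param I_total total inhibitor concentration.
#' @param Ki_app apparent inhibition constant (>= 0).
#' @return bound complex concentration, same unit as the inputs.
#' @examples
#' morrison_bound(5, 5, 0)    # stoichiometric limit: all enzyme bound
#' @export
morrison_bound <- function(E_total, I_total, Ki_app) {
  stopifnot(all(E_total >= 0), all(I_total >= 0), all(Ki_app >= 0))
  s <- E_total + I_total + Ki_app
  disc <- s^2 - 4 * E_total * I_total
  if (any(disc < -1e-9 * pmax(s^2, 1)))
    stop("negative discriminant in Morrison quadratic", call. = FALSE)
  (s - sqrt(pmax(disc, 0))) / 2
}

#' Truncate a kinetic trace at its (smoothed) maximum
#'
#' The coupled-assay fluorescence plateaus once the substrate's cis pool is
#' exhausted and then declines through photobleaching; analysis is halted at
#' the calculated maximum. The trace is smoothed with a centred
#' moving average of width `window` and cut at the LAST index attaining the
#' smoothed maximum, so constant or monotonically rising traces are returned
#' unchanged.
#'
#' @param times,fluorescence numeric vectors (strictly increasing times).
#' @param window odd moving-average width (default 5).
#' @param min_points minimum points required after truncation (default 10);
#'   shorter results are flagged for downstream exclusion.
#' @return list: `times`, `fluorescence` (truncated), `index` (truncation
#'   index in the input), `excluded` (too few points remain).
#' @export
truncate_at_max <- function(times, fluorescence, window = 5, min_points = 10) {
  stopifnot(length(times) == length(fluorescence), length(times) >= 2,
            all(diff(times) > 0), window >= 1, window %% 2 == 1)
  sm <- moving_average(fluorescence, window)
  idx <- max(which(sm == max(sm)))
  list(times = times[seq_len(idx)], fluorescence = fluorescence[seq_len(idx)],
       index = idx, excluded = idx < min_points)
}

#' Fit a one-phase association curve
#'
#' Least-squares fit of `F(t) = F0 + (F_plateau - F0) (1 - exp(-k t))` with
#' `k > 0`, via Levenberg-Marquardt. Initialization: `F0` = first point,
#' `F_plateau` = maximum, `k` from the half-rise time.
#'
#' @param times,fluorescence the (truncated) trace.
#' @return object of class `rate_fit`: list with `k`, `f0`, `f_plateau`,
#'   `r_squared`, `converged`, `message`.
#' @export
fit_one_phase <- function(times, fluorescence) {
  stopifnot(length(times) == length(fluorescence), length(times) >= 4)
  f0_init <- fluorescence[1L]
  fp_init <- max(fluorescence)
  amp <- fp_init - f0_init
  fail <- function(msg) structure(
    list(k = NA_real_, f0 = NA_real_, f_plateau = NA_real_,
         r_squared = NA_real_, converged = FALSE, message = msg),
    class = "rate_fit")
  if (amp <= 0 || stats::sd(fluorescence) == 0)
    return(fail("flat trace: no association amplitude"))
  half <- f0_init + amp / 2
  t_half <- times[which(fluorescence >= half)[1L]]
  if (is.na(t_half) || t_half <= 0) t_half <- stats::median(times)
  k_init <- log(2) / t_half
  model <- function(p) p[1] + (p[2] - p[1]) * (1 - exp(-p[3] * times))
  fit <- nls_lm_fit(c(f0_init, fp_init, k_init),
                    function(p) fluorescence - model(p),
                    lower = c(-Inf, -Inf, 1e-9))
  if (is.null(fit) || !fit$ok)
    return(fail("one-phase fit did not converge"))
  if (fit$par[3] <= 2e-9)
    return(fail("rate constant at lower bound"))
  structure(list(k = fit$par[3], f0 = fit$par[1], f_plateau = fit$par[2],
                 r_squared = r_squared(fluorescence, model(fit$par)),
                 converged = TRUE, message = "ok"),
            class = "rate_fit")
}

#' Truncate and fit every well of a kinetic plate
#'
#' @param plate tidy data.frame with columns `well`, `role`, `compound`,
#'   `dose_uM`, `time_s`, `fluorescence_au` (the layout written by
#'   [simulate_ppiase_plate()]).
#' @param window moving-average width for [truncate_at_max()].
#' @return data.frame with one row per well: identifiers plus `k`,
#'   `truncation_index`, `r_squared`, `converged`, `excluded`, `message`.
#' @export
fit_plate <- function(plate, window = 5) {
  need <- c("well", "role", "time_s", "fluorescence_au")
  if (!all(need %in% names(plate)))
    stop("plate must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  wells <- split(plate, plate$well)
  rows <- lapply(wells, function(w) {
    w <- w[order(w$time_s), ]
    tr <- truncate_at_max(w$time_s, w$fluorescence_au, window = window)
    if (tr$excluded) {
      fit <- list(k = NA_real_, r_squared = NA_real_, converged = FALSE,
                  message = "too few points after truncation")
    } else fit <- fit_one_phase(tr$times, tr$fluorescence)
    data.frame(well = w$well[1L], role = w$role[1L],
               compound = if ("compound" %in% names(w)) w$compound[1L] else NA,
               dose_uM = if ("dose_uM" %in% names(w)) w$dose_uM[1L] else NA,
               k = fit$k, truncation_index = tr$index,
               r_squared = fit$r_squared,
               converged = fit$converged, excluded = tr$excluded,
               message = fit$message, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$well), ]
}

#' Normalize well rates to plate controls
#'
#' Converts fitted rate constants to percent activity anchored on the plate
#' controls: `activity = 100 (k - mean k_substrate_only) /
#' (mean k_enzyme_control - mean k_substrate_only)`; inhibition is
#' `100 - activity`. Values are deliberately not clamped to `[0, 100]`.
#'
#' @param rates output of [fit_plate()] (or any data.frame with `role`, `k`,
#'   `converged`).
#' @param min_dynamic_range plate fails when the control means are separated
#'   by fewer than this many pooled control standard deviations (default 3;
#'   skipped when the controls are singletons and no SD exists).
#' @return the test-well rows with `activity_pct` and `inhibition_pct`
#'   columns; control means are attached as attribute `"controls"`.
#' @export
normalize_rates <- function(rates, min_dynamic_range = 3) {
  ok <- rates$converged & !is.na(rates$k)
  s <- rates$k[ok & rates$role == "substrate_only"]
  e <- rates$k[ok & rates$role == "enzyme_control"]
  if (!length(s) || !length(e))
    stop("need at least one valid well of each control role", call. = FALSE)
  pooled_sd <- if (length(s) > 1L || length(e) > 1L)
    sqrt((sum((s - mean(s))^2) + sum((e - mean(e))^2)) /
           max(length(s) + length(e) - 2L, 1L))
  else NA_real_
  sep <- mean(e) - mean(s)
  if (sep <= 0 || (!is.na(pooled_sd) && pooled_sd > 0 &&
                   sep < min_dynamic_range * pooled_sd))
    stop(sprintf(
      "plate failed dynamic-range check: control separation %.3g vs %g x pooled SD %.3g",
      sep, min_dynamic_range, pooled_sd), call. = FALSE)
  test <- rates[ok & rates$role == "test", , drop = FALSE]
  test$activity_pct <- 100 * (test$k - mean(s)) / sep
  test$inhibition_pct <- 100 - test$activity_pct
  attr(test, "controls") <- list(k_substrate_only = mean(s),
                                 k_enzyme_control = mean(e),
                                 pooled_sd = pooled_sd)
  rownames(test) <- NULL
  test
}

#' Fit a dose-response curve and extract the absolute IC50
#'
#' Fits the four-parameter logistic
#' `I(c) = Bottom + (Top - Bottom) / (1 + 10^(h (log10 m - log10 c)))`
#' to percent inhibition versus dose, with bounds Bottom in `[-10, 40]`,
#' Top in `[60, 110]` and Hill slope `h` in `[0.3, 5]` to prevent asymptote
#' degeneracy on sparse dose ranges. The reported IC50 is the absolute one
#' -- the dose at which the fitted curve crosses 50% inhibition, found by
#' root solving -- which differs from the curve midpoint `m` whenever the
#' asymptotes are not 0 and 100. When the fitted curve does not cross 50%
#' at or below the top tested dose (searched over
#' `[min dose / 10, max dose x 10]`), the result is censored `"> max dose"`:
#' because Top is bounded away from 50 the fitted curve always crosses
#' somewhere, and a crossing beyond the tested range is an extrapolation,
#' not a measured potency.
#'
#' @param doses_uM doses (µM, > 0); repeated doses are fitted pooled.
#' @param inhibition_pct percent inhibition per dose entry.
#' @return object of class `dose_response_fit`: list with `ic50`
#'   (a [censored_qty()], µM), `midpoint_uM`, `params` (bottom, top, hill),
#'   `r_squared`, `converged`, `per_dose` (mean +/- SD per distinct dose)
#'   and `message`.
#' @export
fit_dose_response <- function(doses_uM, inhibition_pct) {
  stopifnot(length(doses_uM) == length(inhibition_pct))
  if (any(doses_uM <= 0) || anyNA(doses_uM))
    stop("doses must be positive", call. = FALSE)
  if (length(unique(doses_uM)) < 4L)
    stop("need at least 4 distinct doses", call. = FALSE)
  x <- log10(doses_uM)
  y <- inhibition_pct
  lo <- min(doses_uM) / 10
  hi <- max(doses_uM) * 10
  mid_init <- doses_uM[which.min(abs(y - 50))]
  # p = (bottom, top, h, logm)
  model <- function(p) p[1] + (p[2] - p[1]) / (1 + 10^(p[3] * (p[4] - x)))
  fit <- nls_lm_fit(c(0, 100, 1, log10(mid_init)),
                    function(p) y - model(p),
                    lower = c(-10, 60, 0.3, log10(lo)),
                    upper = c(40, 110, 5, log10(hi)))
  if (!is.null(fit) && !fit$ok) fit <- NULL
  agg <- stats::aggregate(y, by = list(dose_uM = doses_uM),
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  per_dose <- data.frame(dose_uM = agg$dose_uM,
                         mean_inhibition = agg$x[, "mean"],
                         sd_inhibition = agg$x[, "sd"])
  if (is.null(fit)) {
    return(structure(list(
      ic50 = censored_qty(max(doses_uM), ">"), midpoint_uM = NA_real_,
      params = NULL, r_squared = NA_real_, converged = FALSE,
      per_dose = per_dose,
      message = "4PL fit did not converge; IC50 censored"),
      class = "dose_response_fit"))
  }
  co <- list(bottom = fit$par[1], top = fit$par[2], h = fit$par[3],
             logm = fit$par[4])
  curve <- function(logc)
    co$bottom + (co$top - co$bottom) / (1 + 10^(co$h * (co$logm - logc)))
  g_lo <- curve(log10(lo)) - 50
  g_hi <- curve(log10(hi)) - 50
  if (g_lo * g_hi > 0) {
    ic50 <- if (g_hi < 0) censored_qty(max(doses_uM), ">")
            else censored_qty(min(doses_uM), "<")
  } else {
    root <- stats::uniroot(function(lc) curve(lc) - 50,
                           lower = log10(lo), upper = log10(hi),
                           tol = 1e-12)$root
    # a crossing beyond the top tested dose is an extrapolation of the
    # bounded asymptotes, not a measured potency: censor it
    ic50 <- if (10^root > max(doses_uM)) censored_qty(max(doses_uM), ">")
            else censored_qty(10^root, "none")
  }
  structure(list(ic50 = ic50, midpoint_uM = 10^co$logm,
                 params = list(bottom = co$bottom, top = co$top, hill = co$h),
                 r_squared = r_squared(y, model(fit$par)),
                 converged = TRUE, per_dose = per_dose, message = "ok"),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Dose-response fit\n")
  cat("  absolute IC50:", format(x$ic50, digits = 3), "uM\n")
  if (!is.null(x$params))
    cat(sprintf("  midpoint %.4g uM, Bottom %.1f, Top %.1f, Hill %.2f, R2 %.4f\n",
                x$midpoint_uM, x$params$bottom, x$params$top, x$params$hill,
                x$r_squared))
  invisible(x)
}

#' Full plate analysis: rates, normalization, dose-response per compound
#'
#' Convenience pipeline over [fit_plate()], [normalize_rates()] and
#' [fit_dose_response()].
#'
#' @param plate tidy kinetic plate data.frame (see [fit_plate()]).
#' @param window moving-average width for truncation.
#' @return list: `rates`, `activity`, and `dose_response` (named list of
#'   [fit_dose_response()] results per compound).
#' @export
analyze_ppiase_plate <- function(plate, window = 5) {
  rates <- fit_plate(plate, window = window)
  activity <- normalize_rates(rates)
  fits <- lapply(split(activity, activity$compound), function(a)
    fit_dose_response(a$dose_uM, a$inhibition_pct))
  list(rates = rates, activity = activity, dose_response = fits)
}
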