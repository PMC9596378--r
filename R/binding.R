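#' Fit a one-site total-binding saturation isotherm
#'
#' Fits `A(X) = background + Bmax X / (KD + X) + NS X` to a
#' fluorescence-anisotropy titration (protein concentration `X` against
#' observed anisotropy). The linear `NS` term absorbs nonspecific binding;
#' with `with_ns = FALSE` it is fixed at zero (the plain one-site model).
#'
#' @param conc_uM titrated protein concentrations (µM), spanning at least
#'   two decades over at least five points.
#' @param anisotropy observed anisotropy.
#' @param with_ns fit the nonspecific slope (default `FALSE`).
#' @return object of class `saturation_fit`: `kd_uM`, `bmax`, `ns`,
#'   `background`, `r_squared`, `converged`, `unsaturated` (warning flag set
#'   when the top concentration does not reach the fitted KD), `message`.
#' @export
fit_fp_saturation <- function(conc_uM, anisotropy, with_ns = FALSE) {
  stopifnot(length(conc_uM) == length(anisotropy))
  if (length(unique(conc_uM)) < 5L)
    stop("need at least 5 distinct concentrations", call. = FALSE)
  pos <- conc_uM[conc_uM > 0]
  if (max(pos) / min(pos) < 100)
    stop("titration must span at least 2 decades", call. = FALSE)
  fail <- function(msg) structure(
    list(kd_uM = NA_real_, bmax = NA_real_, ns = NA_real_,
         background = NA_real_, r_squared = NA_real_, converged = FALSE,
         unsaturated = NA, message = msg), class = "saturation_fit")
  amp <- max(anisotropy) - min(anisotropy)
  if (amp <= 0 || stats::sd(anisotropy) == 0)
    return(fail("no anisotropy change across the titration"))
  half <- min(anisotropy) + amp / 2
  kd_init <- conc_uM[which.min(abs(anisotropy - half))]
  if (kd_init <= 0) kd_init <- stats::median(pos)
  # p = (background, bmax, kd[, ns])
  model <- if (with_ns)
    function(p) p[1] + p[2] * conc_uM / (p[3] + conc_uM) + p[4] * conc_uM
  else
    function(p) p[1] + p[2] * conc_uM / (p[3] + conc_uM)
  start <- c(min(anisotropy), amp, kd_init, if (with_ns) 0)
  lower <- c(-Inf, 1e-12, 1e-9, if (with_ns) -Inf)
  fit <- nls_lm_fit(start, function(p) anisotropy - model(p), lower = lower)
  if (is.null(fit) || !fit$ok)
    return(fail("saturation fit did not converge"))
  kd <- fit$par[3]
  structure(list(kd_uM = kd, bmax = fit$par[2],
                 ns = if (with_ns) fit$par[4] else 0,
                 background = fit$par[1],
                 r_squared = r_squared(anisotropy, model(fit$par)),
                 converged = TRUE,
                 unsaturated = max(conc_uM) < kd,
                 message = if (max(conc_uM) < kd)
                   "unsaturated: top concentration below fitted KD" else "ok"),
            class = "saturation_fit")
}

#' Fit a one-site competitive binding curve and derive Ki
#'
#' Fits `Y(X) = Bottom + (Top - Bottom) / (1 + 10^(logIC50 - X))` in
#' `X = log10 [competitor]` to the normalized competition signal
#' (protein + probe = 0%, free probe = 100%), with unit Hill slope (the
#' one-site model) and asymptotes bounded in `[-10, 20]` / `[80, 110]`.
#' The inhibition constant follows from the hot-probe correction
#' `Ki = IC50 / (1 + L_hot / KD_hot)`, which assumes negligible probe
#' depletion; when `L_hot / KD_hot > 10` the closed form is refused and the
#' exact solver ([solve_ternary_equilibrium()]) should be used instead.
#'
#' @param conc_uM competitor concentrations (µM, > 0).
#' @param signal_pct normalized signal (percent).
#' @param probe_nM fluorescent probe concentration (nM).
#' @param kd_probe_nM probe dissociation constant for this protein (nM),
#'   imported from the probe's saturation fit.
#' @return object of class `competition_fit`: `ki_uM`, `ic50_uM`,
#'   `log_ic50`, `params` (bottom, top), `r_squared`, `converged`,
#'   `message`.
#' @export
fit_fp_competition <- function(conc_uM, signal_pct, probe_nM, kd_probe_nM) {
  stopifnot(length(conc_uM) == length(signal_pct))
  if (any(conc_uM <= 0)) stop("competitor doses must be positive", call. = FALSE)
  stop_if_not_scalar_pos(probe_nM, "probe_nM")
  stop_if_not_scalar_pos(kd_probe_nM, "kd_probe_nM")
  depletion_ratio <- probe_nM / kd_probe_nM
  if (depletion_ratio > 10)
    stop(paste("probe-depletion regime (L_hot/KD_hot > 10):",
               "the closed-form correction is invalid;",
               "use solve_ternary_equilibrium()"), call. = FALSE)
  x <- log10(conc_uM)
  y <- signal_pct
  mid_init <- x[which.min(abs(y - 50))]
  # p = (bottom, top, logic50)
  model <- function(p) p[1] + (p[2] - p[1]) / (1 + 10^(p[3] - x))
  fit <- nls_lm_fit(c(0, 100, mid_init), function(p) y - model(p),
                    lower = c(-10, 80, min(x) - 2),
                    upper = c(20, 110, max(x) + 2))
  if (is.null(fit) || !fit$ok)
    return(structure(list(ki_uM = NA_real_, ic50_uM = NA_real_,
                          log_ic50 = NA_real_, params = NULL,
                          r_squared = NA_real_, converged = FALSE,
                          message = "competition fit did not converge"),
                     class = "competition_fit"))
  ic50 <- 10^fit$par[3]
  ki <- ic50 / (1 + depletion_ratio)
  structure(list(ki_uM = ki, ic50_uM = ic50, log_ic50 = fit$par[3],
                 params = list(bottom = fit$par[1], top = fit$par[2]),
                 r_squared = r_squared(y, model(fit$par)),
                 converged = TRUE, message = "ok"),
            class = "competition_fit")
}

#' Exact ternary competitive-binding equilibrium
#'
#' Solves the coupled mass-action equilibria `P + L <-> PL` (probe, KD) and
#' `P + I <-> PI` (competitor, Ki) exactly by root-finding on free protein:
#' `P_free (1 + L/(KD + P_free) + I/(Ki + P_free)) = P_total` has a unique
#' root on `[0, P_total]` because the left side is strictly increasing. The
#' root is polished by Newton steps so all three mass balances hold to
#' relative 1e-9. This is the oracle against which the Cheng-Prusoff
#' shortcut of [fit_fp_competition()] is validated.
#'
#' @param P_total,L_total,I_total total protein, probe and competitor
#'   concentrations (same unit, µM recommended; >= 0).
#' @param KD_probe,Ki dissociation/inhibition constants (> 0, same unit).
#' @return list: free and bound species (`P_free`, `L_free`, `I_free`,
#'   `PL`, `PI`), `probe_bound_fraction`, `protein_free_fraction`,
#'   `inhibitor_bound_fraction`, and `residuals` (relative mass-balance
#'   errors for protein, probe, inhibitor).
#' @export
solve_ternary_equilibrium <- function(P_total, L_total, KD_probe, I_total, Ki) {
  for (nm in c("P_total", "L_total", "I_total"))
    stop_if_not_scalar_pos(get(nm), nm, strict = FALSE)
  stop_if_not_scalar_pos(KD_probe, "KD_probe")
  stop_if_not_scalar_pos(Ki, "Ki")
  g <- function(P) P * (1 + L_total / (KD_probe + P) + I_total / (Ki + P)) -
    P_total
  if (P_total == 0) {
    P <- 0
  } else {
    P <- stats::uniroot(g, lower = 0, upper = P_total,
                        tol = .Machine$double.eps^0.9 * max(P_total, 1))$root
    dg <- function(P) 1 + L_total * KD_probe / (KD_probe + P)^2 +
      I_total * Ki / (Ki + P)^2
    for (i in 1:3) P <- max(P - g(P) / dg(P), 0)
  }
  PL <- P * L_total / (KD_probe + P)
  PI <- P * I_total / (Ki + P)
  L_free <- L_total - PL
  I_free <- I_total - PI
  rel <- function(err, tot) if (tot > 0) abs(err) / tot else abs(err)
  residuals <- c(
    protein = rel(P + PL + PI - P_total, max(P_total, .Machine$double.xmin)),
    probe = rel(L_free + PL - L_total, max(L_total, .Machine$double.xmin)),
    inhibitor = rel(I_free + PI - I_total, max(I_total, .Machine$double.xmin)))
  # probe balance is exact by construction; protein balance reflects root
  # accuracy
  list(P_free = P, L_free = L_free, I_free = I_free, PL = PL, PI = PI,
       probe_bound_fraction = if (L_total > 0) PL / L_total else 0,
       protein_free_fraction = if (P_total > 0) P / P_total else 1,
       inhibitor_bound_fraction = if (I_total > 0) PI / I_total else 0,
       residuals = residuals)
}

#' Fit a one-site specific-binding SPR isotherm
#'
#' Fits `RU(C) = Bmax C / (KD + C)` to equilibrium surface-plasmon-resonance
#' response against analyte concentration. The KD estimate is invariant to
#' any multiplicative normalization of the response (for example to a
#' reference compound's maximal RU).
#'
#' @param conc_uM analyte concentrations (µM), at least 4 distinct.
#' @param response normalized response units.
#' @return object of class `spr_fit`: `kd_uM`, `bmax`, `r_squared`,
#'   `converged`, `message`.
#' @export
fit_spr <- function(conc_uM, response) {
  stopifnot(length(conc_uM) == length(response))
  if (length(unique(conc_uM)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  fail <- function(msg) structure(
    list(kd_uM = NA_real_, bmax = NA_real_, r_squared = NA_real_,
         converged = FALSE, message = msg), class = "spr_fit")
  if (stats::sd(response) == 0) return(fail("flat response"))
  half <- max(response) / 2
  kd_init <- conc_uM[which.min(abs(response - half))]
  if (kd_init <= 0) kd_init <- stats::median(conc_uM[conc_uM > 0])
  # p = (bmax, kd)
  model <- function(p) p[1] * conc_uM / (p[2] + conc_uM)
  fit <- nls_lm_fit(c(max(response), kd_init),
                    function(p) response - model(p),
                    lower = c(1e-12, 1e-9))
  if (is.null(fit) || !fit$ok) return(fail("SPR fit did not converge"))
  structure(list(kd_uM = fit$par[2], bmax = fit$par[1],
                 r_squared = r_squared(response, model(fit$par)),
                 converged = TRUE, message = "ok"),
            class = "spr_fit")
}
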