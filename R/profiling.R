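#' Build a selectivity matrix from long-format panel results
#'
#' @param data data.frame with columns `compound`, `variant` (cyclophilin
#'   wild-type or point mutant), `assay` (e.g. `"ppiase_ic50"`, `"fp_ki"`),
#'   `value_uM` (> 0) and optional `censor` (`""`/`"none"`, `">"`, `"<"`).
#' @return object of class `selectivity_matrix` (validated long-format
#'   data.frame).
#' @export
selectivity_matrix <- function(data) {
  need <- c("compound", "variant", "assay", "value_uM")
  if (!all(need %in% names(data)))
    stop("matrix needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(data$censor)) data$censor <- "none"
  data$censor[data$censor == "" | is.na(data$censor)] <- "none"
  if (!all(data$censor %in% c("none", ">", "<")))
    stop("censor must be '', 'none', '>' or '<'", call. = FALSE)
  if (any(!is.na(data$value_uM) & data$value_uM <= 0))
    stop("all numeric cells must be positive", call. = FALSE)
  if (anyDuplicated(data[c("compound", "variant", "assay")]))
    stop("duplicate compound x variant x assay cells", call. = FALSE)
  structure(as.data.frame(data), class = c("selectivity_matrix", "data.frame"))
}

matrix_cell <- function(matrix, compound, variant, assay = NULL) {
  rows <- matrix$compound == compound & matrix$variant == variant
  if (!is.null(assay)) rows <- rows & matrix$assay == assay
  hit <- which(rows)
  if (!length(hit))
    stop(sprintf("no cell for compound '%s' x variant '%s'", compound,
                 variant), call. = FALSE)
  if (length(hit) > 1L)
    stop(sprintf("compound '%s' x variant '%s' is ambiguous across assays; pass `assay`",
                 compound, variant), call. = FALSE)
  list(value = censored_qty(matrix$value_uM[hit], matrix$censor[hit]),
       assay = matrix$assay[hit])
}

#' Fold selectivity of a compound between two enzyme variants
#'
#' `fold = potency(off_target) / potency(target)` from same-assay IC50 or
#' Ki cells; a compound tested against its own reference gives 1. Censored
#' cells propagate as directed bounds: an off-target `> 100` µM against a
#' 0.010 µM target reports `> 10,000`. Cross-assay folds (an IC50 against a
#' Ki) are refused.
#'
#' @param matrix a [selectivity_matrix()].
#' @param compound compound id.
#' @param target,off_target variant names.
#' @param assay optional assay name when a compound was measured in more
#'   than one assay family.
#' @return a [censored_qty()] fold value.
#' @examples
#' m <- selectivity_matrix(data.frame(
#'   compound = "B52", variant = c("CypD", "CypB"), assay = "ppiase_ic50",
#'   value_uM = c(0.010, 0.21)))
#' fold_selectivity(m, "B52", "CypD", "CypB")   # 21
#' @export
fold_selectivity <- function(matrix, compound, target, off_target,
                             assay = NULL) {
  t_cell <- matrix_cell(matrix, compound, target, assay)
  o_cell <- matrix_cell(matrix, compound, off_target, assay)
  if (t_cell$assay != o_cell$assay)
    stop(sprintf("refusing cross-assay fold: '%s' vs '%s'", t_cell$assay,
                 o_cell$assay), call. = FALSE)
  censored_ratio(o_cell$value, t_cell$value)
}

#' Potency shift of a compound between two variants (mutant rescue)
#'
#' Ratio of the two cells' IC50/Ki values, `variant_a / variant_b`; use the
#' less potent (higher-IC50) variant as `variant_a` to express the shift as
#' a fold improvement. Censored cells propagate as bounds.
#'
#' @inheritParams fold_selectivity
#' @param variant_a,variant_b variant names (numerator / denominator).
#' @return a [censored_qty()] fold shift.
#' @examples
#' m <- selectivity_matrix(data.frame(
#'   compound = "B32", variant = c("CypD", "CypD K118E/R124A"),
#'   assay = "ppiase_ic50", value_uM = c(6, 0.06)))
#' mutant_shift(m, "B32", "CypD", "CypD K118E/R124A")   # 100
#' @export
mutant_shift <- function(matrix, compound, variant_a, variant_b,
                         assay = NULL) {
  a <- matrix_cell(matrix, compound, variant_a, assay)
  b <- matrix_cell(matrix, compound, variant_b, assay)
  if (a$assay != b$assay)
    stop(sprintf("refusing cross-assay shift: '%s' vs '%s'", a$assay,
                 b$assay), call. = FALSE)
  censored_ratio(a$value, b$value)
}

#' Count resorbed calcium pulses in a CRC trace
#'
#' A pulse counts as taken up when, within `window` seconds of its
#' injection, the trace returns below
#' `baseline + return_fraction * (peak - baseline)`, where baseline is the
#' trace value just before the injection and peak the maximum shortly after
#' it. The first pulse failing the criterion (or a terminal sustained rise)
#' marks permeability-transition release; the retention capacity is the
#' number of pulses taken up before it. Traces in which every pulse is
#' resorbed are flagged `released = FALSE` and the count is a lower bound.
#'
#' @param trace data.frame with `time_s` and `value`.
#' @param schedule data.frame with injection `time_s` (one row per pulse).
#' @param return_fraction uptake criterion `f` (default 0.3).
#' @param window seconds allowed for return; default 0.8 x the median
#'   inter-injection interval (or the full remaining trace for a single
#'   injection).
#' @return object of class `crc_result`: `pulses` (count), `released`
#'   (logical), `per_pulse` (diagnostic table).
#' @export
count_crc_pulses <- function(trace, schedule, return_fraction = 0.3,
                             window = NULL) {
  stopifnot(all(c("time_s", "value") %in% names(trace)),
            "time_s" %in% names(schedule))
  inj <- sort(schedule$time_s)
  if (any(inj < min(trace$time_s)) || any(inj > max(trace$time_s)))
    stop("injection times must lie within the trace span", call. = FALSE)
  if (is.null(window)) {
    window <- if (length(inj) > 1L) 0.8 * stats::median(diff(inj))
              else max(trace$time_s) - inj
  }
  tt <- trace$time_s
  vv <- trace$value
  n <- length(inj)
  taken <- logical(n)
  base <- peak <- thresh <- numeric(n)
  for (i in seq_len(n)) {
    pre <- which(tt < inj[i])
    base[i] <- if (length(pre)) vv[max(pre)] else vv[1L]
    in_win <- which(tt >= inj[i] & tt <= inj[i] + window)
    if (!length(in_win)) { taken[i] <- FALSE; next }
    peak_at <- in_win[which.max(vv[in_win])]
    peak[i] <- vv[peak_at]
    thresh[i] <- base[i] + return_fraction * (peak[i] - base[i])
    # the trace must RETURN below threshold after the peak; the jump itself
    # does not count
    after_peak <- in_win[in_win >= peak_at]
    taken[i] <- min(vv[after_peak]) <= thresh[i] && peak[i] > base[i]
  }
  release_at <- which(!taken)
  if (length(release_at)) {
    pulses <- release_at[1L] - 1L
    released <- TRUE
  } else {
    pulses <- n
    released <- FALSE
  }
  structure(list(pulses = as.integer(pulses), released = released,
                 per_pulse = data.frame(pulse = seq_len(n), time_s = inj,
                                        baseline = base, peak = peak,
                                        threshold = thresh, taken_up = taken)),
            class = "crc_result")
}

#' @export
print.crc_result <- function(x, ...) {
  cat(sprintf("CRC: %d pulse(s) taken up%s\n", x$pulses,
              if (x$released) " before release"
              else " (no release detected; count is a lower bound)"))
  invisible(x)
}

#' Calcium-retention-capacity ratio versus control
#'
#' `ratio = treated pulses / control pulses` (the vehicle-control
#' normalization of CRC assays). A treated trace with no detected release
#' yields a lower-bound ratio.
#'
#' @param treated,control `crc_result` objects (or bare counts).
#' @return a [censored_qty()] ratio.
#' @export
crc_ratio <- function(treated, control) {
  as_count <- function(x) {
    if (inherits(x, "crc_result")) list(n = x$pulses, open = !x$released)
    else list(n = as.numeric(x), open = FALSE)
  }
  tr <- as_count(treated)
  co <- as_count(control)
  if (co$n <= 0) stop("control pulse count must be positive", call. = FALSE)
  num <- censored_qty(tr$n, if (tr$open) ">" else "none")
  den <- censored_qty(co$n, if (co$open) ">" else "none")
  censored_ratio(num, den)
}

#' Ester prodrug species fractions from total-ion counts
#'
#' Expresses the diester, monoester and diacid total-ion counts of a
#' cell-lysate LC-MS measurement each as a fraction of their sum.
#'
#' @param tic numeric vector of total-ion counts (>= 0, sum > 0); names are
#'   preserved, defaulting to diester/monoester/diacid for length 3.
#' @return numeric vector of fractions summing to 1.
#' @examples
#' species_fractions(c(1000, 500, 500))
#' @export
species_fractions <- function(tic) {
  if (!is.numeric(tic) || any(is.na(tic)) || any(tic < 0))
    stop("`tic` must be non-negative counts", call. = FALSE)
  total <- sum(tic)
  if (total <= 0) stop("total ion count must be positive", call. = FALSE)
  out <- tic / total
  if (is.null(names(out)) && length(out) == 3L)
    names(out) <- c("diester", "monoester", "diacid")
  out
}

#' Assemble a machine-readable campaign report
#'
#' Collects the outputs of the pipeline stages into one deterministic
#' structure: enrichment hit table, dose-response IC50 table (censoring
#' flags preserved), selectivity long table, and CRC table. Re-running on
#' identical inputs yields an identical report.
#'
#' @param enrichment optional `enrichment_table` (top rows become the hit
#'   table).
#' @param dose_response optional named list of [fit_dose_response()] results
#'   (names = compound, or `compound|variant`).
#' @param binding optional named list of binding fits (`saturation_fit`,
#'   `competition_fit` or `spr_fit`).
#' @param matrix optional [selectivity_matrix()].
#' @param crc optional named list of `crc_result` objects.
#' @param n_hits number of enrichment rows to keep (default 50).
#' @return list of class `campaign_report` with data.frame sections
#'   `hits`, `ic50`, `binding`, `selectivity`, `crc`.
#' @export
build_report <- function(enrichment = NULL, dose_response = NULL,
                         binding = NULL, matrix = NULL, crc = NULL,
                         n_hits = 50) {
  hits <- if (!is.null(enrichment))
    utils::head(as.data.frame(enrichment), n_hits)
  else data.frame()
  ic50 <- if (!is.null(dose_response)) {
    stopifnot(!is.null(names(dose_response)))
    rows <- lapply(sort(names(dose_response)), function(nm) {
      f <- dose_response[[nm]]
      data.frame(id = nm, ic50_uM = f$ic50$value, censor = f$ic50$censor,
                 midpoint_uM = f$midpoint_uM %||% NA_real_,
                 r_squared = f$r_squared, converged = f$converged,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else data.frame()
  bind <- if (!is.null(binding)) {
    stopifnot(!is.null(names(binding)))
    rows <- lapply(sort(names(binding)), function(nm) {
      f <- binding[[nm]]
      data.frame(id = nm,
                 model = class(f)[1L],
                 kd_uM = f$kd_uM %||% NA_real_,
                 ki_uM = f$ki_uM %||% NA_real_,
                 r_squared = f$r_squared, converged = f$converged,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else data.frame()
  sel <- if (!is.null(matrix)) {
    m <- as.data.frame(matrix)
    m[order(m$compound, m$variant, m$assay), , drop = FALSE]
  } else data.frame()
  crc_tab <- if (!is.null(crc)) {
    stopifnot(!is.null(names(crc)))
    rows <- lapply(sort(names(crc)), function(nm)
      data.frame(condition = nm, pulses = crc[[nm]]$pulses,
                 released = crc[[nm]]$released, stringsAsFactors = FALSE))
    do.call(rbind, rows)
  } else data.frame()
  rownames(sel) <- NULL
  structure(list(hits = hits, ic50 = ic50, binding = bind,
                 selectivity = sel, crc = crc_tab),
            class = "campaign_report")
}

#' Write a campaign report to disk
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if missing). Writes `report.json`
#'   plus one CSV per non-empty section.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "campaign_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  for (nm in names(report)) {
    if (nrow(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(dir)
}
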