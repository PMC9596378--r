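#' Design a DNA-encoded macrocycle library
#'
#' Builds the codon tables and constant regions of an encoded combinatorial
#' library: one building-block table per macrocycle position, each block
#' identified by a short label and a fixed-length DNA codon. Codons within a
#' position are generated greedily from a seeded shuffle of the full
#' enumeration and kept only if they are at Hamming distance >= 3 from every
#' codon already accepted at that position, so a single sequencing
#' substitution can always be corrected during decoding.
#'
#' The default factorization, 20 x 20 x 20 x 32, yields the 256,000-member
#' four-position library used throughout the package's worked examples.
#'
#' @param sizes integer vector of building-block counts per position.
#' @param codon_length codon length in nucleotides; must be at least
#'   `ceil(log4(max(sizes))) + 2` so a distance-3 code of the requested size
#'   is plausible.
#' @param min_distance minimum pairwise Hamming distance within a position
#'   (default 3, required for 1-substitution correction).
#' @param seed integer seed; the design is a pure function of its arguments.
#' @return an object of class `library_design` with fields `sizes`,
#'   `codon_length`, `positions` (list of `labels` + `codons` per position),
#'   `constant` (`five_prime`, `spacers`, `three_prime`) and `total_members`.
#' @examples
#' d <- design_library(sizes = c(2, 2, 2, 2), codon_length = 6, seed = 1)
#' d$total_members
#' @export
design_library <- function(sizes = c(20, 20, 20, 32), codon_length = 8,
                           min_distance = 3, seed = 1) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || any(is.na(sizes)) || any(sizes < 1L))
    stop("`sizes` must be positive integers", call. = FALSE)
  min_len <- ceiling(log(max(sizes), base = 4)) + 2L
  if (codon_length < min_len)
    stop(sprintf("`codon_length` must be >= %d for the requested sizes", min_len),
         call. = FALSE)
  max_labels <- length(LETTERS) + length(letters)
  if (any(sizes > max_labels))
    stop(sprintf("at most %d building blocks per position are supported", max_labels),
         call. = FALSE)

  with_seed(seed, {
    positions <- lapply(sizes, function(sz) {
      list(labels = c(LETTERS, letters)[seq_len(sz)],
           codons = make_codon_table(sz, codon_length, min_distance))
    })
    constant <- list(
      five_prime  = random_dna(12L),
      spacers     = vapply(seq_len(length(sizes) - 1L), function(i) random_dna(4L), ""),
      three_prime = random_dna(12L)
    )
    structure(list(sizes = sizes, codon_length = as.integer(codon_length),
                   min_distance = as.integer(min_distance),
                   positions = positions, constant = constant,
                   total_members = prod(sizes)),
              class = "library_design")
  })
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# greedy distance-d code over a seeded shuffle of the 4^len enumeration
make_codon_table <- function(size, len, min_distance) {
  bases <- c("A", "C", "G", "T")
  pool_n <- 4^len
  if (pool_n > 4^10)
    stop("codon length > 10 not supported", call. = FALSE)
  ord <- sample.int(pool_n) - 1L
  # base-4 digit matrix of the shuffled pool
  digits <- matrix(0L, nrow = pool_n, ncol = len)
  for (j in seq_len(len)) digits[, j] <- (ord %/% 4L^(len - j)) %% 4L
  accepted <- matrix(0L, nrow = size, ncol = len)
  n_acc <- 0L
  for (i in seq_len(pool_n)) {
    cand <- digits[i, ]
    if (n_acc > 0L) {
      d <- rowSums(accepted[seq_len(n_acc), , drop = FALSE] !=
                     matrix(cand, n_acc, len, byrow = TRUE))
      if (min(d) < min_distance) next
    }
    n_acc <- n_acc + 1L
    accepted[n_acc, ] <- cand
    if (n_acc == size) break
  }
  if (n_acc < size)
    stop(sprintf(
      "capacity error: no Hamming-distance-%d code of size %d exists in the explored length-%d pool (found %d)",
      min_distance, size, len, n_acc), call. = FALSE)
  apply(accepted, 1L, function(row) paste(bases[row + 1L], collapse = ""))
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("Encoded library design: %s positions, %s members\n",
              length(x$sizes), format(x$total_members, big.mark = ",")))
  cat(sprintf("  sizes: %s; codon length %d nt (min distance %d)\n",
              paste(x$sizes, collapse = " x "), x$codon_length, x$min_distance))
  invisible(x)
}

# per-position building-block index for every member in canonical order
# (position 1 varies fastest)
member_index_matrix <- function(design) {
  n <- design$total_members
  p <- length(design$sizes)
  out <- matrix(0L, nrow = n, ncol = p)
  stride <- 1L
  base <- 0:(n - 1L)
  for (j in seq_len(p)) {
    out[, j] <- (base %/% stride) %% design$sizes[j] + 1L
    stride <- stride * design$sizes[j]
  }
  out
}

#' Member identifiers of a library design
#'
#' @param design a `library_design`.
#' @return character vector of member ids (concatenated per-position labels,
#'   e.g. `"JOMB"`), in the design's canonical order.
#' @export
member_ids <- function(design) {
  idx <- member_index_matrix(design)
  cols <- lapply(seq_along(design$sizes),
                 function(j) design$positions[[j]]$labels[idx[, j]])
  do.call(paste0, cols)
}

#' Match a wildcard family pattern against library members
#'
#' A pattern has one entry per position: a building-block label or `"*"`
#' (any block). With the default single-character labels a pattern can be
#' given as a compact string such as `"JO**"`.
#'
#' @param design a `library_design`.
#' @param pattern character string (one character per position) or character
#'   vector with one label/`"*"` per position.
#' @return logical vector over the design's canonical member order.
#' @export
match_pattern <- function(design, pattern) {
  pat <- split_pattern(design, pattern)
  idx <- member_index_matrix(design)
  keep <- rep(TRUE, design$total_members)
  for (j in seq_along(pat)) {
    if (pat[j] == "*") next
    hit <- match(pat[j], design$positions[[j]]$labels)
    if (is.na(hit))
      stop(sprintf("pattern label '%s' not found at position %d", pat[j], j),
           call. = FALSE)
    keep <- keep & idx[, j] == hit
  }
  keep
}

split_pattern <- function(design, pattern) {
  p <- length(design$sizes)
  if (length(pattern) == p && is.character(pattern)) {
    if (p > 1L || nchar(pattern) == 1L) return(pattern)
  }
  if (length(pattern) == 1L && is.character(pattern)) {
    widths <- vapply(design$positions, function(ps) unique(nchar(ps$labels)), 1L)
    if (any(widths != 1L))
      stop("compact string patterns need single-character labels; pass a vector",
           call. = FALSE)
    if (nchar(pattern) != p)
      stop(sprintf("pattern '%s' has %d characters; the design has %d positions",
                   pattern, nchar(pattern), p), call. = FALSE)
    return(strsplit(pattern, "")[[1L]])
  }
  stop("pattern must be one label/'*' per position", call. = FALSE)
}

#' Simulate an affinity selection on an encoded library
#'
#' Draws pre- and post-selection sequencing reads. Pre-selection member
#' probabilities are uniform; post-selection probabilities multiply the
#' baseline by the enrichment factors and renormalize. Factors of patterns
#' that overlap compose multiplicatively, so a family-wide factor can be
#' combined with an extra factor on a single member. Reads are the 5'
#' constant region, the position codons interleaved with constant spacers,
#' and the 3' constant region, with uniform per-base substitution errors.
#'
#' @param design a `library_design`.
#' @param enrichment_map named numeric vector: wildcard pattern ->
#'   multiplicative enrichment factor (>= 0). `NULL` for a null selection.
#' @param read_depth_pre,read_depth_post read counts to draw.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed; output is byte-identical for equal inputs.
#' @return list with `pre` and `post` (character read vectors) and `truth`
#'   (list of the member probability vectors actually sampled from).
#' @export
simulate_selection <- function(design, enrichment_map = NULL,
                               read_depth_pre = 1e5, read_depth_post = 1e5,
                               error_rate = 0.005, seed = 1) {
  stopifnot(inherits(design, "library_design"))
  stop_if_not_scalar_pos(read_depth_pre, "read_depth_pre")
  stop_if_not_scalar_pos(read_depth_post, "read_depth_post")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1)
    stop("`error_rate` must be in [0, 1)", call. = FALSE)

  n <- design$total_members
  pre_prob <- rep(1 / n, n)
  post_w <- rep(1, n)
  if (!is.null(enrichment_map)) {
    if (is.null(names(enrichment_map)) || any(names(enrichment_map) == ""))
      stop("`enrichment_map` must be a named numeric vector", call. = FALSE)
    if (any(enrichment_map < 0))
      stop("enrichment factors must be >= 0", call. = FALSE)
    for (pat in names(enrichment_map)) {
      hits <- match_pattern(design, pat)
      if (!any(hits))
        stop(sprintf("enrichment pattern '%s' matches no library member", pat),
             call. = FALSE)
      post_w[hits] <- post_w[hits] * enrichment_map[[pat]]
    }
  }
  post_prob <- pre_prob * post_w
  post_prob <- post_prob / sum(post_prob)

  with_seed(seed, {
    pre_members <- sample.int(n, read_depth_pre, replace = TRUE, prob = pre_prob)
    post_members <- sample.int(n, read_depth_post, replace = TRUE, prob = post_prob)
    pre <- build_reads(design, pre_members)
    post <- build_reads(design, post_members)
    if (error_rate > 0) {
      pre <- mutate_reads(pre, error_rate)
      post <- mutate_reads(post, error_rate)
    }
    list(pre = pre, post = post,
         truth = list(pre_prob = pre_prob, post_prob = post_prob))
  })
}

build_reads <- function(design, members) {
  idx <- member_index_matrix(design)[members, , drop = FALSE]
  p <- length(design$sizes)
  parts <- vector("list", 2L * p + 1L)
  parts[[1L]] <- design$constant$five_prime
  for (j in seq_len(p)) {
    parts[[2L * j]] <- design$positions[[j]]$codons[idx[, j]]
    parts[[2L * j + 1L]] <- if (j < p) design$constant$spacers[j]
                            else design$constant$three_prime
  }
  do.call(paste0, parts)
}

# uniform substitution errors; positions drawn without replacement so
# repeated hits on one read are applied sequentially, never lost
mutate_reads <- function(reads, rate) {
  n <- length(reads)
  len <- nchar(reads[1L])
  k <- stats::rbinom(1L, n * len, rate)
  if (k == 0L) return(reads)
  flat <- sample.int(n * len, k)
  read_i <- (flat - 1L) %/% len + 1L
  pos <- (flat - 1L) %% len + 1L
  cur <- substring(reads[read_i], pos, pos)
  bases <- c("A", "C", "G", "T")
  shift <- sample.int(3L, k, replace = TRUE)
  newb <- bases[(match(cur, bases) - 1L + shift) %% 4L + 1L]
  while (length(read_i)) {
    first <- !duplicated(read_i)
    ri <- read_i[first]
    s <- reads[ri]
    substr(s, pos[first], pos[first]) <- newb[first]
    reads[ri] <- s
    read_i <- read_i[!first]; pos <- pos[!first]; newb <- newb[!first]
  }
  reads
}

#' Write selection reads as FASTQ
#'
#' @param reads character vector of DNA reads.
#' @param path output FASTQ path.
#' @param prefix read-name prefix.
#' @return `path`, invisibly. Qualities are constant Phred 40 (`'I'`).
#' @export
write_selection_fastq <- function(reads, path, prefix = "read") {
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- paste0(prefix, seq_along(reads))
  qual <- Biostrings::PhredQuality(strrep("I", nchar(reads)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read selection FASTQ into a character vector
#' @param path FASTQ path.
#' @return character vector of reads.
#' @export
read_selection_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write / read a library design as JSON
#'
#' @param design a `library_design`.
#' @param path JSON path.
#' @return `write_library_design` returns `path` invisibly;
#'   `read_library_design` returns the `library_design`.
#' @export
write_library_design <- function(design, path) {
  stopifnot(inherits(design, "library_design"))
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_library_design
#' @export
read_library_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$sizes <- as.integer(x$sizes)
  x$codon_length <- as.integer(x$codon_length)
  x$min_distance <- as.integer(x$min_distance)
  if (is.data.frame(x$positions))
    x$positions <- lapply(seq_len(nrow(x$positions)), function(i)
      list(labels = x$positions$labels[[i]], codons = x$positions$codons[[i]]))
  x$constant$spacers <- as.character(x$constant$spacers)
  structure(x, class = "library_design")
}

#' Scenario for a coupled prolyl-isomerase assay plate
#'
#' Parameter container for [simulate_ppiase_plate()]. Defaults reflect the
#' assay's standard conditions: 5 nM enzyme, fluorescence read every 1 s for
#' 330 s, thermal (uncatalyzed) cis-trans rate 0.005 s^-1 and enzymatic
#' contribution 0.025 s^-1 at zero inhibitor.
#'
#' @param ki_app_nM named numeric: apparent inhibition constant (nM) per
#'   compound.
#' @param doses_uM inhibitor doses (µM) applied to every compound.
#' @param enzyme_total_nM total enzyme concentration (nM).
#' @param k_thermal,k_enzyme thermal and enzymatic rate contributions (s^-1).
#' @param f0,f_plateau initial and plateau fluorescence (AU).
#' @param bleach_rate post-plateau exponential decay (fraction per second).
#' @param noise_sd Gaussian fluorescence noise (AU).
#' @param interval_s,duration_s sampling interval and total duration (s).
#' @param replicates technical replicates per compound x dose.
#' @param n_control wells per control role.
#' @param seed integer seed.
#' @return a list of class `assay_scenario`.
#' @export
assay_scenario <- function(ki_app_nM, doses_uM,
                           enzyme_total_nM = 5, k_thermal = 0.005,
                           k_enzyme = 0.025, f0 = 100, f_plateau = 600,
                           bleach_rate = 0.001, noise_sd = 2,
                           interval_s = 1, duration_s = 330,
                           replicates = 3, n_control = 3, seed = 1) {
  stopifnot(is.numeric(ki_app_nM), !is.null(names(ki_app_nM)),
            all(ki_app_nM >= 0), all(doses_uM >= 0))
  for (nm in c("enzyme_total_nM", "k_thermal", "k_enzyme", "bleach_rate",
               "noise_sd"))
    stop_if_not_scalar_pos(get(nm), nm, strict = FALSE)
  stop_if_not_scalar_pos(interval_s, "interval_s")
  stop_if_not_scalar_pos(duration_s, "duration_s")
  structure(list(ki_app_nM = ki_app_nM, doses_uM = doses_uM,
                 enzyme_total_nM = enzyme_total_nM, k_thermal = k_thermal,
                 k_enzyme = k_enzyme, f0 = f0, f_plateau = f_plateau,
                 bleach_rate = bleach_rate, noise_sd = noise_sd,
                 interval_s = interval_s, duration_s = duration_s,
                 replicates = replicates, n_control = n_control, seed = seed),
            class = "assay_scenario")
}

#' Simulate a coupled prolyl-isomerase assay plate
#'
#' Generates kinetic wells for substrate-only and enzyme controls plus every
#' compound x dose x replicate combination. The observed rate is
#' `k_obs = k_thermal + k_enzyme * f_free`, where the free-enzyme fraction
#' follows the Morrison tight-binding quadratic (see [morrison_bound()]);
#' this matters because the enzyme is used at 5 nM while inhibition
#' constants run down to low-nM. Fluorescence follows one-phase association
#' `F(t) = F_plateau - (F_plateau - F0) exp(-k_obs t)` up to the plateau end
#' (99% of amplitude), after which photobleaching multiplies the signal by
#' `exp(-bleach_rate (t - t_plateau))`. Gaussian noise is added last.
#'
#' @param scenario an [assay_scenario()].
#' @return list with `data` (tidy data.frame: well, role, compound, dose_uM,
#'   time_s, fluorescence_au) and `truth` (per-well role, dose, free-enzyme
#'   fraction and true `k_obs`).
#' @export
simulate_ppiase_plate <- function(scenario) {
  stopifnot(inherits(scenario, "assay_scenario"))
  sc <- scenario
  wells <- data.frame(role = character(), compound = character(),
                      dose_uM = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(sc$n_control)) {
    wells <- rbind(wells,
                   data.frame(role = "substrate_only", compound = NA_character_,
                              dose_uM = NA_real_),
                   data.frame(role = "enzyme_control", compound = NA_character_,
                              dose_uM = NA_real_))
  }
  for (cmp in names(sc$ki_app_nM))
    for (d in sc$doses_uM)
      for (r in seq_len(sc$replicates))
        wells <- rbind(wells, data.frame(role = "test", compound = cmp,
                                         dose_uM = d))
  wells$well <- sprintf("W%03d", seq_len(nrow(wells)))

  k_true <- f_free <- numeric(nrow(wells))
  for (i in seq_len(nrow(wells))) {
    if (wells$role[i] == "substrate_only") {
      f_free[i] <- NA_real_
      k_true[i] <- sc$k_thermal
    } else if (wells$role[i] == "enzyme_control") {
      f_free[i] <- 1
      k_true[i] <- sc$k_thermal + sc$k_enzyme
    } else {
      ki <- sc$ki_app_nM[[wells$compound[i]]]
      ei <- morrison_bound(sc$enzyme_total_nM, wells$dose_uM[i] * 1e3, ki)
      f_free[i] <- 1 - ei / sc$enzyme_total_nM
      k_true[i] <- sc$k_thermal + sc$k_enzyme * f_free[i]
    }
  }

  times <- seq(0, sc$duration_s, by = sc$interval_s)
  with_seed(sc$seed, {
    rows <- lapply(seq_len(nrow(wells)), function(i) {
      k <- k_true[i]
      f <- sc$f_plateau - (sc$f_plateau - sc$f0) * exp(-k * times)
      t_plateau <- if (k > 0) log(100) / k else Inf
      late <- times > t_plateau
      if (sc$bleach_rate > 0 && any(late))
        f[late] <- f[late] * exp(-sc$bleach_rate * (times[late] - t_plateau))
      if (sc$noise_sd > 0) f <- f + stats::rnorm(length(f), 0, sc$noise_sd)
      data.frame(well = wells$well[i], role = wells$role[i],
                 compound = wells$compound[i], dose_uM = wells$dose_uM[i],
                 time_s = times, fluorescence_au = f,
                 stringsAsFactors = FALSE)
    })
    truth <- cbind(wells[c("well", "role", "compound", "dose_uM")],
                   f_free = f_free, k_true = k_true)
    list(data = do.call(rbind, rows), truth = truth)
  })
}

#' Simulate a fluorescence-polarization titration
#'
#' Saturation mode titrates protein against a fixed fluorescent probe; the
#' bound-probe fraction comes from the exact two-component quadratic (probe
#' depletion included). Competition mode titrates an unlabeled competitor at
#' fixed protein and probe; the bound fraction comes from the exact ternary
#' equilibrium ([solve_ternary_equilibrium()]). The observed anisotropy is
#' the population-weighted mix `f_bound * r_bound + (1 - f_bound) * r_free`
#' (plus an optional linear nonspecific term in saturation mode); the
#' quantum-yield change on binding is neglected.
#'
#' @param mode `"saturation"` or `"competition"`.
#' @param protein_uM protein concentration(s), µM: a vector (saturation) or
#'   scalar (competition).
#' @param probe_nM fluorescent probe concentration (nM; default 0.5).
#' @param kd_probe_uM probe dissociation constant (µM).
#' @param competitor_uM competitor concentrations (µM; competition mode).
#' @param ki_uM competitor inhibition constant (µM; competition mode).
#' @param r_free,r_bound anisotropy of free and bound probe.
#' @param ns_per_uM linear nonspecific anisotropy slope (per µM protein).
#' @param noise_sd Gaussian anisotropy noise.
#' @param seed integer seed.
#' @return data.frame of the titration. Saturation: `conc_uM`, `anisotropy`.
#'   Competition: `conc_uM` (competitor), `anisotropy`, `signal_pct`
#'   (normalized so protein + probe alone = 0% and free probe = 100%).
#'   Ground truth (bound fractions and parameters) is attached as the
#'   `"truth"` attribute.
#' @export
simulate_fp <- function(mode = c("saturation", "competition"),
                        protein_uM, probe_nM = 0.5, kd_probe_uM,
                        competitor_uM = NULL, ki_uM = NULL,
                        r_free = 0.05, r_bound = 0.25, ns_per_uM = 0,
                        noise_sd = 0, seed = 1) {
  mode <- match.arg(mode)
  stop_if_not_scalar_pos(probe_nM, "probe_nM")
  stop_if_not_scalar_pos(kd_probe_uM, "kd_probe_uM")
  L <- probe_nM * 1e-3
  if (mode == "saturation") {
    stopifnot(is.numeric(protein_uM), all(protein_uM >= 0))
    pl <- two_component_bound(protein_uM, L, kd_probe_uM)
    f_bound <- pl / L
    r <- r_free + f_bound * (r_bound - r_free) + ns_per_uM * protein_uM
    out <- data.frame(conc_uM = protein_uM, anisotropy = r)
    truth <- list(f_bound = f_bound, r_free = r_free, r_bound = r_bound,
                  kd_probe_uM = kd_probe_uM, ns_per_uM = ns_per_uM)
  } else {
    stop_if_not_scalar_pos(protein_uM, "protein_uM")
    stopifnot(is.numeric(competitor_uM), all(competitor_uM >= 0))
    stop_if_not_scalar_pos(ki_uM, "ki_uM")
    f_bound <- vapply(competitor_uM, function(I) {
      eq <- solve_ternary_equilibrium(protein_uM, L, kd_probe_uM, I, ki_uM)
      eq$probe_bound_fraction
    }, 1.0)
    r <- r_free + f_bound * (r_bound - r_free)
    f0 <- solve_ternary_equilibrium(protein_uM, L, kd_probe_uM, 0,
                                    ki_uM)$probe_bound_fraction
    r0 <- r_free + f0 * (r_bound - r_free)
    signal <- if (r0 > r_free) 100 * (r0 - r) / (r0 - r_free)
              else rep(0, length(r))
    out <- data.frame(conc_uM = competitor_uM, anisotropy = r,
                      signal_pct = signal)
    truth <- list(f_bound = f_bound, f_bound0 = f0, ki_uM = ki_uM,
                  kd_probe_uM = kd_probe_uM, protein_uM = protein_uM,
                  probe_nM = probe_nM, r_free = r_free, r_bound = r_bound)
  }
  if (noise_sd > 0) {
    out <- with_seed(seed, {
      out$anisotropy <- out$anisotropy + stats::rnorm(nrow(out), 0, noise_sd)
      if (!is.null(out$signal_pct) && r_bound > r_free)
        out$signal_pct <- 100 * ((r0 - out$anisotropy) / (r0 - r_free))
      out
    })
  }
  attr(out, "truth") <- truth
  out
}

# exact bound complex of P + L <-> PL with depletion (all concentrations in
# the same unit)
two_component_bound <- function(P, L, KD) {
  s <- P + L + KD
  disc <- pmax(s^2 - 4 * P * L, 0)
  (s - sqrt(disc)) / 2
}

#' Simulate a mitochondrial calcium-retention-capacity trace
#'
#' Emulates an extramitochondrial calcium-dye fluorescence recording under
#' sequential CaCl2 pulses: each injection produces an instantaneous
#' fluorescence jump followed by exponential return toward baseline as
#' mitochondria take the calcium up. After `capacity` resorbed pulses the
#' next injection triggers permeability-transition pore opening: the trace
#' rises abruptly toward the level of all released calcium and stays
#' elevated.
#'
#' @param capacity number of pulses taken up before release (>= 1).
#' @param baseline baseline fluorescence (AU).
#' @param pulse_amplitude fluorescence jump per pulse (AU).
#' @param decay_rate uptake return rate (s^-1).
#' @param interval_s time between injections (s).
#' @param dt_s sampling interval (s).
#' @param tail_s recording time after the release injection (s).
#' @param noise_sd Gaussian noise (AU).
#' @param seed integer seed.
#' @return list with `trace` (data.frame `time_s`, `value`), `schedule`
#'   (data.frame `pulse`, `time_s` of every injection, including the one
#'   that triggers release) and `capacity` (ground truth).
#' @export
simulate_crc <- function(capacity, baseline = 100, pulse_amplitude = 400,
                         decay_rate = 0.08, interval_s = 120, dt_s = 1,
                         tail_s = 600, noise_sd = 0, seed = 1) {
  stopifnot(capacity >= 1)
  stop_if_not_scalar_pos(pulse_amplitude, "pulse_amplitude")
  stop_if_not_scalar_pos(decay_rate, "decay_rate")
  stop_if_not_scalar_pos(interval_s, "interval_s")
  n_inj <- capacity + 1L
  inj_times <- interval_s * seq_len(n_inj)
  t_end <- inj_times[n_inj] + tail_s
  times <- seq(0, t_end, by = dt_s)
  f <- rep(baseline, length(times))
  for (i in seq_len(capacity)) {
    after <- times >= inj_times[i]
    f[after] <- f[after] +
      pulse_amplitude * exp(-decay_rate * (times[after] - inj_times[i]))
  }
  t_rel <- inj_times[n_inj]
  after <- times >= t_rel
  release_level <- baseline + pulse_amplitude * n_inj
  f_pre <- f[max(which(!after))] + pulse_amplitude
  f[after] <- release_level - (release_level - f_pre) *
    exp(-decay_rate * (times[after] - t_rel))
  if (noise_sd > 0)
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  list(trace = data.frame(time_s = times, value = f),
       schedule = data.frame(pulse = seq_len(n_inj), time_s = inj_times),
       capacity = as.integer(capacity))
}
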