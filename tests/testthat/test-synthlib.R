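test_that("library designs satisfy code invariants across configurations", {
  configs <- list(list(sizes = c(2, 2, 2, 2), len = 6),
                  list(sizes = c(4, 3), len = 5),
                  list(sizes = c(20, 20, 20, 32), len = 8))
  for (cf in configs) {
    d <- design_library(sizes = cf$sizes, codon_length = cf$len, seed = 3)
    expect_equal(d$total_members, prod(cf$sizes))
    for (ps in d$positions) {
      expect_equal(length(unique(ps$codons)), length(ps$codons))
      expect_true(all(nchar(ps$codons) == cf$len))
      if (length(ps$codons) > 1) {
        pairs <- utils::combn(ps$codons, 2)
        dists <- apply(pairs, 2, function(p) hamming(p[1], p[2]))
        expect_true(min(dists) >= 3)
      }
    }
  }
})

test_that("library design is deterministic in the seed", {
  d1 <- design_library(sizes = c(4, 4), codon_length = 6, seed = 5)
  d2 <- design_library(sizes = c(4, 4), codon_length = 6, seed = 5)
  d3 <- design_library(sizes = c(4, 4), codon_length = 6, seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(d1$positions, d3$positions))
})

test_that("default configuration yields the 256,000-member library", {
  d <- design_library(seed = 1)
  expect_equal(d$total_members, 256000)
  expect_equal(d$sizes, c(20L, 20L, 20L, 32L))
})

test_that("infeasible code requests raise a capacity error", {
  # 300 codons of length 4 at distance 3 exceed what the pool can encode
  expect_error(design_library(sizes = 300, codon_length = 4), "codon_length")
  # length admitted by the precondition but beyond the greedy code's reach
  expect_error(design_library(sizes = 40, codon_length = 5, seed = 2),
               "capacity")
})

test_that("design JSON round-trips", {
  d <- toy_design()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_library_design(d, path)
  d2 <- read_library_design(path)
  expect_equal(member_ids(d2), member_ids(d))
  expect_equal(d2$positions[[3]]$codons, d$positions[[3]]$codons)
  expect_equal(d2$constant, d$constant)
})

test_that("Morrison bound reproduces its limiting cases", {
  expect_equal(morrison_bound(5, 0, 1), 0)            # no inhibitor
  expect_equal(morrison_bound(5, 5, 0), 5)            # stoichiometric, Ki -> 0
  expect_equal(morrison_bound(5, 1e9, 1), 5, tolerance = 1e-6) # saturation
  # classical limit: I >> E recovers 1/(1 + Ki/I) occupancy
  ei <- morrison_bound(0.001, 100, 50)
  expect_equal(ei / 0.001, 100 / 150, tolerance = 1e-4)
})

test_that("the 50%-activity dose equals Ki_app + E/2 (root-find oracle)", {
  E <- 5
  for (ki in c(0.1, 1, 10, 100)) {
    f_free <- function(I) 1 - morrison_bound(E, I, ki) / E
    root <- uniroot(function(I) f_free(I) - 0.5, c(0, 1e6), tol = 1e-12)$root
    expect_equal(root, ki + E / 2, tolerance = 1e-6)
    expect_true(root >= E / 2)
  }
})

test_that("simulated plate rates honour the Morrison ground truth", {
  sc <- assay_scenario(ki_app_nM = c(X = 1), doses_uM = c(0.001, 5e-3),
                      noise_sd = 0, replicates = 1, seed = 2)
  pl <- simulate_ppiase_plate(sc)
  tr <- pl$truth
  # enzyme control: full rate; substrate only: thermal rate
  expect_equal(tr$k_true[tr$role == "enzyme_control"][1], 0.03)
  expect_equal(tr$k_true[tr$role == "substrate_only"][1], 0.005)
  # stoichiometric titration at Ki -> 0: dose 5 nM kills all enzyme activity
  sc0 <- assay_scenario(ki_app_nM = c(X = 0), doses_uM = 5e-3,
                        noise_sd = 0, replicates = 1)
  tr0 <- simulate_ppiase_plate(sc0)$truth
  expect_equal(tr0$k_true[tr0$role == "test"], 0.005, tolerance = 1e-12)
})

test_that("plate traces plateau and then bleach", {
  sc <- assay_scenario(ki_app_nM = c(X = 1e6), doses_uM = 1e-6,
                      noise_sd = 0, replicates = 1, bleach_rate = 0.002)
  pl <- simulate_ppiase_plate(sc)$data
  wid <- pl$well[pl$role == "enzyme_control"][1]
  w <- pl[pl$well == wid, ]
  k <- 0.03
  t_plateau <- log(100) / k
  peak_t <- w$time_s[which.max(w$fluorescence_au)]
  expect_lt(abs(peak_t - t_plateau), 25)
  expect_lt(w$fluorescence_au[nrow(w)], max(w$fluorescence_au))
})

test_that("selection with null enrichment decodes fully and shows no signal", {
  d <- toy_design()
  sel <- simulate_selection(d, NULL, read_depth_pre = 5000,
                            read_depth_post = 5000, error_rate = 0, seed = 4)
  pre <- tally_counts(sel$pre, d)
  post <- tally_counts(sel$post, d)
  expect_equal(attr(pre, "report")$assigned, 5000)
  expect_equal(length(attr(pre, "report")$rejected), 0)
  enr <- compute_enrichment(pre, post)
  # binomial sampling error: sd of each pct ~ 100*sqrt(p(1-p)/n) ~ 0.34
  expect_lt(max(abs(enr$delta_pct)), 2)
})

test_that("selection output is byte-identical for equal seeds", {
  d <- toy_design()
  s1 <- simulate_selection(d, c("AA**" = 10), 2000, 2000,
                           error_rate = 0.01, seed = 9)
  s2 <- simulate_selection(d, c("AA**" = 10), 2000, 2000,
                           error_rate = 0.01, seed = 9)
  expect_identical(s1, s2)
})

test_that("a pattern matching no member is rejected by name", {
  d <- toy_design()
  expect_error(simulate_selection(d, c("AZ**" = 10), 100, 100),
               "position 2")
})

test_that("null-selection |delta pct| shrinks with read depth", {
  d <- toy_design()
  mean_abs <- function(depth) {
    sel <- simulate_selection(d, NULL, depth, depth, error_rate = 0, seed = 21)
    enr <- compute_enrichment(tally_counts(sel$pre, d),
                              tally_counts(sel$post, d))
    mean(abs(enr$delta_pct))
  }
  shallow <- mean_abs(1e4)
  deep <- mean_abs(1e6)
  # O(1/sqrt(depth)): a 100x depth increase should shrink the noise ~10x
  expect_lt(deep, shallow / 3)
})

test_that("FP saturation limit reaches the bound anisotropy", {
  fp <- simulate_fp("saturation", protein_uM = c(0.001, 0.1, 1, 10, 1e4),
                    probe_nM = 0.5, kd_probe_uM = 1,
                    r_free = 0.05, r_bound = 0.25)
  expect_equal(fp$anisotropy[nrow(fp)], 0.25, tolerance = 1e-3)
})

test_that("competition at zero competitor reproduces the saturation point", {
  sat <- simulate_fp("saturation", protein_uM = 0.5, probe_nM = 0.5,
                     kd_probe_uM = 0.2)
  comp <- simulate_fp("competition", protein_uM = 0.5, probe_nM = 0.5,
                      kd_probe_uM = 0.2, competitor_uM = 0, ki_uM = 1)
  expect_equal(comp$anisotropy[1], sat$anisotropy[1], tolerance = 1e-9)
  expect_equal(comp$signal_pct[1], 0, tolerance = 1e-9)
})

test_that("FP generator conserves probe mass to 1e-9 relative", {
  set.seed(31)
  for (i in 1:20) {
    eq <- solve_ternary_equilibrium(10^runif(1, -3, 1), 5e-4,
                                    10^runif(1, -2, 1), 10^runif(1, -3, 1),
                                    10^runif(1, -2, 1))
    expect_true(all(eq$residuals < 1e-9))
  }
})

test_that("CRC traces contain exactly `capacity` resorbed pulses", {
  crc <- simulate_crc(6)
  expect_equal(nrow(crc$schedule), 7)       # release-triggering injection
  res <- count_crc_pulses(crc$trace, crc$schedule)
  expect_equal(res$pulses, 6L)
  expect_true(res$released)
  # trace stays elevated after release
  late <- crc$trace$value[crc$trace$time_s > max(crc$schedule$time_s) + 200]
  expect_true(all(late > 100 + 400))
})

test_that("noiseless CRC traces are reproducible", {
  c1 <- simulate_crc(4, noise_sd = 0, seed = 1)
  c2 <- simulate_crc(4, noise_sd = 0, seed = 99)
  expect_identical(c1$trace, c2$trace)
})

test_that("generators do not disturb the session RNG state", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_selection(toy_design(), NULL, 100, 100, seed = 7))
  invisible(simulate_crc(3, noise_sd = 1, seed = 8))
  expect_identical(runif(1), before)
})
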