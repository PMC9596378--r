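panel_fixture <- function() {
  selectivity_matrix(data.frame(
    compound = c("JOMBt", "A26",
                 "B52", "B52", "B52",
                 "B32", "B32",
                 "C3A", "C3A", "C3A", "C3A"),
    variant  = c("CypD", "CypD",
                 "CypD", "CypB", "PPWD1",
                 "CypD", "CypD K118E/R124A",
                 "CypE", "CypE K217A", "CypE", "CypE K217A"),
    assay    = c("ppiase_ic50", "ppiase_ic50",
                 "ppiase_ic50", "ppiase_ic50", "ppiase_ic50",
                 "ppiase_ic50", "ppiase_ic50",
                 "ppiase_ic50", "ppiase_ic50", "fp_ki", "fp_ki"),
    value_uM = c(17, 0.20, 0.010, 0.21, 100, 6, 0.06, 0.013, 2, 0.072, 3.1),
    censor   = c("", "", "", "", ">", "", "", "", "", "", ""),
    stringsAsFactors = FALSE))
}

test_that("fold selectivity reproduces the panel's worked examples", {
  m <- panel_fixture()
  f <- fold_selectivity(m, "B52", "CypD", "CypB")
  expect_false(is_censored(f))
  expect_equal(f$value, 21)
  # censored off-target propagates as a lower bound
  f2 <- fold_selectivity(m, "B52", "CypD", "PPWD1")
  expect_equal(f2$censor, ">")
  expect_equal(f2$value, 10000)
  # identity
  expect_equal(fold_selectivity(m, "B52", "CypD", "CypD")$value, 1)
})

test_that("mutant shifts match the printed rescue and loss folds", {
  m <- panel_fixture()
  expect_equal(mutant_shift(m, "B32", "CypD", "CypD K118E/R124A")$value, 100)
  s <- mutant_shift(m, "C3A", "CypE K217A", "CypE", assay = "ppiase_ic50")
  expect_equal(round_fold(s, 2)$value, 150)
  s2 <- mutant_shift(m, "C3A", "CypE K217A", "CypE", assay = "fp_ki")
  expect_equal(round_fold(s2, 1)$value, 40)
})

test_that("cross-assay folds are refused and ambiguity requires `assay`", {
  m <- panel_fixture()
  expect_error(fold_selectivity(m, "C3A", "CypE", "CypE K217A"), "ambiguous")
  m2 <- selectivity_matrix(data.frame(
    compound = "X", variant = c("CypD", "CypE"),
    assay = c("ppiase_ic50", "fp_ki"), value_uM = c(1, 2)))
  expect_error(fold_selectivity(m2, "X", "CypD", "CypE"), "cross-assay")
})

test_that("censoring algebra is closed and correctly directed", {
  num_plain <- censored_qty(10)
  lower <- censored_qty(100, ">")
  upper <- censored_qty(0.1, "<")
  expect_equal(censored_ratio(lower, num_plain)$censor, ">")
  expect_equal(censored_ratio(upper, num_plain)$censor, "<")
  expect_equal(censored_ratio(num_plain, lower)$censor, "<")
  expect_equal(censored_ratio(num_plain, upper)$censor, ">")
  expect_equal(censored_ratio(lower, upper)$censor, "indeterminate")
  expect_equal(censored_ratio(num_plain, num_plain)$censor, "none")
  # rounding preserves the bound direction
  expect_equal(format(round_fold(censored_qty(10400, ">"), 2)), "> 10,000")
})

test_that("CRC detector recovers generator capacity exactly for 1-20", {
  for (cap in 1:20) {
    crc <- simulate_crc(cap)
    res <- count_crc_pulses(crc$trace, crc$schedule)
    expect_equal(res$pulses, cap)
    expect_true(res$released)
  }
})

test_that("CRC detector tolerates 1% pulse-amplitude noise", {
  hits <- sum(vapply(1:100, function(s) {
    crc <- simulate_crc(5, noise_sd = 4, seed = s)   # 1% of 400 AU
    count_crc_pulses(crc$trace, crc$schedule)$pulses == 5L
  }, TRUE))
  expect_gte(hits, 95)
})

test_that("traces without release are flagged and bound the ratio", {
  crc <- simulate_crc(6)
  # drop the release injection and the post-release trace: all pulses resorbed
  t_rel <- crc$schedule$time_s[7]
  trace <- crc$trace[crc$trace$time_s < t_rel, ]
  sched <- crc$schedule[1:6, ]
  res <- count_crc_pulses(trace, sched)
  expect_false(res$released)
  expect_equal(res$pulses, 6L)

  control <- count_crc_pulses(crc$trace, crc$schedule)   # 6, released
  ratio <- crc_ratio(res, control)
  expect_equal(ratio$censor, ">")
  expect_equal(ratio$value, 1)
})

test_that("CRC ratio arithmetic matches hand computation", {
  expect_equal(crc_ratio(8, 4)$value, 2)
  expect_equal(crc_ratio(4, 4)$value, 1)
  expect_error(crc_ratio(4, 0), "positive")
})

test_that("species fractions normalize total-ion counts", {
  expect_equal(unname(species_fractions(c(1000, 500, 500))),
               c(0.50, 0.25, 0.25))
  expect_equal(unname(species_fractions(c(0, 0, 10))), c(0, 0, 1))
  expect_error(species_fractions(c(0, 0, 0)), "positive")
  set.seed(3)
  for (i in 1:50) {
    tic <- runif(3, 0, 1e6)
    expect_equal(sum(species_fractions(tic)), 1, tolerance = 1e-12)
  }
})

test_that("reports are complete and byte-identical across re-runs", {
  m <- panel_fixture()
  d <- toy_design()
  sel <- simulate_selection(d, c("AB**" = 20), 2000, 2000,
                            error_rate = 0, seed = 2)
  enr <- compute_enrichment(tally_counts(sel$pre, d),
                            tally_counts(sel$post, d))
  crc6 <- simulate_crc(6); crc3 <- simulate_crc(3)
  crcs <- list(DMSO = count_crc_pulses(crc3$trace, crc3$schedule),
               B52 = count_crc_pulses(crc6$trace, crc6$schedule))
  rep1 <- build_report(enrichment = enr, matrix = m, crc = crcs)
  expect_equal(nrow(rep1$selectivity), nrow(m))    # one row per cell
  expect_equal(rep1$crc$pulses, c(6L, 3L))         # sorted by condition

  dir1 <- tempfile(); dir2 <- tempfile()
  on.exit(unlink(c(dir1, dir2), recursive = TRUE))
  write_report(rep1, dir1)
  write_report(build_report(enrichment = enr, matrix = m, crc = crcs), dir2)
  expect_identical(readLines(file.path(dir1, "report.json")),
                   readLines(file.path(dir2, "report.json")))

  empty <- build_report()
  expect_s3_class(empty, "campaign_report")
  expect_equal(nrow(empty$hits), 0)
})
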