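test_that("error-free and singly-mutated reads decode to the right member", {
  d <- toy_design()
  ids <- member_ids(d)
  read1 <- member_read(d, 1L)                       # member (1,1,1,1)
  expect_equal(decode_read(read1, d, max_mismatch = 0)$member, ids[1])

  # one substitution inside codon 2 is corrected at max_mismatch = 1 ...
  off2 <- nchar(d$constant$five_prime) + d$codon_length +
    nchar(d$constant$spacers[1]) + 1L
  mut <- sub_base(read1, off2)
  expect_equal(decode_read(mut, d, max_mismatch = 1)$member, ids[1])
  # ... but rejected at max_mismatch = 0
  r0 <- decode_read(mut, d, max_mismatch = 0)
  expect_true(is.na(r0$member))
  expect_equal(r0$reason, "unmatched")
  expect_equal(r0$position, 2L)
})

test_that("a codon 2+ substitutions from every table entry is unmatched", {
  d <- toy_design()
  read1 <- member_read(d, 1L)
  off2 <- nchar(d$constant$five_prime) + d$codon_length +
    nchar(d$constant$spacers[1]) + 1L
  # distance-3 code: two substitutions leave the codon >= 1 from the true
  # entry and >= 1 from all others, outside the radius-1 ball
  mut <- sub_base(sub_base(read1, off2), off2 + 1L)
  r <- decode_read(mut, d, max_mismatch = 1)
  expect_true(is.na(r$member))
  expect_equal(r$reason, "unmatched")
  expect_equal(r$position, 2L)
})

test_that("short reads are rejected as truncated", {
  d <- toy_design()
  r <- decode_read(substr(member_read(d, 3L), 1, 20), d)
  expect_equal(r$reason, "truncated")
})

test_that("decoding agrees with the brute-force nearest-member scan", {
  d <- toy_design()
  set.seed(17)
  n_reads <- 120
  members <- sample.int(d$total_members, n_reads, replace = TRUE)
  reads <- vapply(members, function(m) member_read(d, m), "")
  len <- nchar(reads[1])
  # sprinkle 0-3 substitutions per read anywhere in the read
  for (i in seq_len(n_reads)) {
    for (p in sample.int(len, sample(0:3, 1)))
      reads[i] <- sub_base(reads[i], p)
  }
  for (mm in 0:1) {
    got <- decode_reads(reads, d, max_mismatch = mm)$member
    want <- vapply(reads, brute_decode, "", design = d, max_mismatch = mm,
                   USE.NAMES = FALSE)
    expect_equal(got, want)
  }
})

test_that("tallies conserve reads and compute percentages over decoded reads", {
  d <- design_library(sizes = 3, codon_length = 4, seed = 2)
  reads <- c(rep(member_read(d, 1L), 50), rep(member_read(d, 2L), 30),
             rep(member_read(d, 3L), 20))
  tc <- tally_counts(reads, d)
  rep_ <- attr(tc, "report")
  expect_equal(rep_$assigned, 100)
  expect_equal(rep_$total, 100)
  expect_equal(tc$pct, c(50, 30, 20))

  # conservation with rejections: corrupt some reads beyond repair
  bad <- vapply(reads[1:10], function(r) {
    for (p in 1:6) r <- sub_base(r, nchar(d$constant$five_prime) + p)
    r
  }, "", USE.NAMES = FALSE)
  tc2 <- tally_counts(c(reads, bad), d)
  rep2 <- attr(tc2, "report")
  expect_equal(rep2$assigned + sum(unlist(rep2$rejected)), rep2$total)
})

test_that("empty input is an error, not a silent 0/0", {
  d <- toy_design()
  expect_error(tally_counts(character(0), d), "no reads")
})

test_that("1-mismatch decoding rescues more reads than exact decoding", {
  d <- toy_design()
  sel <- simulate_selection(d, NULL, 5000, 100, error_rate = 0.01, seed = 13)
  a1 <- attr(tally_counts(sel$pre, d, max_mismatch = 1), "report")$assigned
  a0 <- attr(tally_counts(sel$pre, d, max_mismatch = 0), "report")$assigned
  expect_gt(a1, a0 + 1)
})

test_that("enrichment arithmetic, pseudocount and ordering behave", {
  d <- design_library(sizes = 3, codon_length = 4, seed = 2)
  mk <- function(counts) {
    reads <- unlist(lapply(seq_along(counts), function(i)
      rep(member_read(d, i), counts[i])))
    tally_counts(reads, d)
  }
  pre <- mk(c(50, 30, 20))
  post <- mk(c(10, 30, 60))
  enr <- compute_enrichment(pre, post)
  expect_equal(enr$delta_pct[match(member_ids(d), enr$member)],
               c(-40, 0, 40))
  expect_equal(sum(enr$delta_pct), 0, tolerance = 1e-9)
  # descending delta ordering
  expect_equal(enr$delta_pct, sort(enr$delta_pct, decreasing = TRUE))

  # identity
  same <- compute_enrichment(pre, pre)
  expect_true(all(same$delta_pct == 0))
  expect_true(all(abs(same$fold - 1) < 1e-12))

  # pseudocount keeps zero-count folds finite
  enr0 <- compute_enrichment(mk(c(100, 0, 0)), mk(c(90, 0, 10)),
                             pseudocount = 0.5)
  row <- enr0[enr0$member == member_ids(d)[3], ]
  expect_true(is.finite(row$fold) && row$fold > 1)
  expect_equal(row$delta_pct, row$post_pct)
})

test_that("mismatched member universes are refused", {
  d <- toy_design()
  sel <- simulate_selection(d, NULL, 500, 500, error_rate = 0, seed = 2)
  pre <- tally_counts(sel$pre, d)
  post <- tally_counts(sel$post, d)
  expect_error(compute_enrichment(pre[-1, ], post), "universe")
})

test_that("family aggregation sums, ranks and validates patterns", {
  d <- toy_design()
  sel <- simulate_selection(d, c("AB**" = 40), 3e4, 3e4,
                            error_rate = 0, seed = 5)
  enr <- compute_enrichment(tally_counts(sel$pre, d),
                            tally_counts(sel$post, d))
  # the full-universe pattern sums to zero by the zero-sum invariant
  all_fam <- aggregate_families(enr, d, "****")
  expect_equal(all_fam$sum_delta_pct, 0, tolerance = 1e-9)
  expect_equal(all_fam$n_members, 16)

  # planted family ranks first among double-wildcard patterns, and its
  # summed delta matches direct summation over the 4 matching members
  auto <- aggregate_families(enr, d, "auto")
  two <- auto[auto$n_wildcards == 2, ]
  expect_equal(two$pattern[1], "AB**")
  direct <- sum(enr$delta_pct[match_pattern(d, "AB**")[
    match(enr$member, member_ids(d))]])
  expect_equal(two$sum_delta_pct[1], direct)
  expect_equal(two$n_members[1], 4)

  expect_error(aggregate_families(enr, d, "AB*"), "4 positions")
})

test_that("FASTQ round trip preserves reads", {
  d <- toy_design()
  sel <- simulate_selection(d, NULL, 50, 50, error_rate = 0, seed = 3)
  path <- tempfile(fileext = ".fastq")
  on.exit(unlink(path))
  write_selection_fastq(sel$pre, path)
  back <- read_selection_fastq(path)
  expect_equal(unname(back), sel$pre)
})
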