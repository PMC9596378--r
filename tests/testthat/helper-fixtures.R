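# shared fixtures: small designs and an independent brute-force decoder

toy_design <- function(seed = 1) {
  design_library(sizes = c(2, 2, 2, 2), codon_length = 6, seed = seed)
}

# reconstruct the error-free read of one member straight from design fields
# (independent of build_reads)
member_read <- function(design, member_idx) {
  p <- length(design$sizes)
  stride <- 1L
  parts <- design$constant$five_prime
  rest <- member_idx - 1L
  for (j in seq_len(p)) {
    ij <- (rest %/% stride) %% design$sizes[j] + 1L
    stride <- stride * design$sizes[j]
    parts <- paste0(parts, design$positions[[j]]$codons[ij],
                    if (j < p) design$constant$spacers[j]
                    else design$constant$three_prime)
  }
  parts
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force decode: scan every member and accept the unique one whose
# codons all lie within max_mismatch of the observed codon at that slot
brute_decode <- function(read, design, max_mismatch) {
  p <- length(design$sizes)
  cl <- design$codon_length
  off <- nchar(design$constant$five_prime) + 1L
  obs <- character(p)
  for (j in seq_len(p)) {
    obs[j] <- substr(read, off, off + cl - 1L)
    off <- off + cl + if (j < p) nchar(design$constant$spacers[j]) else 0L
  }
  ok <- vapply(seq_len(design$total_members), function(i) {
    full <- member_read(design, i)
    o <- nchar(design$constant$five_prime) + 1L
    for (j in seq_len(p)) {
      cod <- substr(full, o, o + cl - 1L)
      if (hamming(cod, obs[j]) > max_mismatch) return(FALSE)
      o <- o + cl + if (j < p) nchar(design$constant$spacers[j]) else 0L
    }
    TRUE
  }, TRUE)
  if (sum(ok) == 1L) member_ids(design)[ok] else NA_character_
}

# substitute one base at a given position
sub_base <- function(read, pos) {
  bases <- c("A", "C", "G", "T")
  cur <- substr(read, pos, pos)
  substr(read, pos, pos) <- setdiff(bases, cur)[1]
  read
}
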