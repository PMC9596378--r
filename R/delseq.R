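#' Decode selection reads into library members
#'
#' Locates each codon slot at its fixed offset in the read layout and
#' assigns the observed codon to the unique building block within
#' `max_mismatch` substitutions. Because codon tables are built at pairwise
#' Hamming distance >= 3, assignment at `max_mismatch = 1` is always
#' unambiguous; the ambiguity rejection path exists for user-supplied
#' designs with weaker codes.
#'
#' @param reads character vector of DNA reads.
#' @param design a `library_design`.
#' @param max_mismatch 0 (exact codons only) or 1 (correct single
#'   substitutions).
#' @return data.frame with one row per read: `member_index` (canonical index
#'   or `NA`), `member` (id or `NA`), `reason` (`NA` when assigned, else
#'   `"truncated"`, `"unmatched"` or `"ambiguous"`) and `position` (codon
#'   slot at fault, `NA` otherwise).
#' @export
decode_reads <- function(reads, design, max_mismatch = 1) {
  stopifnot(inherits(design, "library_design"))
  if (!max_mismatch %in% c(0L, 1L))
    stop("`max_mismatch` must be 0 or 1", call. = FALSE)
  n <- length(reads)
  p <- length(design$sizes)
  cl <- design$codon_length
  offsets <- codon_offsets(design)
  layout_len <- nchar(design$constant$five_prime) + p * cl +
    sum(nchar(design$constant$spacers)) + nchar(design$constant$three_prime)

  reason <- rep(NA_character_, n)
  position <- rep(NA_integer_, n)
  ok <- nchar(reads) >= layout_len
  reason[!ok] <- "truncated"

  pos_idx <- matrix(NA_integer_, nrow = n, ncol = p)
  for (j in seq_len(p)) {
    active <- which(ok & is.na(reason))
    if (!length(active)) break
    obs <- substr(reads[active], offsets[j], offsets[j] + cl - 1L)
    codons <- design$positions[[j]]$codons
    hit <- match(obs, codons)
    if (max_mismatch >= 1L && anyNA(hit)) {
      miss <- which(is.na(hit))
      res <- nearest_codon(unique(obs[miss]), codons, max_mismatch)
      m <- match(obs[miss], res$query)
      hit[miss] <- res$index[m]
      amb <- res$ambiguous[m]
      reason[active[miss][amb]] <- "ambiguous"
      position[active[miss][amb]] <- j
    }
    bad <- is.na(hit) & is.na(reason[active])
    reason[active[bad]] <- "unmatched"
    position[active[bad]] <- j
    pos_idx[active, j] <- hit
  }

  member_index <- rep(NA_integer_, n)
  assigned <- is.na(reason)
  if (any(assigned)) {
    stride <- 1L
    lin <- rep(0, sum(assigned))
    for (j in seq_len(p)) {
      lin <- lin + (pos_idx[assigned, j] - 1L) * stride
      stride <- stride * design$sizes[j]
    }
    member_index[assigned] <- as.integer(lin) + 1L
  }
  ids <- member_ids(design)
  data.frame(member_index = member_index,
             member = ifelse(is.na(member_index), NA_character_,
                             ids[member_index]),
             reason = reason, position = position,
             stringsAsFactors = FALSE)
}

#' @rdname decode_reads
#' @param read a single DNA read.
#' @return `decode_read` returns a one-row list: `member` (id or `NA`),
#'   `reason`, `position`.
#' @export
decode_read <- function(read, design, max_mismatch = 1) {
  res <- decode_reads(read, design, max_mismatch)
  list(member = res$member[1L], reason = res$reason[1L],
       position = res$position[1L])
}

codon_offsets <- function(design) {
  p <- length(design$sizes)
  cl <- design$codon_length
  off <- integer(p)
  cur <- nchar(design$constant$five_prime) + 1L
  for (j in seq_len(p)) {
    off[j] <- cur
    cur <- cur + cl + if (j < p) nchar(design$constant$spacers[j]) else 0L
  }
  off
}

# Hamming-nearest table entry for each query codon; ambiguous when two or
# more entries lie within max_mismatch
nearest_codon <- function(queries, codons, max_mismatch) {
  if (!length(queries))
    return(list(query = character(), index = integer(), ambiguous = logical()))
  cl <- nchar(codons[1L])
  qm <- matrix(unlist(strsplit(queries, "", fixed = TRUE), use.names = FALSE),
               ncol = cl, byrow = TRUE)
  tm <- matrix(unlist(strsplit(codons, "", fixed = TRUE), use.names = FALSE),
               ncol = cl, byrow = TRUE)
  d <- matrix(0L, nrow = length(queries), ncol = length(codons))
  for (j in seq_len(cl))
    d <- d + outer(qm[, j], tm[, j], "!=")
  within <- d <= max_mismatch
  n_within <- rowSums(within)
  idx <- apply(d, 1L, which.min)
  idx[n_within == 0L] <- NA_integer_
  list(query = queries, index = as.integer(idx), ambiguous = n_within > 1L)
}

#' Tally decoded reads over the full member universe
#'
#' @param reads character vector of reads (or a decode data.frame from
#'   [decode_reads()]).
#' @param design a `library_design`.
#' @param max_mismatch passed to [decode_reads()].
#' @return object of class `member_counts`: data.frame (`member`, `count`,
#'   `pct`) covering every library member (zero-filled when unobserved),
#'   with percent computed over decoded reads only. The decode report
#'   (total, assigned, rejected-by-reason) is attached as attribute
#'   `"report"`.
#' @export
tally_counts <- function(reads, design, max_mismatch = 1) {
  stopifnot(inherits(design, "library_design"))
  if (is.data.frame(reads)) decoded <- reads
  else {
    if (!length(reads)) stop("no reads supplied", call. = FALSE)
    decoded <- decode_reads(reads, design, max_mismatch)
  }
  if (!nrow(decoded)) stop("no reads supplied", call. = FALSE)
  assigned <- !is.na(decoded$member_index)
  n_assigned <- sum(assigned)
  if (n_assigned == 0L)
    stop("no read decoded to a library member; percentages undefined",
         call. = FALSE)
  counts <- tabulate(decoded$member_index[assigned],
                     nbins = design$total_members)
  rejected <- table(decoded$reason[!assigned])
  out <- data.frame(member = member_ids(design), count = counts,
                    pct = 100 * counts / n_assigned,
                    stringsAsFactors = FALSE)
  attr(out, "report") <- list(total = nrow(decoded), assigned = n_assigned,
                              rejected = as.list(rejected))
  class(out) <- c("member_counts", "data.frame")
  out
}

#' Change in percentage abundance between selection rounds
#'
#' The enrichment statistic of the selection analysis: for every library
#' member, `delta_pct = post_pct - pre_pct` in percent of decoded reads.
#' A pseudocounted fold ratio is reported alongside,
#' `fold = ((post + a)/(post_total + a N)) / ((pre + a)/(pre_total + a N))`,
#' which stays finite for members unobserved in one round.
#'
#' @param pre,post `member_counts` tables over the identical member
#'   universe.
#' @param pseudocount pseudocount `a` (default 0.5).
#' @return object of class `enrichment_table`: data.frame (`member`,
#'   `pre_count`, `post_count`, `pre_pct`, `post_pct`, `delta_pct`, `fold`)
#'   sorted by descending `delta_pct`, ties broken by descending `fold`,
#'   then member id.
#' @export
compute_enrichment <- function(pre, post, pseudocount = 0.5) {
  stopifnot(is.data.frame(pre), is.data.frame(post))
  if (nrow(pre) != nrow(post) || !identical(pre$member, post$member))
    stop("pre and post tables must cover the identical member universe",
         call. = FALSE)
  stop_if_not_scalar_pos(pseudocount, "pseudocount")
  n <- nrow(pre)
  pre_total <- sum(pre$count)
  post_total <- sum(post$count)
  a <- pseudocount
  fold <- ((post$count + a) / (post_total + a * n)) /
          ((pre$count + a) / (pre_total + a * n))
  out <- data.frame(member = pre$member,
                    pre_count = pre$count, post_count = post$count,
                    pre_pct = pre$pct, post_pct = post$pct,
                    delta_pct = post$pct - pre$pct, fold = fold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta_pct, -out$fold, out$member), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Aggregate enrichment over wildcard families
#'
#' Hit families share building blocks at some positions and vary at others
#' (for example all members matching `"JO**"`). For every pattern the member
#' count, summed delta-percent and the mean/median member delta-percent are
#' reported, ranked by summed delta-percent.
#'
#' @param enrichment an `enrichment_table` over the full member universe.
#' @param design the `library_design` the table was computed from.
#' @param patterns character vector of patterns, or `"auto"` to enumerate
#'   every single- and double-wildcard pattern.
#' @return data.frame (`pattern`, `n_wildcards`, `n_members`,
#'   `sum_delta_pct`, `mean_delta_pct`, `median_delta_pct`) sorted by
#'   descending `sum_delta_pct`. Zero-match explicit patterns are reported
#'   with `n_members = 0`.
#' @export
aggregate_families <- function(enrichment, design, patterns = "auto") {
  stopifnot(inherits(design, "library_design"), is.data.frame(enrichment))
  p <- length(design$sizes)
  idx <- member_index_matrix(design)
  ids <- member_ids(design)
  row_of <- match(enrichment$member, ids)
  if (anyNA(row_of))
    stop("enrichment table contains members absent from the design",
         call. = FALSE)
  labs <- lapply(seq_len(p), function(j)
    design$positions[[j]]$labels[idx[row_of, j]])
  dt <- data.table::as.data.table(stats::setNames(labs, paste0("L", seq_len(p))))
  dt[, delta := enrichment$delta_pct]

  summarize <- function(sub, wild) {
    keep <- setdiff(seq_len(p), wild)
    if (length(keep)) {
      agg <- sub[, .(n_members = .N, sum_delta_pct = sum(delta),
                     mean_delta_pct = mean(delta),
                     median_delta_pct = stats::median(delta)),
                 by = c(paste0("L", keep))]
    } else {
      agg <- sub[, .(n_members = .N, sum_delta_pct = sum(delta),
                     mean_delta_pct = mean(delta),
                     median_delta_pct = stats::median(delta))]
    }
    pat <- rep("", nrow(agg))
    parts <- matrix("*", nrow = nrow(agg), ncol = p)
    for (j in keep) parts[, j] <- agg[[paste0("L", j)]]
    agg$pattern <- apply(parts, 1L, paste, collapse = "")
    agg$n_wildcards <- length(wild)
    agg[, c("pattern", "n_wildcards", "n_members", "sum_delta_pct",
            "mean_delta_pct", "median_delta_pct"), with = FALSE]
  }

  if (identical(patterns, "auto")) {
    wilds <- c(lapply(seq_len(p), function(j) j),
               utils::combn(p, 2L, simplify = FALSE))
    res <- data.table::rbindlist(lapply(wilds, function(w) summarize(dt, w)))
  } else {
    rows <- lapply(patterns, function(pt) {
      pat <- split_pattern(design, pt)
      hits <- match_pattern(design, pat)
      sel <- dt$delta[hits[row_of]]
      data.table::data.table(
        pattern = paste(pat, collapse = ""),
        n_wildcards = sum(pat == "*"),
        n_members = length(sel),
        sum_delta_pct = if (length(sel)) sum(sel) else 0,
        mean_delta_pct = if (length(sel)) mean(sel) else NA_real_,
        median_delta_pct = if (length(sel)) stats::median(sel) else NA_real_)
    })
    res <- data.table::rbindlist(rows)
  }
  res <- res[order(-sum_delta_pct, pattern)]
  out <- as.data.frame(res)
  rownames(out) <- NULL
  out
}

#' Write an enrichment table and decode reports to disk
#'
#' @param enrichment an `enrichment_table`.
#' @param families optional family table from [aggregate_families()].
#' @param reports optional named list of decode reports (attribute
#'   `"report"` of [tally_counts()] output).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly. Writes `enrichment.csv`, optionally
#'   `families.csv` and `decode_report.json`.
#' @export
write_enrichment <- function(enrichment, families = NULL, reports = NULL,
                             dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(enrichment, file.path(dir, "enrichment.csv"),
                   row.names = FALSE)
  if (!is.null(families))
    utils::write.csv(families, file.path(dir, "families.csv"),
                     row.names = FALSE)
  if (!is.null(reports))
    jsonlite::write_json(reports, file.path(dir, "decode_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
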