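# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build an exact-match k-mer seed index over a transcript set
#'
#' @param transcripts Named character vector of transcript sequences
#'   (A/C/G/T/N), or a `Biostrings::DNAStringSet`.
#' @param seed_length Seed k-mer length (default 20).
#' @return Object of class `kmer_index` wrapping a keyed data.table of
#'   (kmer, tx, pos) plus the transcript sequences.
#' @export
build_kmer_index <- function(transcripts, seed_length = 20) {
  transcripts <- as_transcript_vector(transcripts)
  if (length(transcripts) == 0)
    stop("configuration error: empty transcript set")
  tabs <- lapply(names(transcripts), function(id) {
    s <- transcripts[[id]]
    n <- nchar(s) - seed_length + 1L
    if (n < 1L) return(NULL)
    data.table(kmer = substring(s, 1:n, seed_length:(nchar(s))),
               tx = id, pos = 1:n)
  })
  idx <- rbindlist(tabs)
  setkey(idx, kmer)
  structure(list(index = idx, transcripts = transcripts,
                 seed_length = seed_length),
            class = "kmer_index")
}

# Coerce DNAStringSet / list / character to a named character vector;
# errors on missing or duplicate ids.
as_transcript_vector <- function(transcripts) {
  if (inherits(transcripts, "DNAStringSet"))
    transcripts <- as.character(transcripts)
  transcripts <- unlist(as.list(transcripts))
  if (is.null(names(transcripts)) || anyNA(names(transcripts)) ||
      any(names(transcripts) == ""))
    stop("transcripts must be named")
  if (anyDuplicated(names(transcripts)))
    stop("transcript ids must be unique")
  toupper(transcripts)
}

# Best contiguous exact-match block of `read` placed on `txseq` so that read
# position 1 sits at transcript position `astart` (may be off-transcript).
# Returns NULL or list(start, span, clip5, clip3, mismatches, score).
# Kadane-style scan: matches score +1, mismatches -3; the block must contain
# >= min_block matching bases and keep its mismatch rate <= max_mm_rate.
best_block <- function(read, txseq, astart, min_block, max_mm_rate) {
  L <- nchar(read)
  txlen <- nchar(txseq)
  i0 <- max(1L, 2L - astart)                 # first read pos on transcript
  i1 <- min(L, txlen - astart + 1L)
  if (i1 - i0 + 1L < min_block) return(NULL)
  r <- utf8ToInt(substr(read, i0, i1))
  t <- utf8ToInt(substr(txseq, astart + i0 - 1L, astart + i1 - 1L))
  m <- r == t
  sc <- ifelse(m, 1, -3)
  # Kadane with position tracking
  best_s <- 0; best_a <- 0L; best_b <- -1L
  cur <- 0; cur_a <- 1L
  for (k in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[k]; cur_a <- k } else cur <- cur + sc[k]
    if (cur > best_s) { best_s <- cur; best_a <- cur_a; best_b <- k }
  }
  if (best_b < best_a) return(NULL)
  # trim mismatching ends (Kadane can keep interior mismatches only)
  while (best_a <= best_b && !m[best_a]) best_a <- best_a + 1L
  while (best_b >= best_a && !m[best_b]) best_b <- best_b - 1L
  span <- best_b - best_a + 1L
  if (span < min_block) return(NULL)
  mm <- sum(!m[best_a:best_b])
  if (mm / span > max_mm_rate) return(NULL)
  ra <- i0 + best_a - 1L                     # read coordinate of block start
  list(start = astart + ra - 1L, span = span,
       clip5 = ra - 1L, clip3 = L - (ra + span - 1L),
       mismatches = mm, score = span - 4L * mm)
}

# Map one read set (character vector, names = read ids) against a kmer_index.
# Vectorised fast path for full-length exact placements; per-candidate loop
# only for clipped/mismatched placements (junction-spanning reads).
map_read_set <- function(reads, index, max_mismatch_rate = 0.04) {
  k <- index$seed_length
  txseqs <- index$transcripts
  txlen <- nchar(txseqs)
  rlen <- nchar(reads)
  if (any(rlen < k))
    stop("read length must be >= seed_length")
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(reads))

  rc <- revcomp(reads)
  cand_list <- list()
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") reads else rc
    # seeds at the two read ends: any read with >= k contiguous bases on one
    # side of a junction is seeded by at least one of them
    for (off in list(rep(1L, length(seqs)), rlen - k + 1L)) {
      q <- data.table(ri = seq_along(seqs),
                      kmer = substring(seqs, off, off + k - 1L),
                      off = off)
      hits <- index$index[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hits)) {
        hits[, astart := pos - (off - 1L)]
        hits[, strand := strand]
        cand_list[[length(cand_list) + 1L]] <-
          hits[, list(ri, tx, astart, strand)]
      }
    }
  }
  if (length(cand_list) == 0) {
    return(data.table(read = ids, tx = NA_character_, start = NA_integer_,
                      strand = NA_character_, span = NA_integer_,
                      clip5 = NA_integer_, clip3 = NA_integer_,
                      mismatches = NA_integer_, score = NA_real_,
                      seq = reads, status = "unmapped"))
  }
  cand <- unique(rbindlist(cand_list))
  cand[, rl := rlen[ri]]
  cand[, oseq := ifelse(strand == "+", reads[ri], rc[ri])]

  # fast path: the whole read fits inside the transcript at the implied
  # offset and matches exactly
  cand[, fits := astart >= 1L & astart + rl - 1L <= txlen[tx]]
  cand[, full := FALSE]
  if (any(cand$fits)) {
    w <- which(cand$fits)
    txsub <- substring(txseqs[cand$tx[w]], cand$astart[w],
                       cand$astart[w] + cand$rl[w] - 1L)
    cand$full[w] <- txsub == cand$oseq[w]
  }
  res_full <- cand[full == TRUE,
                   list(ri, tx, start = astart, strand,
                        span = rl, clip5 = 0L, clip3 = 0L,
                        mismatches = 0L, score = as.numeric(rl), seq = oseq)]

  # slow path: remaining candidates (clipped ends / mismatches)
  rest <- cand[full == FALSE]
  min_block <- k
  res_part <- data.table(ri = integer(), tx = character(),
                         start = integer(), strand = character(),
                         span = integer(), clip5 = integer(),
                         clip3 = integer(), mismatches = integer(),
                         score = numeric(), seq = character())
  if (nrow(rest)) {
    out <- vector("list", nrow(rest))
    for (r in seq_len(nrow(rest))) {
      b <- best_block(rest$oseq[r], txseqs[[rest$tx[r]]], rest$astart[r],
                      min_block, max_mismatch_rate)
      if (!is.null(b))
        out[[r]] <- data.table(ri = rest$ri[r], tx = rest$tx[r],
                               start = b$start, strand = rest$strand[r],
                               span = b$span, clip5 = b$clip5,
                               clip3 = b$clip3, mismatches = b$mismatches,
                               score = as.numeric(b$score),
                               seq = rest$oseq[r])
    }
    out <- out[!vapply(out, is.null, TRUE)]
    if (length(out)) res_part <- rbindlist(out)
  }
  res <- rbindlist(list(res_full, res_part))
  if (nrow(res) == 0) {
    return(data.table(read = ids, tx = NA_character_, start = NA_integer_,
                      strand = NA_character_, span = NA_integer_,
                      clip5 = NA_integer_, clip3 = NA_integer_,
                      mismatches = NA_integer_, score = NA_real_,
                      seq = reads, status = "unmapped"))
  }
  res <- unique(res, by = c("ri", "tx", "start", "strand", "span"))
  # unique-best placement per read; ties -> multi-mapped (excluded later)
  setorder(res, ri, -score)
  best1 <- res[, list(tx = tx[1], start = start[1], strand = strand[1],
                      span = span[1], clip5 = clip5[1], clip3 = clip3[1],
                      mismatches = mismatches[1], score = score[1],
                      seq = seq[1],
                      status = if (.N > 1 && score[2] == score[1] &&
                                   !(tx[2] == tx[1] && start[2] == start[1]))
                        "multi" else "unique"),
               by = ri]
  mapped <- best1[, list(read = ids[ri], tx, start, strand, span, clip5,
                         clip3, mismatches, score, seq, status)]
  un <- setdiff(seq_along(reads), best1$ri)
  if (length(un)) {
    mapped <- rbindlist(list(
      mapped,
      data.table(read = ids[un], tx = NA_character_, start = NA_integer_,
                 strand = NA_character_, span = NA_integer_,
                 clip5 = NA_integer_, clip3 = NA_integer_,
                 mismatches = NA_integer_, score = NA_real_,
                 seq = reads[un], status = "unmapped")))
  }
  mapped[]
}

#' Map paired-end reads to a transcript set
#'
#' Toy-scale read mapper: exact-match seeds from the two ends of each read
#' are looked up in a k-mer index of the transcript set and extended without
#' gaps, soft-clipping read ends that do not match (so junction-spanning
#' reads map to one fusion partner with a clipped tail). Each read keeps its
#' unique best placement; reads with tied best placements on different
#' locations are flagged `"multi"` and reads with no placement `"unmapped"`.
#' Mate 2 placements are recorded after normalising both mates to the
#' transcript (sense) orientation, with `seq` holding the sense-strand bases.
#'
#' @param reads1,reads2 Character vectors of mate-1/mate-2 sequences (named
#'   by read id), as returned by [read_fastq_pair()] or
#'   [simulate_read_pairs()].
#' @param transcripts Named character vector / `DNAStringSet`, or a
#'   pre-built [build_kmer_index()] object.
#' @param seed_length Exact seed length (default 20).
#' @param max_mismatch_rate Maximum mismatch fraction inside the aligned
#'   block (default 0.04).
#' @return `data.table` with one row per mate: `pair` (read-pair id), `mate`
#'   (1/2), `read`, `tx`, `start` (1-based), `strand`, `span` (matched
#'   bases), `clip5`/`clip3` (soft-clip lengths on the aligned strand),
#'   `mismatches`, `score`, `seq` (sense-oriented), `status`
#'   (unique/multi/unmapped).
#' @export
map_reads <- function(reads1, reads2, transcripts, seed_length = 20,
                      max_mismatch_rate = 0.04) {
  index <- if (inherits(transcripts, "kmer_index")) transcripts
           else build_kmer_index(transcripts, seed_length)
  if (length(reads1) != length(reads2))
    stop("mate files carry different numbers of reads")
  pair_ids <- names(reads1)
  if (is.null(pair_ids)) pair_ids <- as.character(seq_along(reads1))
  names(reads1) <- names(reads2) <- pair_ids
  a1 <- map_read_set(reads1, index, max_mismatch_rate)
  a2 <- map_read_set(reads2, index, max_mismatch_rate)
  a1[, `:=`(pair = read, mate = 1L)]
  a2[, `:=`(pair = read, mate = 2L)]
  aln <- rbindlist(list(a1, a2))
  setorder(aln, pair, mate)
  data.table::setcolorder(aln, c("pair", "mate"))
  aln[]
}

#' Count discordant (chimeric) read pairs per transcript pair
#'
#' A chimeric pair has its two mates mapped uniquely to two *different*
#' transcripts — the read-level evidence for a fusion transcript. Pairs with
#' either mate unmapped or multi-mapped are excluded from the counts but
#' tallied separately.
#'
#' @param alignments Alignment table from [map_reads()].
#' @return Object of class `chimeric_pair_table`: list with `counts`
#'   (data.table `tx_a`, `tx_b`, `n`, sorted by `n` descending, unordered
#'   pair with `tx_a < tx_b`), `n_excluded_unmapped`, `n_excluded_multi`.
#' @export
find_chimeric_pairs <- function(alignments) {
  stopifnot(all(c("pair", "mate", "tx", "status") %in% names(alignments)))
  aln <- data.table::as.data.table(alignments)
  wide <- aln[mate <= 2L,
              list(tx1 = tx[mate == 1L][1], s1 = status[mate == 1L][1],
                   tx2 = tx[mate == 2L][1], s2 = status[mate == 2L][1]),
              by = pair]
  n_unmapped <- wide[s1 == "unmapped" | s2 == "unmapped", .N]
  n_multi <- wide[(s1 == "multi" | s2 == "multi") &
                    s1 != "unmapped" & s2 != "unmapped", .N]
  chim <- wide[s1 == "unique" & s2 == "unique" & tx1 != tx2]
  if (nrow(chim)) {
    chim[, `:=`(tx_a = pmin(tx1, tx2), tx_b = pmax(tx1, tx2))]
    counts <- chim[, list(n = .N), by = list(tx_a, tx_b)]
    setorder(counts, -n)
  } else {
    counts <- data.table(tx_a = character(), tx_b = character(),
                         n = integer())
  }
  structure(list(counts = counts,
                 n_excluded_unmapped = n_unmapped,
                 n_excluded_multi = n_multi),
            class = "chimeric_pair_table")
}

#' @export
print.chimeric_pair_table <- function(x, ...) {
  cat(sprintf("<chimeric_pair_table> %d transcript pair(s); excluded: %d unmapped, %d multi\n",
              nrow(x$counts), x$n_excluded_unmapped, x$n_excluded_multi))
  if (nrow(x$counts)) print(utils::head(x$counts, 5))
  invisible(x)
}
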