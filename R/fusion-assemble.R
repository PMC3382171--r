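#' De novo assembly of junction-supporting reads into contigs
#'
#' Minimal de Bruijn assembler for the handful of reads supporting one
#' candidate fusion: reads are decomposed into k-mers, and maximal
#' unambiguous paths of the k-mer graph (every node entered and left by a
#' single edge) are emitted as contigs. On error-free reads tiling a
#' junction region the longest contig reconstructs the region, with at
#' least k bases on each side of the junction.
#'
#' @param reads Character vector of (sense-oriented) read sequences, >= 2.
#' @param k Odd k-mer size, smaller than the read length (default 31).
#' @return Object of class `assembly_result`: list with `contigs` (character
#'   vector sorted by decreasing length), `k`, and `status` (`"ok"`, or
#'   `"assembly_failed"` when no contig reaches 2k bases — distinguishable
#'   from a no-fusion outcome).
#' @export
assemble_junction <- function(reads, k = 31) {
  reads <- toupper(as.character(reads))
  if (length(reads) < 2L)
    stop("need at least 2 reads to assemble")
  if (k %% 2 == 0 || k < 3)
    stop("'k' must be an odd integer >= 3")
  if (k >= min(nchar(reads)))
    stop("'k' must be smaller than the read length")
  km <- unlist(lapply(reads, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, 1:n, k:(k + n - 1L))
  }), use.names = FALSE)
  U <- unique(km)
  nU <- length(U)
  bases <- c("A", "C", "G", "T")
  suf <- substring(U, 2L, k)
  pre <- substring(U, 1L, k - 1L)
  # successor/predecessor ids per extension base; NA when absent
  succ <- matrix(NA_integer_, nU, 4)
  pred <- matrix(NA_integer_, nU, 4)
  for (b in 1:4) {
    succ[, b] <- match(paste0(suf, bases[b]), U)
    pred[, b] <- match(paste0(bases[b], pre), U)
  }
  outdeg <- rowSums(!is.na(succ))
  indeg <- rowSums(!is.na(pred))
  succ1 <- ifelse(outdeg == 1L, succ[cbind(1:nU, max.col(!is.na(succ)))],
                  NA_integer_)
  pred1 <- ifelse(indeg == 1L, pred[cbind(1:nU, max.col(!is.na(pred)))],
                  NA_integer_)
  is_start <- indeg != 1L | (indeg == 1L & outdeg[pred1] != 1L)
  is_start[is.na(is_start)] <- TRUE
  visited <- logical(nU)
  contigs <- character()
  walk <- function(v) {
    path <- v
    visited[v] <<- TRUE
    while (!is.na(succ1[v])) {
      nxt <- succ1[v]
      if (indeg[nxt] != 1L || visited[nxt]) break
      visited[nxt] <<- TRUE
      path <- c(path, nxt)
      v <- nxt
    }
    paste0(U[path[1]],
           paste(substring(U[path[-1]], k, k), collapse = ""))
  }
  for (v in which(is_start)) {
    if (!visited[v]) contigs <- c(contigs, walk(v))
  }
  # leftover nodes belong to cycles; unwind each once
  for (v in seq_len(nU)) {
    if (!visited[v]) contigs <- c(contigs, walk(v))
  }
  contigs <- contigs[order(-nchar(contigs))]
  status <- if (length(contigs) == 0 || max(nchar(contigs)) < 2L * k)
    "assembly_failed" else "ok"
  structure(list(contigs = contigs, k = k, status = status),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly_result> %s: %d contig(s), longest %d bp (k = %d)\n",
              x$status, length(x$contigs),
              if (length(x$contigs)) max(nchar(x$contigs)) else 0L, x$k))
  invisible(x)
}

# Largest s such that substr(contig, 1, s) occurs in txseq (0 if none).
# Substring containment is monotone in s, so binary search applies.
.max_prefix_in <- function(contig, txseq) {
  L <- nchar(contig)
  occurs <- function(s) {
    grepl(substr(contig, 1L, s), txseq, fixed = TRUE)
  }
  if (!occurs(1L)) return(0L)
  lo <- 1L; hi <- L
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (occurs(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Localize a fusion junction within an assembled contig
#'
#' Finds the split of the contig into a prefix exactly contained in the 5'
#' partner transcript and a suffix exactly contained in the 3' partner,
#' maximizing the total matched length, with each side required to anchor at
#' least `min_anchor` bases. When junction-flanking bases are shared by both
#' partners the split can slide without changing the fusion sequence; the
#' 5'-most split is reported together with the `homology_interval` (number
#' of alternative equivalent splits). Coordinates follow the transcript
#' (sense) strand, 1-based inclusive: `J5` is the last retained base of the
#' 5' partner and `J3` the first retained base of the 3' partner.
#'
#' @param contig Assembled contig sequence (length >= 2 * `min_anchor`).
#' @param tx5,tx3 Sequences of the candidate 5' and 3' partner transcripts.
#' @param min_anchor Minimum exactly-matching bases required on each side of
#'   the split (default 25).
#' @param five_prime_tx,three_prime_tx Optional ids recorded in the call.
#' @return Object of class `fusion_call` (or `NULL`-like no-call with
#'   `status = "no_call"`): list with `five_prime_tx`, `J5`, `three_prime_tx`,
#'   `J3`, `contig`, `homology_interval`, `supporting_pairs`,
#'   `spanning_reads` (the last two filled by [detect_fusion()]), `status`.
#' @export
locate_junction <- function(contig, tx5, tx3, min_anchor = 25,
                            five_prime_tx = "tx5", three_prime_tx = "tx3") {
  contig <- toupper(contig); tx5 <- toupper(tx5); tx3 <- toupper(tx3)
  L <- nchar(contig)
  if (L < 2 * min_anchor)
    stop("contig shorter than twice the anchor requirement")
  pmax_ <- .max_prefix_in(contig, tx5)
  rev_ <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  # smallest j with substr(contig, j, L) in tx3 == reversed-prefix search
  smax_rev <- .max_prefix_in(rev_(contig), rev_(tx3))
  smin <- L - smax_rev + 1L
  lo <- max(smin - 1L, min_anchor)
  hi <- min(pmax_, L - min_anchor)
  gap <- 0L
  if (lo <= hi) {
    s <- lo  # 5'-most split among the equivalent (homologous) ones
  } else if (pmax_ >= min_anchor && L - smin + 1L >= min_anchor &&
             smin - 1L > pmax_) {
    # prefix and suffix matches do not meet: best total match length is
    # pmax_ + (L - smin + 1) with unmatched middle bases in between
    s <- pmax_
    hi <- lo <- s
    gap <- smin - 1L - pmax_
  } else {
    return(structure(list(status = "no_call",
                          reason = "no split meets both anchors"),
                     class = "fusion_call"))
  }
  prefix <- substr(contig, 1L, s)
  suffix <- substr(contig, max(s + 1L, smin), L)
  p5 <- regexpr(prefix, tx5, fixed = TRUE)[1]
  p3 <- regexpr(suffix, tx3, fixed = TRUE)[1]
  structure(list(
    five_prime_tx = five_prime_tx,
    J5 = p5 + s - 1L,
    three_prime_tx = three_prime_tx,
    J3 = as.integer(p3),
    contig = contig,
    split = s,
    gap = gap,
    homology_interval = hi - lo,
    supporting_pairs = NA_integer_,
    spanning_reads = NA_integer_,
    status = "ok"
  ), class = "fusion_call")
}

#' @export
print.fusion_call <- function(x, ...) {
  if (!identical(x$status, "ok")) {
    cat(sprintf("<fusion_call> %s (%s)\n", x$status,
                if (!is.null(x$reason)) x$reason else ""))
    return(invisible(x))
  }
  cat(sprintf("<fusion_call> %s:1-%d | %s:%d-end (homology %d, %s pairs, %s spanning)\n",
              x$five_prime_tx, x$J5, x$three_prime_tx, x$J3,
              x$homology_interval,
              ifelse(is.na(x$supporting_pairs), "?", x$supporting_pairs),
              ifelse(is.na(x$spanning_reads), "?", x$spanning_reads)))
  invisible(x)
}
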