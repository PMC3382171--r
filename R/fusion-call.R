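#' End-to-end fusion-transcript detection from paired reads
#'
#' Runs the full fusion workflow: map read pairs to the (wild-type)
#' transcript set, count discordant pairs per transcript pair, take the
#' top-ranked pair, pool its supporting reads (both mates of every chimeric
#' pair plus soft-clipped reads on the two transcripts, all in sense
#' orientation), assemble them into contigs and localize the junction. Both
#' orderings of the candidate pair are tried as (5', 3') partner and the
#' valid call is kept. `supporting_pairs` is the chimeric-pair count and
#' `spanning_reads` the number of clipped alignments whose clip boundary
#' falls at the called junction.
#'
#' @param reads1,reads2 Mate sequences (named character vectors) or `NULL`
#'   when `alignments` is given.
#' @param transcripts Named character vector / `DNAStringSet` of reference
#'   transcripts (the wild-type set, without the fusion).
#' @param alignments Optional pre-computed alignment table ([map_reads()] or
#'   [read_minimal_sam()]); when supplied, `reads1`/`reads2` are ignored.
#' @param min_support Minimum chimeric pairs for a candidate (default 2).
#' @param k Assembly k-mer size (default 31).
#' @param min_anchor Minimum split anchor (default 25).
#' @param min_clip Minimum soft-clip length for a read to join the assembly
#'   pool and to count as junction-spanning (default 10).
#' @return A `fusion_call` (status `"ok"`), or a no-call result with
#'   `status` `"no_fusion"` (no candidate pair with enough support) or
#'   `"assembly_failed"` / `"no_call"` from the downstream stages.
#' @export
detect_fusion <- function(reads1 = NULL, reads2 = NULL, transcripts,
                          alignments = NULL, min_support = 2,
                          k = 31, min_anchor = 25, min_clip = 10) {
  transcripts <- as_transcript_vector(transcripts)
  if (is.null(alignments)) {
    if (is.null(reads1) || is.null(reads2))
      stop("supply either reads1/reads2 or a pre-computed alignment table")
    alignments <- map_reads(reads1, reads2, transcripts)
  }
  chim <- find_chimeric_pairs(alignments)
  if (nrow(chim$counts) == 0 || chim$counts$n[1] < min_support) {
    return(structure(list(status = "no_fusion",
                          reason = "no transcript pair with sufficient chimeric support",
                          chimeric = chim),
                     class = "fusion_call"))
  }
  txa <- chim$counts$tx_a[1]
  txb <- chim$counts$tx_b[1]
  support <- chim$counts$n[1]
  aln <- data.table::as.data.table(alignments)
  pair_ids <- aln[status == "unique" & tx %in% c(txa, txb),
                  list(both = length(unique(tx)) == 2L), by = pair][both == TRUE, pair]
  pool <- aln[status == "unique" &
                ((pair %in% pair_ids & tx %in% c(txa, txb)) |
                   (tx %in% c(txa, txb) & (clip5 >= min_clip | clip3 >= min_clip))),
              ]
  if (nrow(pool) < 2L) {
    return(structure(list(status = "assembly_failed",
                          reason = "fewer than 2 supporting reads",
                          chimeric = chim),
                     class = "fusion_call"))
  }
  asm <- assemble_junction(pool$seq, k = k)
  if (asm$status != "ok") {
    return(structure(list(status = "assembly_failed",
                          reason = "no contig of at least 2k bases",
                          chimeric = chim),
                     class = "fusion_call"))
  }
  call <- NULL
  for (contig in asm$contigs[nchar(asm$contigs) >= 2 * min_anchor]) {
    for (ord in list(c(txa, txb), c(txb, txa))) {
      cand <- locate_junction(contig, transcripts[[ord[1]]],
                              transcripts[[ord[2]]], min_anchor = min_anchor,
                              five_prime_tx = ord[1], three_prime_tx = ord[2])
      if (identical(cand$status, "ok") &&
          (is.null(call) || nchar(cand$contig) > nchar(call$contig)))
        call <- cand
    }
    if (!is.null(call)) break  # contigs are length-sorted
  }
  if (is.null(call)) {
    return(structure(list(status = "no_call",
                          reason = "no contig localized to a junction",
                          chimeric = chim, assembly = asm),
                     class = "fusion_call"))
  }
  call$supporting_pairs <- support
  spanning <- aln[status == "unique" &
                    ((tx == call$five_prime_tx &
                        start + span - 1L == call$J5 & clip3 >= min_clip) |
                       (tx == call$three_prime_tx &
                          start == call$J3 & clip5 >= min_clip)), .N]
  call$spanning_reads <- spanning
  call$chimeric <- chim
  call
}

#' Per-base RBM coverage profile of one transcript
#'
#' Piles up the matched spans of all uniquely mapped reads on a transcript
#' and normalizes to RBM — reads per base per million reads: per-base
#' coverage times 1e6 divided by the total number of reads in the library
#' (mapped or not), so profiles are comparable across libraries of
#' different depth.
#'
#' @param alignments Alignment table ([map_reads()] / [read_minimal_sam()]).
#' @param transcript Transcript id to profile.
#' @param transcript_length Length of the transcript in bases.
#' @param library_size Total number of reads in the library.
#' @return Object of class `rbm_profile`: list with `transcript`, `coverage`
#'   (integer per-base counts), `rbm` (numeric), `library_size`.
#' @export
compute_rbm <- function(alignments, transcript, transcript_length,
                        library_size) {
  if (!is.numeric(library_size) || library_size <= 0)
    stop("'library_size' must be positive")
  aln <- data.table::as.data.table(alignments)
  hits <- aln[status == "unique" & tx == transcript]
  cov <- integer(transcript_length)
  if (nrow(hits)) {
    # difference-array pileup: +1 at span start, -1 after span end
    d <- integer(transcript_length + 1L)
    s <- pmax(hits$start, 1L)
    e <- pmin(hits$start + hits$span - 1L, transcript_length)
    keep <- s <= e
    add <- tabulate(s[keep], nbins = transcript_length)
    rem <- tabulate(e[keep] + 1L, nbins = transcript_length + 1L)
    cov <- cumsum(add - rem[seq_len(transcript_length)])
  }
  structure(list(transcript = transcript, coverage = as.integer(cov),
                 rbm = cov * 1e6 / library_size,
                 library_size = library_size),
            class = "rbm_profile")
}

#' @export
print.rbm_profile <- function(x, ...) {
  cat(sprintf("<rbm_profile> %s: %d bases, mean RBM %.3g (library %g reads)\n",
              x$transcript, length(x$rbm), mean(x$rbm), x$library_size))
  invisible(x)
}

#' Coverage fold between two RBM profiles over a region
#'
#' Ratio of mean RBM over a 1-based inclusive interval, with a pseudocount
#' guarding against empty regions:
#' `(mean(rbm_a) + pseudocount) / (mean(rbm_b) + pseudocount)`.
#'
#' @param profile_a,profile_b `rbm_profile` objects on the same transcript.
#' @param region Length-2 integer vector, 1-based inclusive interval.
#' @param pseudocount RBM units added to both means (default 0.1).
#' @return Fold ratio (numeric scalar).
#' @export
region_fold <- function(profile_a, profile_b, region, pseudocount = 0.1) {
  stopifnot(length(region) == 2L)
  region <- as.integer(region)
  if (region[1] < 1L || region[2] > length(profile_a$rbm) ||
      region[2] > length(profile_b$rbm) || region[1] > region[2])
    stop("invalid region: must be a non-empty interval within both profiles")
  idx <- region[1]:region[2]
  (mean(profile_a$rbm[idx]) + pseudocount) /
    (mean(profile_b$rbm[idx]) + pseudocount)
}

#' Map a fusion junction onto the fusion open reading frame
#'
#' Given the junction coordinates and the coding-region annotation of both
#' partners, determines whether the junction preserves the reading frame
#' (the retained 5' coding bases and the skipped 5'-UTR+coding bases of the
#' 3' partner must both be whole codons) and, when in frame, the amino-acid
#' ranges contributed by each partner: residues `1..(J5 - cds_start5 + 1)/3`
#' of the 5' protein and residues `(J3 - cds_start3)/3 + 1` through the end
#' of the 3' protein.
#'
#' @param call A `fusion_call` (or any list with `J5`, `J3`).
#' @param cds_start5,cds_start3 1-based first coding base of each partner.
#' @param cds_end3 Last base of the final sense codon of the 3' partner
#'   (stop codon excluded), defining the annotated protein end.
#' @return Object of class `fusion_orf`: list with `in_frame`,
#'   `five_prime_aa` (c(start, end) or NULL), `three_prime_aa`,
#'   `protein_length`, `status` (`"ok"`, `"out_of_frame"`, or
#'   `"junction_in_utr"` when `J5 < cds_start5`).
#' @export
fusion_orf <- function(call, cds_start5, cds_start3, cds_end3) {
  J5 <- call$J5; J3 <- call$J3
  stopifnot(is.numeric(J5), is.numeric(J3),
            is.numeric(cds_start5), is.numeric(cds_start3),
            is.numeric(cds_end3))
  if (J5 < cds_start5) {
    return(structure(list(in_frame = NA, five_prime_aa = NULL,
                          three_prime_aa = NULL, protein_length = NA_integer_,
                          status = "junction_in_utr"),
                     class = "fusion_orf"))
  }
  in_frame <- (J5 - cds_start5 + 1) %% 3 == 0 && (J3 - cds_start3) %% 3 == 0
  if (!in_frame) {
    return(structure(list(in_frame = FALSE, five_prime_aa = NULL,
                          three_prime_aa = NULL, protein_length = NA_integer_,
                          status = "out_of_frame"),
                     class = "fusion_orf"))
  }
  aa5_end <- (J5 - cds_start5 + 1) / 3
  aa3_start <- (J3 - cds_start3) / 3 + 1
  aa3_end <- (cds_end3 - cds_start3 + 1) / 3
  structure(list(in_frame = TRUE,
                 five_prime_aa = c(1, aa5_end),
                 three_prime_aa = c(aa3_start, aa3_end),
                 protein_length = aa5_end + (aa3_end - aa3_start + 1),
                 status = "ok"),
            class = "fusion_orf")
}

#' @export
print.fusion_orf <- function(x, ...) {
  if (!identical(x$status, "ok")) {
    cat(sprintf("<fusion_orf> %s\n", x$status))
  } else {
    cat(sprintf("<fusion_orf> in frame: 5' aa %d-%d + 3' aa %d-%d (%d residues)\n",
                x$five_prime_aa[1], x$five_prime_aa[2],
                x$three_prime_aa[1], x$three_prime_aa[2],
                x$protein_length))
  }
  invisible(x)
}
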