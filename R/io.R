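#' Read / write FASTA transcript sets
#'
#' Thin wrappers over Biostrings keeping the package's named-character
#' representation of a transcript set.
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  as_transcript_vector(Biostrings::readDNAStringSet(path))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write paired FASTQ files
#'
#' Reads (or writes) the two mate files of a paired-end library. Written
#' qualities are uniform placeholders (the simulators do not model base
#' quality).
#'
#' @param path1,path2 Mate-1 and mate-2 FASTQ paths.
#' @return `read_fastq_pair()` returns `list(reads1, reads2)` of named
#'   character vectors; an error is raised if the mate counts differ.
#' @export
read_fastq_pair <- function(path1, path2) {
  rd <- function(p) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    out <- as.character(x)
    names(out) <- sub("[/ ].*$", "", names(x))
    out
  }
  r1 <- rd(path1); r2 <- rd(path2)
  if (length(r1) != length(r2))
    stop("mate files carry different numbers of reads")
  list(reads1 = r1, reads2 = r2)
}

#' @rdname read_fastq_pair
#' @param reads1,reads2 Named character vectors of mate sequences.
#' @export
write_fastq_pair <- function(reads1, reads2, path1, path2) {
  wr <- function(reads, mate, path) {
    x <- Biostrings::DNAStringSet(unlist(as.list(reads)))
    names(x) <- paste0(names(reads), "/", mate)
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
    invisible(NULL)
  }
  wr(reads1, 1, path1)
  wr(reads2, 2, path2)
  invisible(c(path1, path2))
}

#' Read / write the minimal SAM dialect
#'
#' The package exchanges alignments in a restricted SAM text dialect:
#' `@SQ` header lines (`SN:`/`LN:` tags) followed by records with columns
#' `QNAME FLAG RNAME POS MAPQ CIGAR`, where the CIGAR may contain only `M`
#' (match span) and `S` (soft clip) operations. FLAG bits used: 0x1 paired,
#' 0x10 reverse strand, 0x40/0x80 first/second mate, 0x4 unmapped.
#'
#' @param path SAM file path.
#' @return `read_minimal_sam()` returns a list with `alignments` (a
#'   `data.table` in the [map_reads()] layout, without `seq`) and
#'   `sequences` (named lengths from the `@SQ` header).
#' @export
read_minimal_sam <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ", lines)]
  sn <- sub(".*SN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*LN:([0-9]+).*", "\\1", sq))
  names(ln) <- sn
  recs <- lines[!hdr & nzchar(lines)]
  rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    f <- strsplit(recs[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6)
      stop(sprintf("%s line %d: expected 6 columns (QNAME FLAG RNAME POS MAPQ CIGAR), got %d",
                   path, which(!hdr & nzchar(lines))[i], length(f)))
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag))
      stop(sprintf("%s line %d: FLAG field '%s' is not an integer",
                   path, i, f[2]))
    mate <- if (bitwAnd(flag, 0x80L) > 0L) 2L else 1L
    unmapped <- bitwAnd(flag, 0x4L) > 0L
    if (unmapped) {
      rows[[i]] <- data.table::data.table(
        pair = f[1], mate = mate, read = f[1], tx = NA_character_,
        start = NA_integer_, strand = NA_character_, span = NA_integer_,
        clip5 = NA_integer_, clip3 = NA_integer_,
        mismatches = NA_integer_, score = NA_real_,
        status = "unmapped")
      next
    }
    ops <- regmatches(f[6], gregexpr("[0-9]+[A-Z=]", f[6]))[[1]]
    opc <- substring(ops, nchar(ops))
    opl <- as.integer(substring(ops, 1, nchar(ops) - 1L))
    bad <- setdiff(opc, c("M", "S"))
    if (length(bad))
      stop(sprintf("%s line %d: unsupported CIGAR operation '%s' (dialect allows M and S only)",
                   path, i, bad[1]))
    m <- opc == "M"
    clip5 <- if (!m[1]) opl[1] else 0L
    clip3 <- if (!m[length(m)]) opl[length(m)] else 0L
    rows[[i]] <- data.table::data.table(
      pair = f[1], mate = mate, read = f[1], tx = f[3],
      start = as.integer(f[4]),
      strand = if (bitwAnd(flag, 0x10L) > 0L) "-" else "+",
      span = sum(opl[m]),
      clip5 = clip5, clip3 = clip3,
      mismatches = NA_integer_, score = as.numeric(f[5]),
      status = "unique")
  }
  aln <- data.table::rbindlist(rows)
  list(alignments = aln, sequences = ln)
}

#' @rdname read_minimal_sam
#' @param alignments Alignment table ([map_reads()] layout).
#' @param seq_lengths Named integer vector of transcript lengths for the
#'   `@SQ` header.
#' @export
write_minimal_sam <- function(alignments, seq_lengths, path) {
  aln <- data.table::as.data.table(alignments)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)))
  flag_base <- 0x1L
  flag <- flag_base +
    ifelse(aln$mate == 2L, 0x80L, 0x40L) +
    ifelse(!is.na(aln$strand) & aln$strand == "-", 0x10L, 0L) +
    ifelse(aln$status == "unmapped" | is.na(aln$tx), 0x4L, 0L)
  cigar <- ifelse(is.na(aln$tx), "*",
                  paste0(ifelse(aln$clip5 > 0, paste0(aln$clip5, "S"), ""),
                         aln$span, "M",
                         ifelse(aln$clip3 > 0, paste0(aln$clip3, "S"), "")))
  recs <- paste(aln$pair, flag,
                ifelse(is.na(aln$tx), "*", aln$tx),
                ifelse(is.na(aln$start), 0L, aln$start),
                ifelse(aln$status == "unique", 60L, 0L),
                cigar, sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a viability-plate CSV
#'
#' Expected columns: `well`, `drug`, `dose_molar`, `count`, `role` with
#' `role` in treated/untreated/baseline; `dose_molar` may be empty only for
#' non-treated roles.
#'
#' @param path CSV path.
#' @return A `plate_readout` object (see [simulate_plate()]).
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "drug", "dose_molar", "count", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("plate CSV %s is missing required column(s): %s (required: %s)",
                 path, paste(miss, collapse = ", "),
                 paste(need, collapse = ", ")))
  if (!all(df$role %in% c("treated", "untreated", "baseline")))
    stop("plate CSV: 'role' must be one of treated, untreated, baseline")
  if (any(df$role == "treated" & !is.finite(df$dose_molar)))
    stop("plate CSV: treated wells must carry a numeric dose_molar")
  if (any(df$count < 0, na.rm = TRUE))
    stop("plate CSV: raw counts must be >= 0")
  structure(list(wells = df,
                 baseline_wells = df$count[df$role == "baseline"],
                 untreated_wells = df$count[df$role == "untreated"],
                 truth = NULL),
            class = "plate_readout")
}

#' @rdname read_plate_csv
#' @param plate A `plate_readout`.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate$wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a copy-number probe TSV
#'
#' Expected columns: `chrom`, `pos`, `log2_ratio`; positions must increase
#' strictly within each chromosome.
#'
#' @param path TSV path.
#' @return `data.frame` probe track for [segment_track()].
#' @export
read_probe_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "log2_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("probe TSV %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  for (ch in unique(df$chrom))
    if (is.unsorted(df$pos[df$chrom == ch], strictly = TRUE))
      stop(sprintf("probe TSV %s: positions on %s are not strictly increasing",
                   path, ch))
  df
}

#' Read gene models from an exon-per-row TSV
#'
#' Expected columns: `gene_id`, `chrom`, `strand`, `exon_start`, `exon_end`
#' (1-based inclusive). Rows are grouped into one gene model per `gene_id`.
#'
#' @param path TSV path.
#' @return List of gene models for [bisected_genes()].
#' @export
read_gene_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "exon_start", "exon_end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("gene TSV %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  lapply(split(df, df$gene_id), function(g)
    list(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
         exons = data.frame(start = g$exon_start, end = g$exon_end)))
}

#' Read a combination-matrix CSV
#'
#' Expected columns: `dose_a_molar`, `dose_b_molar`, `tgi`, covering a full
#' dose grid including the zero-dose single-agent edges.
#'
#' @param path CSV path.
#' @return List with `observed` (matrix), `doses_a`, `doses_b` ready for
#'   [delta_bliss_surface()].
#' @export
read_combo_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose_a_molar", "dose_b_molar", "tgi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("combination CSV %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  da <- sort(unique(df$dose_a_molar))
  db <- sort(unique(df$dose_b_molar))
  obs <- matrix(NA_real_, length(da), length(db))
  obs[cbind(match(df$dose_a_molar, da), match(df$dose_b_molar, db))] <- df$tgi
  if (any(is.na(obs)))
    stop(sprintf("combination CSV %s does not cover the full dose grid", path))
  list(observed = obs, doses_a = da, doses_b = db)
}

#' @rdname read_combo_csv
#' @param surface A `combination_surface`.
#' @export
write_surface_tsv <- function(surface, path) {
  grid <- expand.grid(dose_a_molar = surface$doses_a,
                      dose_b_molar = surface$doses_b)
  grid$observed <- as.vector(surface$observed)
  grid$expected <- as.vector(surface$expected)
  grid$delta <- as.vector(surface$delta)
  grid$excess <- as.vector(surface$excess)
  utils::write.table(grid, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param report Named list of results.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write per-base RBM values as TSV
#'
#' @param profile An `rbm_profile`.
#' @param path Output path.
#' @export
write_rbm_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(transcript = profile$transcript,
               pos = seq_along(profile$rbm), rbm = profile$rbm),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
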