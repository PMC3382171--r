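# Shared fixtures, built in code at test time.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 4PL truth constructors
pl4 <- function(lower = 0, upper = 1, ic50 = 10e-9, hill = 1) {
  list(lower = lower, upper = upper, ic50 = ic50, hill = hill)
}
flat_4pl <- function() pl4(0, 0, 1e-9, 1)
full_4pl <- function() pl4(1, 1, 1e-9, 1)

# Canonical study transcript architecture, cached per session
.arch_cache <- new.env(parent = emptyenv())
arch_fixture <- function() {
  if (is.null(.arch_cache$arch))
    .arch_cache$arch <- fusion_study_transcripts(seed = 7)
  .arch_cache$arch
}

# Parental abundances and calibrated fusion abundance for a 20-fold
# 3'-partner region excess
study_abundances <- function(fold = 20) {
  arch <- arch_fixture()
  lens <- nchar(c(arch$transcripts, fusion = arch$fusion))
  parental <- c(SND1like = 1, BRAFlike = 1, background = 40)
  fusion <- calibrate_fusion_abundance(fold, parental, lens[names(parental)],
                                       "BRAFlike", lens[["fusion"]])
  list(parental = parental,
       resistant = c(parental, fusion = fusion))
}

# Exhaustive split-point oracle for junction localization: evaluates every
# split of the contig and applies the 5'-most tie rule.
oracle_locate <- function(contig, tx5, tx3, min_anchor = 25) {
  L <- nchar(contig)
  ss <- min_anchor:(L - min_anchor)
  valid <- vapply(ss, function(s)
    grepl(substr(contig, 1, s), tx5, fixed = TRUE) &&
      grepl(substr(contig, s + 1, L), tx3, fixed = TRUE), TRUE)
  if (!any(valid)) return(NULL)
  s <- min(ss[valid])
  p5 <- regexpr(substr(contig, 1, s), tx5, fixed = TRUE)[1]
  p3 <- regexpr(substr(contig, s + 1, L), tx3, fixed = TRUE)[1]
  list(split = s, homology = max(ss[valid]) - s,
       J5 = p5 + s - 1L, J3 = as.integer(p3))
}

# Bookkeeping oracle for chimeric-pair counting on a fusion library mapped
# against the wild-type set: assigns each mate of a fusion fragment to the
# partner holding the larger part of the read, and counts pairs whose mates
# land on different partners. Fragments from wild-type transcripts are
# always concordant.
oracle_chimeric_count <- function(truth, J5, read_len = 75) {
  fr <- truth$fragments[truth$fragments$tx == "fusion", , drop = FALSE]
  if (nrow(fr) == 0) return(0L)
  side <- function(s) {
    # bases of a read starting at fusion coordinate s on the 5' side
    n5 <- pmin(pmax(J5 - s + 1L, 0L), read_len)
    ifelse(n5 > read_len - n5, "five", "three")
  }
  s1 <- fr$start
  s2 <- fr$start + fr$insert - read_len
  sum(side(s1) != side(s2))
}
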