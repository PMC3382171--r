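# Multiplicative lognormal noise factors with unit mean and given CV.
.lognorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Simulate a viability-plate readout from a known dose-response truth
#'
#' Draws raw luminescence-style counts for a dilution ladder under a known
#' four-parameter logistic truth: the expected treated count at dose `d` is
#' `baseline_mean + (untreated_mean - baseline_mean) * (1 - TGI(d))`, and
#' every well (treated, endpoint-untreated and day-1 baseline) is multiplied
#' by lognormal noise with coefficient of variation `noise_cv` (unit mean;
#' `noise_cv = 0` is exactly deterministic, so `compute_tgi()` returns the
#' generating curve).
#'
#' @param truth List with `lower`, `upper`, `ic50`, `hill` (the generating
#'   4PL parameters).
#' @param ladder Doses (molar), e.g. [build_dilution_ladder()].
#' @param noise_cv Coefficient of variation of well noise (default 0.05).
#' @param baseline_mean,untreated_mean Expected day-1 and endpoint untreated
#'   counts (`untreated_mean > baseline_mean`).
#' @param replicates Treated wells per dose (default 3).
#' @param n_control Baseline and untreated wells each (default 8).
#' @param seed Optional RNG seed.
#' @return Object of class `plate_readout`: list with `wells` (data.frame
#'   `well`, `drug`, `dose_molar`, `count`, `role`), `baseline_wells`,
#'   `untreated_wells`, and `truth`.
#' @export
simulate_plate <- function(truth, ladder, noise_cv = 0.05,
                           baseline_mean = 1000, untreated_mean = 9000,
                           replicates = 3, n_control = 8, seed = NULL,
                           drug = "drugA") {
  if (!is.numeric(baseline_mean) || !is.numeric(untreated_mean) ||
      untreated_mean <= baseline_mean || baseline_mean < 0)
    stop("configuration error: need untreated_mean > baseline_mean >= 0")
  if (!is.null(seed)) set.seed(seed)
  doses <- rep(as.numeric(ladder), each = replicates)
  tgi <- truth$lower + (truth$upper - truth$lower) /
    (1 + (truth$ic50 / doses)^truth$hill)
  expected <- baseline_mean + (untreated_mean - baseline_mean) * (1 - tgi)
  treated <- pmax(expected * .lognorm_factor(length(doses), noise_cv), 0)
  baseline <- baseline_mean * .lognorm_factor(n_control, noise_cv)
  untreated <- untreated_mean * .lognorm_factor(n_control, noise_cv)
  wells <- data.frame(
    well = c(sprintf("T%02d", seq_along(doses)),
             sprintf("U%02d", seq_len(n_control)),
             sprintf("B%02d", seq_len(n_control))),
    drug = c(rep(drug, length(doses)), rep(NA_character_, 2 * n_control)),
    dose_molar = c(doses, rep(NA_real_, 2 * n_control)),
    count = c(treated, untreated, baseline),
    role = c(rep("treated", length(doses)), rep("untreated", n_control),
             rep("baseline", n_control)),
    stringsAsFactors = FALSE
  )
  structure(list(wells = wells, baseline_wells = baseline,
                 untreated_wells = untreated, truth = truth),
            class = "plate_readout")
}

#' Plate readout to per-dose TGI values
#'
#' Convenience wrapper: computes TGI for every treated well of a plate and
#' averages replicates per (drug, dose).
#'
#' @param plate A `plate_readout`.
#' @return `data.frame` with `drug`, `dose_molar`, `tgi` (replicate mean).
#' @export
plate_tgi <- function(plate) {
  tr <- plate$wells[plate$wells$role == "treated", , drop = FALSE]
  tr$tgi <- compute_tgi(tr$count, plate)
  agg <- stats::aggregate(tgi ~ drug + dose_molar, data = tr, FUN = mean)
  agg[order(agg$drug, -agg$dose_molar), ]
}

#' Simulate an observed TGI matrix for a drug-combination checkerboard
#'
#' Generates the observed inhibition surface of a two-drug dose matrix under
#' one of three interaction models, with the zero-dose single-agent edges
#' always present:
#' \describe{
#'   \item{`bliss`}{exact Bliss additivity, `A + B - AB`.}
#'   \item{`rescue`}{single agents follow `params_a`/`params_b` (typically
#'     flat for a resistant line); wherever both doses exceed the
#'     `gate_a`/`gate_b` thresholds the combination instead follows
#'     `rescue_params` evaluated on drug A's dose — emulating a resistant
#'     clone killed only by the combination.}
#'   \item{`antagonism`}{`max(A, B) * 0.8` on interior cells.}
#' }
#'
#' @param params_a,params_b Single-agent 4PL truths (lists with `lower`,
#'   `upper`, `ic50`, `hill`).
#' @param model `"bliss"`, `"rescue"` or `"antagonism"`.
#' @param rescue_params 4PL truth for the rescue response (required for
#'   `model = "rescue"`).
#' @param doses_a,doses_b Non-zero dose ladders (molar); a zero-dose edge is
#'   prepended automatically.
#' @param gate_a,gate_b Dose gates for the rescue model (default 0: any
#'   non-zero dose pair is rescued).
#' @param noise_cv Multiplicative lognormal noise CV applied to every cell
#'   (default 0).
#' @param seed Optional RNG seed.
#' @return Object of class `combo_sim`: list with `observed` (matrix, rows
#'   ascending `doses_a` incl. 0), `doses_a`, `doses_b`, `model`, `truth`.
#' @export
simulate_combination <- function(params_a, params_b,
                                 model = c("bliss", "rescue", "antagonism"),
                                 rescue_params = NULL,
                                 doses_a, doses_b,
                                 gate_a = 0, gate_b = 0,
                                 noise_cv = 0, seed = NULL) {
  if (length(model) != 1 || !model %in% c("bliss", "rescue", "antagonism"))
    stop(sprintf("configuration error: unknown interaction model '%s'",
                 paste(model, collapse = "/")))
  if (!is.null(seed)) set.seed(seed)
  da <- sort(unique(c(0, as.numeric(doses_a))))
  db <- sort(unique(c(0, as.numeric(doses_b))))
  single <- function(p, d) {
    out <- numeric(length(d))
    nz <- d > 0
    out[nz] <- p$lower + (p$upper - p$lower) / (1 + (p$ic50 / d[nz])^p$hill)
    pmin(pmax(out, 0), 1)
  }
  A <- single(params_a, da)
  B <- single(params_b, db)
  obs <- outer(A, B, function(a, b) a + b - a * b)
  if (model == "rescue") {
    if (is.null(rescue_params))
      stop("configuration error: rescue model requires 'rescue_params'")
    gated <- outer(da > gate_a & da > 0, db > gate_b & db > 0, `&`)
    resc <- single(rescue_params, pmax(da, min(da[da > 0])))
    obs[gated] <- matrix(resc, length(da), length(db))[gated]
  } else if (model == "antagonism") {
    interior <- outer(da > 0, db > 0, `&`)
    mx <- outer(A, B, pmax) * 0.8
    obs[interior] <- mx[interior]
  }
  obs <- obs * matrix(.lognorm_factor(length(obs), noise_cv),
                      nrow(obs), ncol(obs))
  dimnames(obs) <- list(dose_a = signif(da, 4), dose_b = signif(db, 4))
  structure(list(observed = obs, doses_a = da, doses_b = db, model = model,
                 truth = list(params_a = params_a, params_b = params_b,
                              rescue_params = rescue_params,
                              gate_a = gate_a, gate_b = gate_b,
                              noise_cv = noise_cv)),
            class = "combo_sim")
}

#' Random transcript sequence
#'
#' @param length Sequence length in bases, >= 1.
#' @param gc GC content (default 0.5).
#' @param seed Optional RNG seed (same seed, same sequence).
#' @return Character scalar over A/C/G/T.
#' @export
make_transcript <- function(length, gc = 0.5, seed = NULL) {
  if (!is.numeric(length) || length < 1)
    stop("'length' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Construct a fusion transcript from two partners
#'
#' Joins bases `1..J5` of the 5' partner to bases `J3..end` of the 3'
#' partner (1-based inclusive junction coordinates), so the fusion length is
#' `J5 + (length(tx3) - J3 + 1)`.
#'
#' @param tx5,tx3 Partner transcript sequences.
#' @param J5 Last retained base of the 5' partner.
#' @param J3 First retained base of the 3' partner.
#' @return Fusion sequence (character scalar).
#' @export
make_fusion_transcript <- function(tx5, J5, tx3, J3) {
  if (J5 < 1 || J5 > nchar(tx5) || J3 < 1 || J3 > nchar(tx3))
    stop("junction coordinates out of transcript range")
  paste0(substr(tx5, 1, J5), substr(tx3, J3, nchar(tx3)))
}

#' Simulate paired-end reads from a weighted transcript mixture
#'
#' Draws `n_pairs` fragments from the transcripts with probability
#' proportional to molar abundance times effective length
#' (`length - insert_mean + 1`), samples each fragment's insert size from a
#' normal distribution (clamped to `[read_len, transcript length]`), and
#' reads `read_len` bases from both fragment ends on opposite strands (mate
#' 2 is reverse-complemented). With `error_rate > 0`, bases are substituted
#' uniformly at that per-base rate. Ground truth for every fragment is
#' recorded for recovery tests.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param abundances Named numeric molar abundances (same names).
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (default 75).
#' @param insert_mean,insert_sd Fragment-size distribution (default 250/30).
#' @param error_rate Per-base substitution rate (default 0).
#' @param seed Optional RNG seed.
#' @return Object of class `read_sim`: list with `reads1`, `reads2` (named
#'   character vectors), and `truth` (list: per-fragment `data.frame`
#'   `pair`, `tx`, `start`, `insert`, plus the generator parameters).
#' @export
simulate_read_pairs <- function(transcripts, abundances, n_pairs,
                                read_len = 75, insert_mean = 250,
                                insert_sd = 30, error_rate = 0,
                                seed = NULL) {
  transcripts <- as_transcript_vector(transcripts)
  if (is.null(names(abundances)) ||
      !all(names(abundances) %in% names(transcripts)))
    stop("'abundances' must be named after transcripts")
  if (insert_mean < 2) stop("'insert_mean' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  txlen <- nchar(transcripts)
  ids <- names(abundances)
  eff <- pmax(txlen[ids] - insert_mean + 1, 1)
  prob <- abundances * eff
  tx <- ids[sample.int(length(ids), n_pairs, replace = TRUE, prob = prob)]
  insert <- round(stats::rnorm(n_pairs, insert_mean, insert_sd))
  insert <- pmin(pmax(insert, read_len), txlen[tx])
  start <- floor(stats::runif(n_pairs) * (txlen[tx] - insert + 1)) + 1L
  r1 <- substring(transcripts[tx], start, start + read_len - 1L)
  r2 <- revcomp(substring(transcripts[tx], start + insert - read_len,
                          start + insert - 1L))
  if (error_rate > 0) {
    mutate <- function(reads) {
      n_err <- stats::rbinom(length(reads), read_len, error_rate)
      for (i in which(n_err > 0)) {
        s <- strsplit(reads[i], "")[[1]]
        pos <- sample.int(read_len, n_err[i])
        s[pos] <- vapply(s[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        reads[i] <- paste(s, collapse = "")
      }
      reads
    }
    r1 <- mutate(r1); r2 <- mutate(r2)
  }
  ids_pair <- sprintf("p%07d", seq_len(n_pairs))
  names(r1) <- names(r2) <- ids_pair
  structure(list(
    reads1 = r1, reads2 = r2,
    truth = list(fragments = data.frame(pair = ids_pair, tx = tx,
                                        start = start, insert = insert,
                                        stringsAsFactors = FALSE),
                 abundances = abundances, n_pairs = n_pairs,
                 read_len = read_len, insert_mean = insert_mean,
                 insert_sd = insert_sd, error_rate = error_rate,
                 seed = seed)
  ), class = "read_sim")
}

#' Fusion abundance giving a target coverage fold over the 3'-partner region
#'
#' For two libraries of equal read count — a parental one without the fusion
#' and a resistant one that adds it — the expected interior per-base
#' coverage contributed by transcript `T` is proportional to
#' `abundance_T / sum(abundance * effective_length)` (fragments are drawn
#' proportional to abundance x effective length and each deposits
#' `2 * read_len` bases over `effective_length` start positions). Solving
#' for the fusion abundance that makes the expected RBM over the retained
#' 3'-partner region `fold` times the parental value gives
#' `a_F = a_3 * S * (fold - 1) / (S - fold * a_3 * eff_F)` where `S` is the
#' parental `sum(abundance * effective_length)`. The denominator must stay
#' positive: the rest of the library (a transcriptome-like background) must
#' outweigh the fusion, else the fusion's own mass dilutes the library and
#' the target fold is unreachable.
#'
#' @param fold Target region fold (e.g. 20).
#' @param abundances Parental molar abundances (named, incl. background).
#' @param lengths Transcript lengths (named like `abundances`).
#' @param three_prime_tx Name of the wild-type 3' partner.
#' @param fusion_length Length of the fusion transcript.
#' @param insert_mean Insert size used by the read simulator.
#' @return Fusion molar abundance (numeric scalar).
#' @export
calibrate_fusion_abundance <- function(fold, abundances, lengths,
                                       three_prime_tx, fusion_length,
                                       insert_mean = 250) {
  eff <- pmax(lengths[names(abundances)] - insert_mean + 1, 1)
  S <- sum(abundances * eff)
  a3 <- abundances[[three_prime_tx]]
  eff_f <- max(fusion_length - insert_mean + 1, 1)
  denom <- S - fold * a3 * eff_f
  if (denom <= 0)
    stop(paste0("target fold unreachable: add background abundance so the ",
                "library is not dominated by the fusion"))
  unname(a3 * S * (fold - 1) / denom)
}

#' Canonical fusion study transcript architecture
#'
#' Builds the synthetic transcript set emulating the study system: a
#' 3522-base 5' partner (SND1-like), a 2947-base 3' partner (BRAF-like), a
#' transcriptome-like background transcript, and the fusion joining partner
#' bases 1-2006 to 1202-end. Coding-region offsets are chosen so the
#' junction is in frame and the fusion protein spans 5'-partner residues
#' 1-593 followed by 3'-partner residues 381-766.
#'
#' @param seed RNG seed for the random sequences (default 1).
#' @param bg_length Background transcript length (default 5000).
#' @return List with `transcripts` (named vector: `SND1like`, `BRAFlike`,
#'   `background`), `fusion` (sequence), `J5`, `J3`, `cds` (list with
#'   `start5`, `start3`, `end3`).
#' @export
fusion_study_transcripts <- function(seed = 1, bg_length = 5000) {
  set.seed(seed)
  tx5 <- make_transcript(3522)
  tx3 <- make_transcript(2947)
  bg <- make_transcript(bg_length)
  J5 <- 2006L; J3 <- 1202L
  list(transcripts = c(SND1like = tx5, BRAFlike = tx3, background = bg),
       fusion = make_fusion_transcript(tx5, J5, tx3, J3),
       J5 = J5, J3 = J3,
       cds = list(start5 = 228L, start3 = 62L, end3 = 2359L))
}

#' Simulate a copy-number probe track from segment truth
#'
#' Probes at unit spacing whose log2 ratios are the stated segment means
#' plus Gaussian noise.
#'
#' @param segments `data.frame` (or list coercible to one) with columns
#'   `n_probes` and `mean_log2`, in genomic order.
#' @param noise_sd Gaussian noise SD per probe (default 0.25).
#' @param chrom Chromosome label (default `"chr7"`).
#' @param seed Optional RNG seed.
#' @return List with `track` (data.frame `chrom`, `pos`, `log2_ratio`) and
#'   `truth` (segment frame with true `start_idx`/`end_idx` added).
#' @export
simulate_cnv_track <- function(segments, noise_sd = 0.25, chrom = "chr7",
                               seed = NULL) {
  segments <- as.data.frame(segments)
  if (nrow(segments) < 1) stop("need at least one segment")
  if (!is.null(seed)) set.seed(seed)
  mu <- rep(segments$mean_log2, segments$n_probes)
  n <- length(mu)
  track <- data.frame(chrom = chrom, pos = seq_len(n),
                      log2_ratio = mu + stats::rnorm(n, 0, noise_sd))
  ends <- cumsum(segments$n_probes)
  segments$start_idx <- c(1L, utils::head(ends, -1) + 1L)
  segments$end_idx <- ends
  list(track = track, truth = segments)
}
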