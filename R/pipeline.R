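#' Run the resistance-analysis workflow from a configuration list
#'
#' Executes the requested analysis stages in a fixed order and aggregates
#' their results into one report. Stages are independent; a failing stage is
#' reported (with its error message) without halting the others, and the
#' fully resolved configuration and seed are echoed into the report.
#'
#' Recognised stage entries in `config` (unknown keys are rejected):
#' \describe{
#'   \item{`dose_response`}{`plate` (CSV path or `plate_readout`),
#'     optional `min_span`.}
#'   \item{`synergy`}{`matrix` (CSV path, see [read_combo_csv()]) or
#'     `observed`/`doses_a`/`doses_b`; optional `window_threshold`.}
#'   \item{`fusion`}{`reads1`/`reads2` (FASTQ paths or named vectors) and
#'     `transcripts` (FASTA path or named vector); optional `min_support`,
#'     `k`, `min_anchor`.}
#'   \item{`rbm`}{`alignments` (table or minimal-SAM path), `transcript`,
#'     `transcript_length`, `library_size`, optional `region`,
#'     `pseudocount`.}
#'   \item{`cnv`}{`probes` (TSV path or data frame), optional `genes`
#'     (TSV path or gene-model list), `min_seg_probes`, `penalty`.}
#'   \item{`matrix_prep`}{`matrix` (TSV path or matrix), optional `axis`,
#'     `lo`, `hi`.}
#' }
#'
#' @param config Named list: stage entries as above plus optional `seed`
#'   (applied before any stochastic stage) and `out` (path for the JSON
#'   report).
#' @return Named list (class `pipeline_report`) with one entry per executed
#'   stage plus `config_echo`; each failed stage carries
#'   `list(error = <message>)`.
#' @export
run_pipeline <- function(config) {
  stage_order <- c("dose_response", "synergy", "fusion", "rbm", "cnv",
                   "matrix_prep")
  known <- c(stage_order, "seed", "out")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  stages <- intersect(stage_order, names(config))
  if (length(stages) == 0) {
    message("run_pipeline: no stages requested; nothing to do")
    return(structure(list(config_echo = config), class = "pipeline_report"))
  }
  # validate all referenced paths before any computation
  for (st in stages) {
    for (entry in config[[st]]) {
      if (is.character(entry) && length(entry) == 1 &&
          grepl("[/\\.]", entry) && !file.exists(entry) &&
          grepl("\\.(csv|tsv|fa|fasta|fq|fastq|sam|json)$", entry))
        stop(sprintf("stage '%s': input file not found: %s", st, entry))
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  report <- list()
  run_stage <- function(fun) tryCatch(fun(), error = function(e)
    list(error = conditionMessage(e)))

  if ("dose_response" %in% stages) {
    report$dose_response <- run_stage(function() {
      cfg <- config$dose_response
      plate <- if (is.character(cfg$plate)) read_plate_csv(cfg$plate)
               else cfg$plate
      tg <- plate_tgi(plate)
      fits <- lapply(split(tg, tg$drug), function(d)
        fit_4pl(d$dose_molar, d$tgi,
                min_span = if (is.null(cfg$min_span)) 0.2 else cfg$min_span))
      lapply(fits, unclass)
    })
  }
  if ("synergy" %in% stages) {
    report$synergy <- run_stage(function() {
      cfg <- config$synergy
      mat <- if (!is.null(cfg$matrix) && is.character(cfg$matrix))
        read_combo_csv(cfg$matrix)
      else list(observed = cfg$observed, doses_a = cfg$doses_a,
                doses_b = cfg$doses_b)
      surf <- delta_bliss_surface(mat$observed, mat$doses_a, mat$doses_b)
      win <- max_synergy_window(
        surf, if (is.null(cfg$window_threshold)) 0.9 else cfg$window_threshold)
      list(max_delta = max(surf$delta), min_excess = min(surf$excess),
           window = unclass(win))
    })
  }
  if ("fusion" %in% stages) {
    report$fusion <- run_stage(function() {
      cfg <- config$fusion
      tx <- if (is.character(cfg$transcripts) && length(cfg$transcripts) == 1)
        read_fasta(cfg$transcripts) else cfg$transcripts
      reads <- if (is.character(cfg$reads1) && length(cfg$reads1) == 1 &&
                   file.exists(cfg$reads1))
        read_fastq_pair(cfg$reads1, cfg$reads2)
      else list(reads1 = cfg$reads1, reads2 = cfg$reads2)
      call <- detect_fusion(
        reads$reads1, reads$reads2, tx,
        min_support = if (is.null(cfg$min_support)) 2 else cfg$min_support,
        k = if (is.null(cfg$k)) 31 else cfg$k,
        min_anchor = if (is.null(cfg$min_anchor)) 25 else cfg$min_anchor)
      out <- unclass(call)
      out$chimeric <- NULL
      out$assembly <- NULL
      out
    })
  }
  if ("rbm" %in% stages) {
    report$rbm <- run_stage(function() {
      cfg <- config$rbm
      aln <- if (is.character(cfg$alignments))
        read_minimal_sam(cfg$alignments)$alignments else cfg$alignments
      prof <- compute_rbm(aln, cfg$transcript, cfg$transcript_length,
                          cfg$library_size)
      out <- list(transcript = prof$transcript,
                  mean_rbm = mean(prof$rbm),
                  library_size = prof$library_size)
      if (!is.null(cfg$region))
        out$region_mean_rbm <- mean(prof$rbm[cfg$region[1]:cfg$region[2]])
      out
    })
  }
  if ("cnv" %in% stages) {
    report$cnv <- run_stage(function() {
      cfg <- config$cnv
      track <- if (is.character(cfg$probes)) read_probe_tsv(cfg$probes)
               else cfg$probes
      segs <- segment_track(
        track,
        penalty = cfg$penalty,
        min_seg_probes = if (is.null(cfg$min_seg_probes)) 5
                         else cfg$min_seg_probes)
      out <- list(segments = as.data.frame(unclass(segs)))
      if (!is.null(cfg$genes)) {
        genes <- if (is.character(cfg$genes)) read_gene_tsv(cfg$genes)
                 else cfg$genes
        out$bisected <- bisected_genes(segs, genes)
      }
      out
    })
  }
  if ("matrix_prep" %in% stages) {
    report$matrix_prep <- run_stage(function() {
      cfg <- config$matrix_prep
      m <- if (is.character(cfg$matrix))
        as.matrix(utils::read.delim(cfg$matrix, row.names = 1))
      else cfg$matrix
      centered <- median_center(
        m, axis = if (is.null(cfg$axis)) "rows" else cfg$axis)
      scaled <- scale_to_range(centered,
                               lo = if (is.null(cfg$lo)) -3 else cfg$lo,
                               hi = if (is.null(cfg$hi)) 3 else cfg$hi)
      list(dim = dim(scaled), range = range(scaled),
           matrix = scaled)
    })
  }
  report$config_echo <- config[setdiff(names(config), "out")]
  if (!is.null(config$out)) write_report_json(report, config$out)
  structure(report, class = "pipeline_report")
}
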