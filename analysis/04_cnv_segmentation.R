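#!/usr/bin/env Rscript
# Copy-number analysis: a probe-level log2-ratio track carrying one 4-fold
# amplified segment is segmented, the amplification fold estimated, and
# genes bisected by the segment breakpoints reported with their flanking
# exons — the genomic signature that nominates a fusion's partners.
#
# The synthetic gene models place an 18-exon gene across the amplification
# start (break in intron 8/9, like the 3' fusion partner) and a second gene
# across the amplification end. Writes segment and bisected-gene tables.

suppressMessages(library(metresist))
dir.create("results", showWarnings = FALSE)

# 200 neutral probes, 80 amplified at log2 = 2 (4-fold), 200 neutral;
# probe positions 1..480 at unit spacing
sim <- simulate_cnv_track(data.frame(n_probes = c(200, 80, 200),
                                     mean_log2 = c(0, 2, 0)),
                          noise_sd = 0.25, seed = 4)
segs <- segment_track(sim$track)
print(as.data.frame(segs)[, c("chrom", "start", "end", "n_probes",
                              "mean_log2", "fold")])
amp <- amplified_regions(segs)
cat(sprintf("\namplified region: probes %d-%d, fold %.2f (true 201-280, fold 4)\n",
            amp$start_idx, amp$end_idx, amp$fold))

# gene bisected by the amplification-start breakpoint between exons 8 and 9
exon_starts <- 140 + 8 * 0:17
genes <- list(
  list(gene_id = "threeprime_partner", chrom = "chr7", strand = "+",
       exons = data.frame(start = exon_starts, end = exon_starts + 3)),
  list(gene_id = "fiveprime_partner", chrom = "chr7", strand = "+",
       exons = data.frame(start = 250 + 8 * 0:15, end = 253 + 8 * 0:15))
)
bis <- bisected_genes(segs, genes)
print(bis)

utils::write.table(as.data.frame(segs), "results/cnv_segments.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
write_report_json(list(amplified = amp, bisected = bis),
                  "results/cnv_bisected_genes.json")
cat("\nThe amplification breakpoints land within both gene bodies; the\n")
cat("flanking-exon readout localizes each break to an intron, matching the\n")
cat("expected fusion-partner architecture. Outputs: results/cnv_*.{tsv,json}\n")
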