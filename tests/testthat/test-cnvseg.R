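test_that("noiseless piecewise-constant tracks are segmented exactly", {
  sim <- simulate_cnv_track(data.frame(n_probes = c(200, 100, 200),
                                       mean_log2 = c(0, 2, 0)),
                            noise_sd = 0, seed = 1)
  segs <- segment_track(sim$track)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$start_idx, c(1L, 201L, 301L))
  expect_equal(segs$end_idx, c(200L, 300L, 500L))
  expect_equal(segs$mean_log2, c(0, 2, 0))
  expect_equal(segs$fold, c(1, 4, 1))
  # more changepoints, still exact
  sim2 <- simulate_cnv_track(data.frame(n_probes = c(60, 40, 80, 50),
                                        mean_log2 = c(0, 1, -1, 0.5)),
                             noise_sd = 0, seed = 1)
  segs2 <- segment_track(sim2$track)
  expect_equal(segs2$start_idx, c(1L, 61L, 101L, 181L))
})

test_that("constant and tiny tracks return a single segment", {
  const <- data.frame(chrom = "chr1", pos = 1:100, log2_ratio = 0.3)
  segs <- segment_track(const)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_probes, 100L)
  tiny <- data.frame(chrom = "chr1", pos = 1:6, log2_ratio = rnorm(6))
  st <- segment_track(tiny, min_seg_probes = 5)
  expect_equal(nrow(st), 1)
  expect_match(attr(st, "warning"), "too few probes")
})

test_that("segments partition the probe track", {
  set.seed(7)
  sim <- simulate_cnv_track(data.frame(n_probes = c(150, 60, 150),
                                       mean_log2 = c(0, 2, 0)),
                            noise_sd = 0.25, seed = 7)
  segs <- segment_track(sim$track)
  expect_equal(sum(segs$n_probes), nrow(sim$track))
  expect_equal(segs$start_idx[-1], segs$end_idx[-nrow(segs)] + 1L)
  expect_equal(segs$start_idx[1], 1L)
  expect_equal(segs$end_idx[nrow(segs)], nrow(sim$track))
})

test_that("fold estimates follow 2^mean_log2 with reciprocal symmetry", {
  expect_equal(estimate_fold(list(mean_log2 = 0)), 1)
  expect_equal(estimate_fold(list(mean_log2 = 2)), 4)
  expect_equal(estimate_fold(list(mean_log2 = -1)), 0.5)
  for (x in c(0.3, 1.7, 2.5))
    expect_equal(estimate_fold(list(mean_log2 = x)) *
                   estimate_fold(list(mean_log2 = -x)), 1)
})

test_that("noisy amplified segments are recovered near truth", {
  folds <- devs <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_cnv_track(data.frame(n_probes = c(200, 80, 200),
                                         mean_log2 = c(0, 2, 0)),
                              noise_sd = 0.25, seed = 100 + s)
    amp <- amplified_regions(segment_track(sim$track))
    expect_equal(nrow(amp), 1)
    folds[s] <- amp$fold
    devs[s] <- max(abs(amp$start_idx - 201), abs(amp$end_idx - 280))
  }
  expect_equal(mean(folds), 4, tolerance = 0.1)
  expect_true(all(devs <= 2))
})

test_that("breakpoints bisecting genes report the flanking exons", {
  # 18 exons of 100 bases every 200 bases starting at 1001
  exons <- data.frame(start = 1001 + 200 * 0:17, end = 1100 + 200 * 0:17)
  gene <- list(gene_id = "BRAFlike", chrom = "chr7", strand = "+",
               exons = exons)
  # segment boundary between genomic exons 8 and 9: probes up to 2450,
  # next segment starting at 2550 -> breakpoint at 2500 (intron 8)
  segs <- data.frame(chrom = "chr7", start = c(1, 2550), end = c(2450, 6000),
                     n_probes = c(10, 10), mean_log2 = c(0, 2),
                     fold = c(1, 4), start_idx = c(1L, 11L),
                     end_idx = c(10L, 20L))
  hit <- bisected_genes(segs, list(gene))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$exon5, 8L)
  expect_equal(hit$exon3, 9L)
  expect_false(hit$in_exon)
  # minus strand: same breakpoint, transcription-order indices flip
  gene_m <- gene; gene_m$strand <- "-"
  hit_m <- bisected_genes(segs, list(gene_m))
  expect_equal(hit_m$exon5, 18L - 9L + 1L)
  expect_equal(hit_m$exon3, 18L - 8L + 1L)
  # gene fully inside one segment is not reported
  far <- list(gene_id = "other", chrom = "chr7", strand = "+",
              exons = data.frame(start = c(100, 300), end = c(200, 400)))
  expect_equal(nrow(bisected_genes(segs, list(far))), 0)
})

test_that("breakpoints at exon edges land in the adjacent intron", {
  exons <- data.frame(start = c(101, 301, 501), end = c(200, 400, 600))
  gene <- list(gene_id = "g", chrom = "c", strand = "+", exons = exons)
  # breakpoint exactly at the end of exon 2 (pos 400)
  segs <- data.frame(chrom = "c", start = c(1, 450), end = c(350, 900),
                     n_probes = c(5, 5), mean_log2 = c(0, 1),
                     fold = c(1, 2), start_idx = c(1L, 6L),
                     end_idx = c(5L, 10L))
  hit <- bisected_genes(segs, list(gene))
  expect_equal(hit$breakpoint, 400)
  expect_false(hit$in_exon)
  expect_equal(c(hit$exon5, hit$exon3), c(2L, 3L))
})
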