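test_that("the pipeline recovers the fusion junction end-to-end", {
  arch <- arch_fixture()
  ab <- study_abundances()
  sim <- simulate_read_pairs(c(arch$transcripts, fusion = arch$fusion),
                             ab$resistant, n_pairs = 4000, seed = 61)
  call <- detect_fusion(sim$reads1, sim$reads2, arch$transcripts)
  expect_equal(call$status, "ok")
  expect_equal(call$five_prime_tx, "SND1like")
  expect_equal(call$three_prime_tx, "BRAFlike")
  # coordinates exact up to the homology interval (5'-most convention)
  expect_true(call$J5 <= arch$J5 &&
                call$J5 >= arch$J5 - call$homology_interval)
  expect_equal(call$J5 - arch$J5, call$J3 - arch$J3)
  # the called junction encodes the same fusion sequence as the truth
  called <- make_fusion_transcript(arch$transcripts[["SND1like"]], call$J5,
                                   arch$transcripts[["BRAFlike"]], call$J3)
  expect_equal(substr(called, call$J5 - 100, call$J5 + 100),
               substr(arch$fusion, call$J5 - 100, call$J5 + 100))
  expect_gt(call$supporting_pairs, 20)
  expect_gt(call$spanning_reads, 5)
  # fusion sequence length identity
  expect_equal(nchar(arch$fusion),
               arch$J5 + nchar(arch$transcripts[["BRAFlike"]]) - arch$J3 + 1)
})

test_that("wild-type-only libraries produce no fusion call", {
  arch <- arch_fixture()
  sim <- simulate_read_pairs(arch$transcripts,
                             c(SND1like = 1, BRAFlike = 1, background = 3),
                             n_pairs = 1200, seed = 67)
  call <- detect_fusion(sim$reads1, sim$reads2, arch$transcripts)
  expect_equal(call$status, "no_fusion")
})

test_that("RBM normalization is unitary and depth-invariant", {
  set.seed(71)
  tx <- c(alpha = make_transcript(400))
  aln <- map_reads(c(p = substr(tx[["alpha"]], 51, 125)),
                   c(p = revcomp(substr(tx[["alpha"]], 201, 275))), tx)
  one <- compute_rbm(aln[aln$mate == 1, ], "alpha", 400, library_size = 1e6)
  expect_equal(sum(one$rbm == 1), 75)   # one read in a million => RBM 1
  expect_equal(sum(one$rbm != 0), 75)
  # doubling reads and library size leaves RBM unchanged
  dbl <- data.table::rbindlist(list(aln, aln))
  dbl$pair <- paste0(dbl$pair, rep(c("a", "b"), each = nrow(aln)))
  both <- compute_rbm(aln, "alpha", 400, library_size = 2e6)
  doubled <- compute_rbm(dbl, "alpha", 400, library_size = 4e6)
  expect_equal(both$rbm, doubled$rbm)
  expect_error(compute_rbm(aln, "alpha", 400, library_size = 0), "positive")
})

test_that("coverage totals are conserved across transcripts", {
  arch <- arch_fixture()
  sim <- simulate_read_pairs(arch$transcripts,
                             c(SND1like = 1, BRAFlike = 1, background = 2),
                             n_pairs = 600, seed = 73)
  aln <- map_reads(sim$reads1, sim$reads2, arch$transcripts)
  uni <- aln[aln$status == "unique", ]
  total_cov <- sum(vapply(names(arch$transcripts), function(id)
    sum(compute_rbm(aln, id, nchar(arch$transcripts[[id]]), 1200)$coverage),
    0))
  expect_equal(total_cov, sum(uni$span))
})

test_that("region folds follow the RBM ratio with pseudocount", {
  p20 <- structure(list(transcript = "t", rbm = rep(20, 100),
                        coverage = rep(2, 100), library_size = 1e5),
                   class = "rbm_profile")
  p1 <- structure(list(transcript = "t", rbm = rep(1, 100),
                       coverage = rep(1, 100), library_size = 1e6),
                  class = "rbm_profile")
  expect_equal(region_fold(p20, p1, c(1, 100), pseudocount = 0), 20)
  expect_equal(region_fold(p1, p1, c(10, 50)), 1)
  expect_error(region_fold(p20, p1, c(50, 10)), "region")
  expect_error(region_fold(p20, p1, c(1, 200)), "region")
})

test_that("simulated fusion libraries show the calibrated region-coverage excess", {
  arch <- arch_fixture()
  ab <- study_abundances(fold = 20)
  n <- 30000
  idx <- build_kmer_index(arch$transcripts)
  par <- simulate_read_pairs(arch$transcripts, ab$parental, n, seed = 81)
  res <- simulate_read_pairs(c(arch$transcripts, fusion = arch$fusion),
                             ab$resistant, n, seed = 82)
  p_par <- compute_rbm(map_reads(par$reads1, par$reads2, idx), "BRAFlike",
                       nchar(arch$transcripts[["BRAFlike"]]), 2 * n)
  p_res <- compute_rbm(map_reads(res$reads1, res$reads2, idx), "BRAFlike",
                       nchar(arch$transcripts[["BRAFlike"]]), 2 * n)
  fold <- region_fold(p_res, p_par, c(arch$J3, 2947), pseudocount = 0)
  expect_equal(fold, 20, tolerance = 0.15)
})

test_that("the fusion ORF mapping reproduces the in-frame protein architecture", {
  arch <- arch_fixture()
  call <- list(J5 = arch$J5, J3 = arch$J3)
  orf <- fusion_orf(call, arch$cds$start5, arch$cds$start3, arch$cds$end3)
  expect_true(orf$in_frame)
  expect_equal(orf$five_prime_aa, c(1, 593))
  expect_equal(orf$three_prime_aa, c(381, 766))
  expect_equal(orf$protein_length, 593 + (766 - 381 + 1))

  one_codon <- fusion_orf(list(J5 = arch$cds$start5 + 2, J3 = arch$J3),
                          arch$cds$start5, arch$cds$start3, arch$cds$end3)
  expect_equal(one_codon$five_prime_aa, c(1, 1))

  shifted <- fusion_orf(list(J5 = arch$J5 + 1, J3 = arch$J3),
                        arch$cds$start5, arch$cds$start3, arch$cds$end3)
  expect_false(shifted$in_frame)
  expect_equal(shifted$status, "out_of_frame")

  utr <- fusion_orf(list(J5 = 100, J3 = arch$J3),
                    arch$cds$start5, arch$cds$start3, arch$cds$end3)
  expect_equal(utr$status, "junction_in_utr")
})
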