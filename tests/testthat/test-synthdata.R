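test_that("generators are deterministic under a fixed seed", {
  expect_identical(make_transcript(3522, seed = 5), make_transcript(3522, seed = 5))
  expect_equal(nchar(make_transcript(2947, seed = 8)), 2947)
  expect_error(make_transcript(0), ">= 1")
  s1 <- simulate_read_pairs(c(t = make_transcript(1000, seed = 2)),
                            c(t = 1), 50, seed = 3)
  s2 <- simulate_read_pairs(c(t = make_transcript(1000, seed = 2)),
                            c(t = 1), 50, seed = 3)
  expect_identical(s1$reads1, s2$reads1)
  expect_identical(s1$truth$fragments, s2$truth$fragments)
})

test_that("fusion construction joins the declared prefix and suffix", {
  tx5 <- make_transcript(3522, seed = 4)
  tx3 <- make_transcript(2947, seed = 5)
  fus <- make_fusion_transcript(tx5, 2006, tx3, 1202)
  expect_equal(nchar(fus), 2006 + (2947 - 1202 + 1))  # 3752
  expect_equal(substr(fus, 1, 2006), substr(tx5, 1, 2006))
  expect_equal(substr(fus, 2007, nchar(fus)), substr(tx3, 1202, 2947))
  expect_equal(make_fusion_transcript(tx5, nchar(tx5), tx3, 1),
               paste0(tx5, tx3))
  expect_equal(nchar(make_fusion_transcript(tx5, 1, tx3, nchar(tx3))), 2)
  expect_error(make_fusion_transcript(tx5, 0, tx3, 10), "out of")
  expect_error(make_fusion_transcript(tx5, 10, tx3, 5000), "out of")
})

test_that("zero-noise plates round-trip through TGI exactly", {
  lad <- build_dilution_ladder(10e-6, 4, 9)
  truth <- pl4(0, 1, 10e-9, 1)
  plate <- simulate_plate(truth, lad, noise_cv = 0, replicates = 1)
  tg <- plate_tgi(plate)
  expect_equal(tg$tgi, predict_4pl(truth, tg$dose_molar))
  # every endpoint-untreated well has TGI 0; baseline-level wells TGI 1
  expect_equal(compute_tgi(plate$untreated_wells, plate),
               rep(0, length(plate$untreated_wells)))
  expect_equal(compute_tgi(plate$baseline_wells, plate),
               rep(1, length(plate$baseline_wells)))
  flat <- simulate_plate(flat_4pl(), lad, noise_cv = 0, replicates = 1,
                         untreated_mean = 9000)
  tr <- flat$wells$count[flat$wells$role == "treated"]
  expect_equal(tr, rep(9000, 9))
  expect_error(simulate_plate(truth, lad, baseline_mean = 9000,
                              untreated_mean = 1000),
               "configuration")
})

test_that("noisy plates still recover the generating IC50", {
  lad <- build_dilution_ladder(10e-6, 4, 9)
  truth <- pl4(0, 1, 10e-9, 1)
  est <- vapply(1:10, function(s) {
    plate <- simulate_plate(truth, lad, noise_cv = 0.05, replicates = 3,
                            seed = s)
    tg <- plate_tgi(plate)
    fit_4pl(tg$dose_molar, tg$tgi)$ic50
  }, 0)
  expect_equal(mean(est), 10e-9, tolerance = 0.1)
})

test_that("read simulation conserves counts, lengths and substrings", {
  tx <- c(t = make_transcript(2000, seed = 6))
  sim <- simulate_read_pairs(tx, c(t = 1), n_pairs = 200, seed = 7)
  expect_length(sim$reads1, 200)
  expect_length(sim$reads2, 200)
  expect_true(all(nchar(sim$reads1) == 75))
  expect_true(all(nchar(sim$reads2) == 75))
  # error-free mate 1 is an exact substring; mate 2 after reverse complement
  expect_true(all(vapply(sim$reads1[1:50], grepl, TRUE, x = tx[["t"]],
                         fixed = TRUE)))
  expect_true(all(vapply(revcomp(sim$reads2[1:50]), grepl, TRUE,
                         x = tx[["t"]], fixed = TRUE)))
  # abundances must name transcripts
  expect_error(simulate_read_pairs(tx, c(u = 1), 10), "named after")
})

test_that("simulation truth survives JSON serialization", {
  tx <- c(t = make_transcript(500, seed = 9))
  sim <- simulate_read_pairs(tx, c(t = 1), 20, seed = 10)
  path <- tempfile(fileext = ".json")
  write_report_json(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$fragments$start, sim$truth$fragments$start)
  expect_equal(back$fragments$tx, sim$truth$fragments$tx)
  expect_equal(back$read_len, 75)
})

test_that("fusion-abundance calibration reports unreachable targets", {
  lens <- c(SND1like = 3522, BRAFlike = 2947)
  expect_error(
    calibrate_fusion_abundance(20, c(SND1like = 1, BRAFlike = 1), lens,
                               "BRAFlike", 3752),
    "unreachable")
  ab <- study_abundances(fold = 20)
  expect_gt(ab$resistant[["fusion"]], 0)
})
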