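test_that("generated precursors carry an exact truth record", {
  # octapeptide hormone architecture: 25-aa signal, one amidated copy,
  # dibasic site immediately after the mature peptide (position 35)
  truth <- generate_precursor(
    data.frame(payload = "QLNFSPGW", amidated = TRUE, site = "KR"),
    signal_len = 25, seed = 1)
  expect_equal(truth$matures, "pQLNFSPGWamide")
  expect_equal(truth$sites$start, 35L)
  expect_equal(truth$sites$basic_run, "KR")
  expect_equal(nchar(truth$protein$seq), 36L)

  # an 18-copy multi-peptide precursor yields 18 expected matures
  multi <- generate_precursor(rep("GSEFLamide", 18), signal_len = 25,
                              seed = 2)
  expect_length(multi$matures, 18L)
  expect_true(all(multi$matures == "AGSEFLamide"))

  # determinism under seed
  a <- generate_precursor(c("kinin", "CCAP"), seed = 9)
  b <- generate_precursor(c("kinin", "CCAP"), seed = 9)
  expect_identical(a, b)

  # clean-mode payload validation
  expect_error(generate_precursor(
    data.frame(payload = "AKRA", amidated = TRUE), seed = 1), "clean-mode")
  expect_error(generate_precursor(
    data.frame(payload = "AAAG", amidated = FALSE), seed = 1), "end in G")
})

test_that("the annotation chain recovers planted truths exactly", {
  set.seed(55)
  for (rep in 1:40) {
    truth <- generate_precursor(
      sample(clean_payload_pool()$family, sample(1:6, 1), replace = TRUE),
      signal_len = sample(19:35, 1), seed = sample.int(1e6, 1))
    ann <- annotate_precursor(truth$protein)
    expect_equal(ann$signal$end, truth$signal_end)
    expect_equal(vapply(ann$matures, `[[`, "", "rendered"), truth$matures)
  }
})

test_that("reverse translation round-trips through the ORF scanner", {
  rt <- reverse_translate("MK", seed = 3)
  orfs <- find_orfs(data.frame(id = "t", seq = rt$transcript))
  expect_true("MK" %in% orfs$seq)
  expect_equal(substring(rt$transcript, rt$cds_start, rt$cds_start + 2L),
               "ATG")

  set.seed(61)
  ok <- 0L
  for (rep in 1:100) {
    prot <- paste0("M", random_protein(sample(20:80, 1),
                                       setdiff(AA20, "M")))
    rt <- reverse_translate(prot, seed = sample.int(1e6, 1))
    orfs <- find_orfs(data.frame(id = "t", seq = rt$transcript),
                      min_len_aa = nchar(prot))
    if (prot %in% orfs$seq) ok <- ok + 1L
  }
  expect_equal(ok, 100L)

  expect_error(reverse_translate(""), "nzchar")
})

test_that("GPCR-like constructs satisfy their architectural contract", {
  g0 <- generate_gpcr_like(0, seed = 4)
  expect_equal(nrow(g0$tm_spans), 0L)
  expect_equal(vet_gpcr_candidate(g0$protein)$n_tm, 0L)

  g5 <- generate_gpcr_like(5, seed = 4)
  expect_gte(nchar(g5$protein$seq), 150L)

  # 5% substitution noise: the 7TM verdict survives in at least 95/100 seeds
  pass <- 0L
  for (seed in 1:100) {
    g <- generate_gpcr_like(7, seed = seed, noise = 0.05)
    if (vet_gpcr_candidate(g$protein)$passes_7tm) pass <- pass + 1L
  }
  expect_gte(pass, 95L)
})

test_that("datasets are reproducible and distinct across seeds", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  d1 <- generate_dataset(3, 2, seed = 5, dir = dir1)
  d1b <- generate_dataset(3, 2, seed = 5, dir = dir2)
  expect_identical(d1$truth[c("precursors", "gpcrs")],
                   d1b$truth[c("precursors", "gpcrs")])
  expect_identical(readLines(d1$paths[["transcripts"]]),
                   readLines(d1b$paths[["transcripts"]]))

  d2 <- generate_dataset(3, 2, seed = 6, dir = withr::local_tempdir())
  p1 <- vapply(d1$truth$precursors, `[[`, "", "protein")
  p2 <- vapply(d2$truth$precursors, `[[`, "", "protein")
  expect_false(any(p1 %in% p2))

  d0 <- generate_dataset(0, 0, seed = 7, dir = withr::local_tempdir())
  expect_length(d0$truth$precursors, 0L)
  expect_true(file.exists(d0$paths[["transcripts"]]))
})
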