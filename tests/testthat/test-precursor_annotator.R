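test_that("signal-peptide heuristic scores a classic three-region signal", {
  set.seed(3)
  downstream <- random_protein(60, setdiff(AA20, c("K", "R", "G", "C")))
  p <- data.frame(id = "pos", seq = paste0("MKTLLVLAVLALFSVSSA", downstream))
  sp <- predict_signal_peptide(p)
  expect_true(sp$present)
  expect_equal(sp$start, 1L)
  expect_true(sp$end >= 16 && sp$end <= 20)
  expect_true(sp$score >= 0 && sp$score <= 1)

  # no hydrophobic core: poly-D N-terminus never calls a signal
  neg <- data.frame(id = "neg", seq = paste0(strrep("D", 30), downstream))
  expect_false(predict_signal_peptide(neg)$present)

  # too short for heuristic mode
  short <- data.frame(id = "s", seq = "MKTLLVLAVLAL")
  res <- predict_signal_peptide(short)
  expect_false(res$present)
  expect_equal(res$score, 0)
})

test_that("external signal spans override the heuristic verbatim", {
  p <- data.frame(id = "ccap_like", seq = strrep("D", 80))
  ext <- data.frame(id = "ccap_like", sp_end = 30)
  sp <- predict_signal_peptide(p, external = ext)
  expect_true(sp$present)
  expect_equal(sp$end, 30L)
  expect_equal(sp$method, "external")
})

test_that("cleavage scan handles constructed mono/di/tribasic cases", {
  rules_di <- cleavage_rules(tribasic = FALSE, terminal_monobasic = FALSE)
  s1 <- find_cleavage_sites(data.frame(id = "a", seq = "AAAKRAAA"), rules_di)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$basic_run, "KR")
  expect_equal(s1$start, 4L)
  expect_equal(s1$cut_after, 5L)

  s2 <- find_cleavage_sites(data.frame(id = "b", seq = "AAKRAARKRAA"),
                            cleavage_rules(terminal_monobasic = FALSE))
  expect_equal(s2$basic_run, c("KR", "RKR"))
  expect_equal(s2$start, c(3L, 7L))
  expect_equal(s2$kind, c("dibasic", "tribasic"))

  # a terminal monobasic K (as on precursors ending ...QQWK)
  s3 <- find_cleavage_sites(data.frame(id = "c",
                                       seq = paste0(strrep("A", 20), "QQWK")))
  expect_equal(s3$basic_run, "K")
  expect_equal(s3$kind, "monobasic")
  expect_equal(s3$start, 24L)

  # interior monobasic stays silent unless enabled
  p <- data.frame(id = "d", seq = "AAAAARAAAAAAAAA")
  expect_equal(nrow(find_cleavage_sites(p)), 0L)
  expect_equal(nrow(find_cleavage_sites(p, cleavage_rules(monobasic = "R"))),
               1L)
})

test_that("cleavage scan equals a character-walk oracle over rulesets", {
  set.seed(21)
  for (rep in 1:300) {
    seq <- random_protein(sample(20:120, 1),
                          c(AA20, rep(c("K", "R"), 6)))
    dib <- sample(c("KR", "KK", "RR", "RK"), sample(0:4, 1))
    trib <- sample(c(TRUE, FALSE), 1)
    mono <- sample(c("K", "R"), sample(0:2, 1))
    term <- sample(c(TRUE, FALSE), 1)
    sig <- sample(0:10, 1)
    rules <- cleavage_rules(dibasic = if (length(dib)) dib else character(),
                            tribasic = trib, monobasic = mono,
                            terminal_monobasic = term)
    got <- find_cleavage_sites(data.frame(id = "r", seq = seq), rules,
                               signal_end = sig)
    want <- oracle_cleavage(seq, rules$dibasic, trib, mono, term, 4, sig)
    expect_equal(got$start, want$start)
    expect_equal(got$basic_run, want$basic_run)
    expect_equal(got$kind, want$kind)
    expect_equal(got$cut_after, want$cut_after)
  }
})

test_that("excision reproduces the two-site near-terminal worked example", {
  # 100-aa precursor: 24-aa signal, dibasic KR at 85-86, monobasic R at 97
  seq <- paste0(strrep("A", 84), "KR", strrep("S", 10), "R", "VGG")
  p <- data.frame(id = "myo_like", seq = seq)
  expect_equal(nchar(seq), 100L)
  signal <- list(present = TRUE, start = 1L, end = 24L, score = 1,
                 method = "external")
  sites <- find_cleavage_sites(p, signal_end = 24L)
  expect_equal(sites$start, c(85L, 97L))
  fr <- excise_fragments(p, signal, sites)
  expect_equal(fr$start, c(25L, 87L, 98L))
  expect_equal(fr$end, c(84L, 96L, 100L))
})

test_that("excision tiles the precursor exactly", {
  # no signal, no sites: the whole protein is one fragment
  p <- data.frame(id = "w", seq = "MNSTDEF")
  fr <- excise_fragments(p)
  expect_equal(fr$seq, p$seq)

  set.seed(9)
  for (rep in 1:50) {
    truth <- generate_precursor(
      sample(clean_payload_pool()$family, sample(1:5, 1), replace = TRUE),
      signal_len = sample(19:35, 1), cprp_len = sample(c(0, 12), 1),
      seed = rep)
    p <- truth$protein
    signal <- list(present = TRUE, start = 1L, end = truth$signal_end,
                   score = 1, method = "external")
    sites <- find_cleavage_sites(p, signal_end = truth$signal_end)
    fr <- excise_fragments(p, signal, sites)
    # reassembly: signal + fragments + basic runs cover every residue once
    covered <- c(seq_len(truth$signal_end),
                 unlist(mapply(seq, fr$start, fr$end, SIMPLIFY = FALSE)),
                 unlist(mapply(seq, sites$start, sites$cut_after,
                               SIMPLIFY = FALSE)))
    expect_equal(sort(covered), seq_len(nchar(p$seq)))
  }

  # overlapping sites violate the contract
  bad <- data.frame(start = c(3L, 4L), basic_run = c("KR", "RK"),
                    kind = "dibasic", cut_after = c(4L, 5L))
  expect_error(excise_fragments(data.frame(id = "x", seq = "AAKRKAAA"),
                                NULL, bad), "overlapping")

  # degenerate: all-basic precursor yields zero fragments with a warning
  allb <- data.frame(id = "b", seq = "KRKRKR")
  sites_b <- find_cleavage_sites(allb)
  expect_warning(fr_b <- excise_fragments(allb, NULL, sites_b), "no fragments")
  expect_equal(nrow(fr_b), 0L)
})

test_that("PTM rules amidate, cyclize and render as in printed peptides", {
  acp <- apply_ptm("QITFSRSWVPQG")
  expect_equal(acp$rendered, "pQITFSRSWVPQamide")
  expect_true(acp$amidated)
  expect_true(acp$pyroglu)
  expect_equal(nchar("QITFSRSWVPQG"), 12L)  # unprocessed 12-mer carries the G

  ccap <- apply_ptm("PFCNAFTGCG")
  expect_equal(ccap$rendered, "PFCNAFTGCamide")
  expect_equal(ccap$cys_count, 2L)

  proc <- apply_ptm("RYLPT")
  expect_equal(proc$rendered, "RYLPT")
  expect_false(proc$amidated)
  expect_false(proc$pyroglu)

  # E-cyclization only when enabled
  expect_false(apply_ptm("EFDDYG")$pyroglu)
  expect_true(apply_ptm("EFDDYG", ptm_config(pyroglu_from_E = TRUE))$pyroglu)

  # retained trailing basics are stripped before amidation
  expect_equal(apply_ptm("QAFSAWAGKR")$rendered, "pQAFSAWAamide")
})

test_that("rendering round-trips through its inverse", {
  expect_equal(invert_rendering("pQLNFSPGWamide"), "QLNFSPGWG")
  expect_equal(invert_rendering("RYLPT"), "RYLPT")
  expect_error(invert_rendering("pXLNF"), "pyroglutamate")
  expect_error(invert_rendering("abc"), "malformed")

  set.seed(31)
  for (rep in 1:200) {
    body <- random_protein(sample(4:20, 1),
                           setdiff(AA20, c("K", "R", "G")))
    frag <- paste0(sample(c("Q", ""), 1), body, sample(c("G", ""), 1))
    m <- apply_ptm(frag)
    expect_equal(invert_rendering(m$rendered), frag)
  }
})

test_that("cysteine counting matches the published repertoire peptides", {
  alp <- "WRSCIRRGGACDHRPNDCCYNSSCRCNLWGTNCRCQRMGIFQQW"
  expect_equal(count_cysteines(alp), 8L)
  trissin <- "STVSCDSCGPECQTACGTKNFRACCFNFL"
  expect_equal(count_cysteines(trissin), 6L)
  expect_equal(count_cysteines("AAAA"), 0L)
})

test_that("disulfide pairing counts follow the double factorial", {
  six <- enumerate_disulfide_pairings(6)
  expect_equal(six$bridges, 3L)
  expect_equal(six$n_matchings, 15)
  expect_equal(length(six$matchings), 15L)

  zero <- enumerate_disulfide_pairings(0)
  expect_equal(zero$bridges, 0L)
  expect_equal(zero$n_matchings, 1)

  expect_equal(enumerate_disulfide_pairings(8)$bridges, 4L)

  expect_warning(odd <- enumerate_disulfide_pairings(7), "unpaired")
  expect_equal(odd$bridges, 3L)
  expect_true(odd$unpaired)

  for (n in c(0, 2, 4, 6, 8, 10)) {
    got <- enumerate_disulfide_pairings(n, list_matchings = (n <= 12))
    expect_equal(got$n_matchings, oracle_count_matchings(n))
    expect_equal(length(got$matchings),
                 oracle_count_matchings(n))
    # listed matchings are distinct valid pairings
    keys <- vapply(got$matchings, function(m) {
      paste(apply(m[order(m[, 1]), , drop = FALSE], 1, function(p) {
        paste(sort(p), collapse = "-")
      }), collapse = ";")
    }, "")
    expect_false(anyDuplicated(keys) > 0)
    for (m in got$matchings[seq_len(min(5, length(got$matchings)))]) {
      expect_true(validate_pairing(m, n)$valid)
    }
  }
})

test_that("pairing validation accepts published bridge maps and rejects abuse", {
  gpa2 <- list(c(1, 10), c(2, 8), c(3, 5), c(4, 9), c(6, 7))
  expect_true(validate_pairing(gpa2, 10)$valid)
  gpb5 <- list(c(1, 10), c(2, 5), c(3, 4), c(6, 8), c(7, 9))
  expect_true(validate_pairing(gpb5, 10)$valid)
  trissin <- list(c(1, 6), c(2, 4), c(3, 5))
  expect_true(validate_pairing(trissin, 6)$valid)

  expect_match(validate_pairing(list(c(1, 2), c(1, 3)), 4)$reason, "once")
  expect_match(validate_pairing(list(c(1, 7)), 6)$reason, "range")
  expect_match(validate_pairing(list(c(1, 2)), 4)$reason, "cover")
})

test_that("annotate_precursor chains stages and keeps signal-less inputs", {
  truth <- generate_precursor(c("sNPF", "CCAP"), signal_len = 28, seed = 77)
  ann <- annotate_precursor(truth$protein)
  expect_s3_class(ann, "precursor_annotation")
  expect_equal(ann$signal$end, truth$signal_end)
  expect_equal(vapply(ann$matures, `[[`, "", "rendered"), truth$matures)

  nosig <- generate_precursor(c("AST-A"), signal_len = NA, seed = 5)
  ann2 <- annotate_precursor(nosig$protein)
  expect_false(ann2$signal$present)
  expect_equal(length(ann2$matures), 1L)
})
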