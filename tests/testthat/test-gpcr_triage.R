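test_that("length filter partitions at the 150-aa completeness threshold", {
  prots <- data.frame(id = c("a", "b", "c"),
                      seq = c(strrep("A", 149), strrep("A", 150),
                              strrep("A", 400)))
  parts <- filter_by_length(prots)
  expect_equal(parts$rejected$id, "a")
  expect_equal(parts$retained$id, c("b", "c"))
  expect_equal(nrow(parts$retained) + nrow(parts$rejected), nrow(prots))

  empty <- filter_by_length(prots[0, ])
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(nrow(empty$rejected), 0L)
})

test_that("hydropathy profile is a centered windowed mean of the scale", {
  poly_i <- hydropathy_profile(strrep("I", 40))
  expect_true(all(poly_i$values == 4.5))
  poly_d <- hydropathy_profile(strrep("D", 40))
  expect_true(all(poly_d$values == -3.5))

  set.seed(13)
  for (rep in 1:10) {
    seq <- random_protein(sample(30:200, 1))
    for (w in c(7, 19)) {
      h <- hydropathy_profile(seq, window = w)
      kd <- npmine:::KD_SCALE[strsplit(seq, "")[[1]]]
      expect_equal(h$values, oracle_window_mean(unname(kd), w))
    }
  }
  # X residues score zero
  hx <- hydropathy_profile(paste0(strrep("I", 9), "X", strrep("I", 9)),
                           window = 19)
  expect_equal(hx$values[10], (18 * 4.5) / 19)
})

test_that("TM segment calling recovers planted helix architectures", {
  # canonical construct: seven 21-aa poly-LIV helices, 20-aa polar loops
  set.seed(101)
  helices <- vapply(1:7, function(i) {
    paste0(sample(c("L", "I", "V"), 21, replace = TRUE), collapse = "")
  }, "")
  loops <- vapply(1:8, function(i) {
    paste0(sample(c("D", "E", "N", "Q", "S"), 20, replace = TRUE),
           collapse = "")
  }, "")
  seq7 <- paste0(loops[1], paste0(helices, loops[-1], collapse = ""))
  planted_starts <- 20 + (0:6) * 41 + 1
  v7 <- vet_gpcr_candidate(data.frame(id = "tm7", seq = seq7))
  expect_equal(v7$n_tm, 7L)
  expect_true(v7$passes_7tm)
  expect_true(all(abs(v7$tm_segments$start - planted_starts) <= 2))
  expect_true(all(abs(v7$tm_segments$end - (planted_starts + 20)) <= 2))

  # randomized architectures: segment counts match the planted truth
  set.seed(17)
  for (seed in 1:10) {
    g <- generate_gpcr_like(7, seed = seed)
    v <- vet_gpcr_candidate(g$protein)
    expect_equal(v$n_tm, 7L)
    expect_true(v$passes_7tm)
    expect_true(all(abs(v$tm_segments$start - g$tm_spans$start) <= 4))
    expect_true(all(abs(v$tm_segments$end - g$tm_spans$end) <= 4))
  }

  # all-polar protein: no segments
  polar <- data.frame(id = "p", seq = strrep("DENQST", 40))
  expect_equal(vet_gpcr_candidate(polar)$n_tm, 0L)

  # six helices fail the exact-7 acceptance band but pass a loose band
  g6 <- generate_gpcr_like(6, seed = 2)
  expect_false(vet_gpcr_candidate(g6$protein)$passes_7tm)
  expect_true(vet_gpcr_candidate(g6$protein, band = 6:8)$passes_7tm)
})

test_that("segment count does not increase with the threshold", {
  set.seed(23)
  for (seed in 1:5) {
    g <- generate_gpcr_like(sample(3:8, 1), seed = seed)
    h <- hydropathy_profile(g$protein)
    counts <- vapply(c(0.8, 1.2, 1.6, 2.0, 2.4), function(th) {
      nrow(predict_tm_segments(h, threshold = th))
    }, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("7TM domain extraction spans first to last helix", {
  p <- data.frame(id = "x", seq = paste0(strrep("D", 9),
                                         strrep("I", 21), strrep("D", 10)))
  segs <- data.frame(start = 10L, end = 30L, mean_score = 4.5)
  expect_equal(extract_7tm_domain(p, segs), strrep("I", 21))
  expect_error(extract_7tm_domain(p, segs[0, ]), "no transmembrane")

  full <- data.frame(start = 1L, end = nchar(p$seq), mean_score = 1)
  expect_equal(extract_7tm_domain(p, full), p$seq)

  g <- generate_gpcr_like(7, seed = 41)
  v <- vet_gpcr_candidate(g$protein)
  expect_equal(v$domain_7tm,
               substring(g$protein$seq, v$tm_segments$start[1],
                         v$tm_segments$end[7]))
})

test_that("alignment distance matches an affine-gap DP oracle", {
  expect_equal(pairwise_distance("MKTAYIAK", "MKTAYIAK"), 0)
  expect_equal(pairwise_distance("AAAA", "WWWW"), 1)

  got <- pairwise_distance("HEAGAWGHEE", "PAWHEAE")
  want <- oracle_nw_distance("HEAGAWGHEE", "PAWHEAE")
  expect_equal(got, want$distance)

  set.seed(29)
  for (rep in 1:20) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    d1 <- pairwise_distance(a, b)
    expect_identical(d1, pairwise_distance(b, a))
    expect_true(d1 >= 0 && d1 <= 1)
  }
})

test_that("distance matrices are symmetric with zero diagonal", {
  doms <- c(r1 = "MKTAYIAKQR", r2 = "MKTAYIAKQA", r3 = "WWPLHEAGAW")
  d <- distance_matrix(doms)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(r1 = 0, r2 = 0, r3 = 0))
})

test_that("neighbor joining recovers additive trees", {
  # fixed 4-taxon additive matrix from a known tree
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    true_tree <- ape::rtree(n)
    true_tree$edge.length <- runif(nrow(true_tree$edge), 0.1, 1)
    d <- ape::cophenetic.phylo(true_tree)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    got <- nj_tree(d)
    expect_true(ape::dist.topo(ape::unroot(true_tree), got) == 0)
  }

  # three taxa: the unique unrooted topology, clamped branch lengths
  d3 <- matrix(c(0, .2, .4, .2, 0, .5, .4, .5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(d3)
  expect_equal(length(t3$tip.label), 3L)
  expect_true(all(t3$edge.length >= 0))

  bad <- d3
  bad[1, 2] <- 0.9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("family assignment follows the nearest labelled reference", {
  refs <- data.frame(
    id = c("refA", "refB"),
    family = c("A", "B"),
    seq = c(generate_gpcr_like(7, seed = 101)$protein$seq,
            generate_gpcr_like(7, seed = 202)$protein$seq),
    stringsAsFactors = FALSE
  )
  cand <- list(protein_id = "c1", length = nchar(refs$seq[1]),
               n_tm = 7L, passes_7tm = TRUE, domain_7tm = refs$seq[1])
  got <- assign_family(cand, refs)
  expect_equal(got$family, "A")
  expect_equal(got$nearest_dist, 0)

  # B-derived candidate at 10% mutational distance stays B
  g <- generate_gpcr_like(7, seed = 202, noise = 0.10)
  cand_b <- cand
  cand_b$domain_7tm <- g$protein$seq
  expect_equal(assign_family(cand_b, refs)$family, "B")

  # exact tie leaves the candidate unassigned with both families reported
  refs_tie <- data.frame(id = c("ra", "rb"), family = c("A", "B"),
                         seq = c("MKTAYIAK", "MKTAYIAK"),
                         stringsAsFactors = FALSE)
  cand_t <- cand
  cand_t$domain_7tm <- "MKTAYIAW"
  tie <- assign_family(cand_t, refs_tie)
  expect_equal(tie$family, "unassigned")
  expect_setequal(tie$tied_families, c("A", "B"))

  # empty panel: unassigned
  expect_equal(assign_family(cand, refs[0, ])$family, "unassigned")
})
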