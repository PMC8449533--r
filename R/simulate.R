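# Alphabets used by the generators. The clean payload alphabet excludes
# K/R (would create or extend cleavage sites), G (amide-donor ambiguity at
# fragment ends), C (disulfide bookkeeping stays deliberate) and Q
# (pyroglutamate is planted explicitly via payload choice, never by chance).
CLEAN_ALPHABET <- c("A", "S", "T", "N", "D", "E", "P", "H", "F", "Y",
                    "L", "I", "V", "M", "W")
TM_BLOCK_ALPHABET <- c("L", "I", "V", "F", "A")
POLAR_LOOP_ALPHABET <- c("D", "E", "N", "Q", "S", "T", "G", "K", "R")

#' Built-in clean-mode payload pool
#'
#' Multi-copy payloads drawn from well-known family exemplars that are safe
#' in clean mode (no basic-residue runs, no terminal K/R/G conflicts), used
#' by [generate_precursor()] when copies are given as family names.
#'
#' @return Data frame with columns `family`, `payload`, `amidated`.
#' @export
clean_payload_pool <- function() {
  data.frame(
    family = c("AST-A", "kinin", "GSEFLamide", "tachykinin", "sulfakinin",
               "RYamide", "sNPF", "myosuppressin", "RPCH", "CCAP",
               "corazonin", "ACP"),
    payload = c("AGPYSFGL", "QAFSAWA", "AGSEFL", "APSGFLGMR", "EFDDYGHMRF",
                "FYSQRY", "APPSMRLRF", "QDLDHVFLRF", "QLNFSPGW",
                "PFCNAFTGC", "QTFQYSRGWTN", "QITFSRSWVPQ"),
    amidated = TRUE,
    stringsAsFactors = FALSE
  )
}

.random_string <- function(n, alphabet) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# canonical signal peptide: M, a basic n-region residue, a hydrophobic core
# (A excluded so the -3/-1 context is unique), then the S-S-A cleavage
# context recognized by the heuristic's small-residue scoring
.random_signal <- function(len) {
  stopifnot(len >= 13L)
  paste0("M", "K", .random_string(len - 5L, c("L", "I", "V", "F")), "SSA")
}

.check_clean_payload <- function(payload, amidated) {
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", payload)) {
    stop("payload contains non-residue characters: ", payload)
  }
  # a terminal K/R is only unsafe when no amide-donor G separates it from
  # the planted site run
  if (grepl("[KR]{2,}", payload) || grepl("^[KR]", payload) ||
      (!amidated && grepl("[KR]$", payload))) {
    stop("clean-mode payload must not start/end with K/R or contain ",
         "basic runs: ", payload)
  }
  if (!amidated && grepl("G$", payload)) {
    stop("clean-mode non-amidated payload must not end in G: ", payload)
  }
  invisible(TRUE)
}

#' Generate a ground-truthed synthetic precursor
#'
#' Assembles a precursor from an optional signal peptide, an optional
#' precursor-related peptide (CPRP-like spacer), and one or more mature
#' peptide payloads each followed by a basic cleavage site. The returned
#' truth record states exactly what the annotation chain should recover.
#'
#' @param copies Data frame with columns `payload` (processed peptide
#'   sequence, without amide-donor glycine), `amidated` (flag) and
#'   optionally `family` and `site` (cleavage run after the copy, default
#'   `"KR"`). A plain character vector of family names draws payloads from
#'   the built-in clean pool.
#' @param signal_len Signal-peptide length in residues (19-35 typical), or
#'   `NA` for a signal-less precursor (an initiator M is still prepended).
#' @param cprp_len Length of a precursor-related peptide placed between
#'   signal and first copy (0 for none).
#' @param seed Integer seed; generation is deterministic under it.
#' @param noise Per-residue substitution rate in `[0, 0.2]` applied to
#'   payload and spacer residues (never to planted basic runs or the
#'   signal's cleavage context); substitutions are drawn from the clean
#'   alphabet. Clean-mode payload validation is skipped when `noise > 0`.
#' @return A list of class `synthetic_truth`: `protein` (record row),
#'   `signal_end`, `sites` (expected table), `fragments`, `matures`
#'   (expected rendered strings), `families`.
#' @export
generate_precursor <- function(copies, signal_len = 25L, cprp_len = 0L,
                               seed = 1L, noise = 0) {
  stopifnot(noise >= 0, noise <= 0.2)
  set.seed(seed)
  if (is.character(copies)) {
    pool <- clean_payload_pool()
    idx <- match(copies, pool$family)
    if (anyNA(idx)) stop("unknown pool family: ", copies[is.na(idx)][1L])
    copies <- pool[idx, , drop = FALSE]
  }
  stopifnot(nrow(copies) >= 1L)
  if (is.null(copies$site)) copies$site <- "KR"
  if (is.null(copies$family)) copies$family <- NA_character_
  stopifnot(all(grepl("^[KR]+$", copies$site)))
  if (noise == 0) {
    for (i in seq_len(nrow(copies))) {
      .check_clean_payload(copies$payload[i], copies$amidated[i])
    }
  }
  mutate <- function(s) {
    if (noise == 0 || !nzchar(s)) return(s)
    ch <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(ch)) < noise
    ch[hit] <- sample(CLEAN_ALPHABET, sum(hit), replace = TRUE)
    paste0(ch, collapse = "")
  }
  prefix <- if (is.na(signal_len)) "M" else .random_signal(signal_len)
  sp_end <- if (is.na(signal_len)) 0L else as.integer(signal_len)
  pieces <- prefix
  pos <- nchar(prefix)
  sites <- list()
  fragments <- list()
  matures <- character()
  add_fragment <- function(seq, site_run) {
    pieces <<- c(pieces, seq, site_run)
    start <- pos + 1L
    end <- pos + nchar(seq)
    fragments[[length(fragments) + 1L]] <<- data.frame(
      start = start, end = end, seq = seq, stringsAsFactors = FALSE)
    sites[[length(sites) + 1L]] <<- data.frame(
      start = end + 1L, basic_run = site_run,
      kind = c("monobasic", "dibasic", "tribasic")[min(nchar(site_run), 3L)],
      cut_after = end + nchar(site_run), stringsAsFactors = FALSE)
    pos <<- end + nchar(site_run)
  }
  is_copy <- logical()
  if (cprp_len > 0L) {
    cprp <- mutate(.random_string(cprp_len, CLEAN_ALPHABET))
    add_fragment(cprp, "KR")
    is_copy <- c(is_copy, FALSE)
  }
  for (i in seq_len(nrow(copies))) {
    payload <- mutate(copies$payload[i])
    frag_seq <- paste0(payload, if (copies$amidated[i]) "G" else "")
    add_fragment(frag_seq, copies$site[i])
    is_copy <- c(is_copy, TRUE)
  }
  protein_seq <- paste0(pieces, collapse = "")
  # signal-less precursors keep the initiator M on the first fragment
  if (is.na(signal_len) && length(fragments)) {
    fragments[[1L]]$start <- 1L
    fragments[[1L]]$seq <- substring(protein_seq, 1L, fragments[[1L]]$end)
  }
  # expected matures, reconstructed from the assembled fragments
  copy_idx <- which(is_copy)
  for (j in seq_along(copy_idx)) {
    fseq <- fragments[[copy_idx[j]]]$seq
    amid <- copies$amidated[j]
    if (amid) fseq <- substring(fseq, 1L, nchar(fseq) - 1L)
    matures <- c(matures, render_mature(fseq, amidated = amid,
                                        pyroglu = startsWith(fseq, "Q")))
  }
  structure(list(
    protein = data.frame(id = paste0("synth_prec_", seed),
                         seq = protein_seq, stringsAsFactors = FALSE),
    signal_end = sp_end,
    sites = do.call(rbind, sites),
    fragments = do.call(rbind, fragments),
    matures = matures,
    families = copies$family
  ), class = "synthetic_truth")
}

#' Reverse-translate a protein into a transcript with UTRs
#'
#' Codons are drawn uniformly from the standard code; the coding sequence
#' is preceded by a random 5' UTR ending in an in-frame stop (so the ORF
#' scanner recovers exactly the intended start) and followed by a stop
#' codon and a random 3' UTR.
#'
#' @param protein Protein string (non-empty).
#' @param seed Integer seed.
#' @param utr_len Range of UTR lengths (both ends), default 20-40 nt.
#' @return List with `transcript` (nucleotide string), `cds_start`,
#'   `cds_end` (1-based inclusive, stop codon included).
#' @export
reverse_translate <- function(protein, seed = 1L, utr_len = c(20L, 40L)) {
  stopifnot(nzchar(protein))
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  aa <- strsplit(protein, "")[[1]]
  if (anyNA(match(aa, names(by_aa)))) {
    stop("protein contains residues outside the standard alphabet")
  }
  codons <- vapply(aa, function(a) {
    cs <- by_aa[[a]]
    cs[sample.int(length(cs), 1L)]
  }, "")
  utr5 <- .random_string(sample(seq(utr_len[1], utr_len[2]), 1L),
                         c("A", "C", "G", "T"))
  utr3 <- .random_string(sample(seq(utr_len[1], utr_len[2]), 1L),
                         c("A", "C", "G", "T"))
  utr5 <- paste0(utr5, "TAA")   # in-frame stop guarding the ORF start
  stop_codon <- by_aa[["*"]][sample.int(3L, 1L)]
  cds <- paste0(paste0(codons, collapse = ""), stop_codon)
  list(
    transcript = paste0(utr5, cds, utr3),
    cds_start = nchar(utr5) + 1L,
    cds_end = nchar(utr5) + nchar(cds)
  )
}

#' Generate a GPCR-like protein with known transmembrane spans
#'
#' `n_tm` hydrophobic blocks (19-23 residues from L/I/V/F/A) are separated
#' and flanked by polar loops (12-25 residues from D/E/N/Q/S/T/G/K/R).
#'
#' @param n_tm Number of membrane-spanning blocks (0-10).
#' @param seed Integer seed.
#' @param noise Per-residue substitution rate (uniform over the 20
#'   residues), applied to the whole protein.
#' @return List with `protein` (record row) and `tm_spans` (data frame
#'   `start`/`end` of the planted blocks).
#' @export
generate_gpcr_like <- function(n_tm, seed = 1L, noise = 0) {
  stopifnot(n_tm >= 0L, n_tm <= 10L)
  set.seed(seed)
  pieces <- .random_string(sample(12:25, 1L), POLAR_LOOP_ALPHABET)
  spans <- list()
  pos <- nchar(pieces)
  for (i in seq_len(n_tm)) {
    block_len <- sample(19:23, 1L)
    block <- .random_string(block_len, TM_BLOCK_ALPHABET)
    loop <- .random_string(sample(12:25, 1L), POLAR_LOOP_ALPHABET)
    spans[[i]] <- data.frame(start = pos + 1L, end = pos + block_len)
    pieces <- paste0(pieces, block, loop)
    pos <- pos + block_len + nchar(loop)
  }
  seq <- pieces
  if (n_tm == 0L && nchar(seq) < 160L) {
    seq <- paste0(seq, .random_string(160L - nchar(seq),
                                      POLAR_LOOP_ALPHABET))
  }
  if (noise > 0) {
    ch <- strsplit(seq, "")[[1]]
    hit <- stats::runif(length(ch)) < noise
    ch[hit] <- sample(names(KD_SCALE), sum(hit), replace = TRUE)
    seq <- paste0(ch, collapse = "")
  }
  list(
    protein = data.frame(id = paste0("synth_gpcr_", n_tm, "tm_", seed),
                         seq = seq, stringsAsFactors = FALSE),
    tm_spans = if (n_tm > 0L) do.call(rbind, spans)
               else data.frame(start = integer(), end = integer())
  )
}

#' Generate a mixed synthetic dataset with a truth manifest
#'
#' Writes a nucleotide FASTA of precursor transcripts, a protein FASTA of
#' GPCR-like candidates, and a JSON truth manifest for end-to-end tests.
#'
#' @param n_precursors,n_gpcrs Numbers of records to generate.
#' @param noise Substitution rate in `[0, 0.2]`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named: `transcripts`, `gpcrs`, `truth`) and
#'   `truth` (the manifest as a list).
#' @export
generate_dataset <- function(n_precursors, n_gpcrs, noise = 0, seed = 1L,
                             dir = tempfile("npmine_dataset_")) {
  stopifnot(noise >= 0, noise <= 0.2)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  pool <- clean_payload_pool()
  prec_seeds <- sample.int(1e6L, max(n_precursors, 1L))
  gpcr_seeds <- sample.int(1e6L, max(n_gpcrs, 1L))
  precursors <- list()
  transcripts <- data.frame(id = character(), seq = character(),
                            stringsAsFactors = FALSE)
  if (n_precursors > 0L) {
    for (i in seq_len(n_precursors)) {
      fams <- sample(pool$family, sample(1:5, 1L), replace = TRUE)
      # a precursor-related spacer peptide keeps every precursor above the
      # neuropeptide-track ORF minimum, as in real prohormones
      truth <- generate_precursor(fams,
                                  signal_len = sample(19:35, 1L),
                                  cprp_len = sample(25:40, 1L),
                                  seed = prec_seeds[i],
                                  noise = noise)
      id <- paste0("prec", i)
      truth$protein$id <- id
      rt <- reverse_translate(truth$protein$seq, seed = prec_seeds[i])
      transcripts <- rbind(transcripts,
                           data.frame(id = paste0("tx_", id),
                                      seq = rt$transcript,
                                      stringsAsFactors = FALSE))
      precursors[[id]] <- list(
        id = id, transcript_id = paste0("tx_", id),
        protein = truth$protein$seq, signal_end = truth$signal_end,
        matures = truth$matures, families = truth$families
      )
    }
  }
  gpcrs <- list()
  gpcr_prot <- data.frame(id = character(), seq = character(),
                          stringsAsFactors = FALSE)
  if (n_gpcrs > 0L) {
    # majority true 7TM receptors, remainder incomplete topologies
    n_tm_choices <- c(rep(7L, ceiling(n_gpcrs * 0.6)),
                      sample(c(4L, 5L, 6L, 8L),
                             n_gpcrs - ceiling(n_gpcrs * 0.6),
                             replace = TRUE))
    for (i in seq_len(n_gpcrs)) {
      g <- generate_gpcr_like(n_tm_choices[i], seed = gpcr_seeds[i],
                              noise = noise)
      id <- paste0("gpcr", i)
      g$protein$id <- id
      gpcr_prot <- rbind(gpcr_prot, g$protein)
      gpcrs[[id]] <- list(id = id, n_tm = n_tm_choices[i],
                          expect_7tm = n_tm_choices[i] == 7L)
    }
  }
  paths <- c(transcripts = file.path(dir, "transcripts.fasta"),
             gpcrs = file.path(dir, "gpcrs.fasta"),
             truth = file.path(dir, "truth.json"))
  write_fasta(transcripts, paths[["transcripts"]])
  write_fasta(gpcr_prot, paths[["gpcrs"]])
  truth <- list(seed = seed, noise = noise,
                precursors = unname(precursors), gpcrs = unname(gpcrs))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  list(paths = paths, truth = truth)
}
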