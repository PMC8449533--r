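#' Pipeline configuration
#'
#' Flat key-value configuration shared by the two pipeline tracks. All
#' defaults are recorded in every run's log header for provenance.
#'
#' @param input Path to the input FASTA.
#' @param input_type `"nucleotide"` (ORFs are extracted first) or
#'   `"protein"` (records are used as precursors/candidates directly).
#' @param out_dir Output directory.
#' @param min_orf_neuropeptide Minimum ORF length (aa) on the neuropeptide
#'   track (default 50).
#' @param min_orf_gpcr Minimum protein length on the receptor track
#'   (default 150; shorter candidates are deemed too short to vet).
#' @param tm_band Accepted transmembrane-segment counts (default exactly 7).
#' @param rules Cleavage ruleset ([cleavage_rules()]).
#' @param signal_cfg Signal-stage configuration ([signal_config()]).
#' @param external_signals Optional data frame `id`/`sp_end` of externally
#'   computed signal spans.
#' @param ptm PTM configuration ([ptm_config()]).
#' @param motif_tsv Optional user motif TSV appended to the built-in
#'   library.
#' @param reference_panel Optional labelled reference FASTA for family
#'   assignment ([read_reference_panel()]).
#' @param external_tm Optional external TM-annotation table
#'   (see [vet_gpcr_candidate()]).
#' @param seed Integer seed recorded in the log (the tracks themselves are
#'   deterministic).
#' @return Named list of settings.
#' @export
pipeline_config <- function(input, input_type = c("nucleotide", "protein"),
                            out_dir = "npmine_out",
                            min_orf_neuropeptide = 50L,
                            min_orf_gpcr = 150L,
                            tm_band = 7L,
                            rules = cleavage_rules(),
                            signal_cfg = signal_config(),
                            external_signals = NULL,
                            ptm = ptm_config(),
                            motif_tsv = NULL,
                            reference_panel = NULL,
                            external_tm = NULL,
                            seed = 1L) {
  input_type <- match.arg(input_type)
  stopifnot(file.exists(input))
  if (!is.null(motif_tsv)) stopifnot(file.exists(motif_tsv))
  if (!is.null(reference_panel)) stopifnot(file.exists(reference_panel))
  list(input = input, input_type = input_type, out_dir = out_dir,
       min_orf_neuropeptide = as.integer(min_orf_neuropeptide),
       min_orf_gpcr = as.integer(min_orf_gpcr), tm_band = tm_band,
       rules = rules, signal_cfg = signal_cfg,
       external_signals = external_signals, ptm = ptm,
       motif_tsv = motif_tsv, reference_panel = reference_panel,
       external_tm = external_tm, seed = as.integer(seed))
}

.log_lines <- function(path, lines) {
  cat(paste0(lines, "\n", collapse = ""), file = path, append = TRUE)
  invisible(NULL)
}

.track_proteins <- function(cfg, min_len) {
  if (cfg$input_type == "protein") {
    read_fasta(cfg$input, "protein")
  } else {
    tx <- read_fasta(cfg$input, "nucleotide")
    orfs <- lapply(seq_len(nrow(tx)), function(i) {
      find_orfs(tx[i, ], min_len_aa = min_len)
    })
    if (length(orfs) == 0L) {
      find_orfs(data.frame(id = "none", seq = "", stringsAsFactors = FALSE),
                min_len_aa = 1L)
    } else {
      out <- do.call(rbind, orfs)
      rownames(out) <- NULL
      out
    }
  }
}

#' Run the neuropeptide annotation track
#'
#' ORF extraction (for nucleotide input), signal-peptide prediction,
#' cleavage-site scanning, fragment excision, PTM processing and family
#' classification, with all reports written under `cfg$out_dir`:
#' mature-peptide TSV, per-precursor JSON, GFF3-like features, family
#' assignment TSV and family tally TSV, plus a run log with per-stage
#' record counts.
#'
#' @param cfg Configuration from [pipeline_config()].
#' @return Invisibly, a list with `annotations`, `assignments`, `tally`,
#'   `paths`.
#' @export
run_neuropeptide_track <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(cfg$out_dir, "neuropeptide_track.log")
  cat("", file = log)
  .log_lines(log, c("npmine neuropeptide track",
                    paste0("input=", cfg$input),
                    paste0("input_type=", cfg$input_type),
                    paste0("min_orf=", cfg$min_orf_neuropeptide),
                    paste0("seed=", cfg$seed)))
  proteins <- .track_proteins(cfg, cfg$min_orf_neuropeptide)
  .log_lines(log, paste0("candidate_precursors=", nrow(proteins)))
  annotations <- lapply(seq_len(nrow(proteins)), function(i) {
    annotate_precursor(proteins[i, ], signal_cfg = cfg$signal_cfg,
                       external_signals = cfg$external_signals,
                       rules = cfg$rules, ptm = cfg$ptm)
  })
  lib <- compile_motif_library(cfg$motif_tsv)
  cls <- classify_all(annotations, lib)
  .log_lines(log, c(
    paste0("mature_peptides=", nrow(cls$assignments)),
    paste0("classified=", sum(cls$assignments$family != "unclassified")),
    paste0("families=", nrow(cls$tally))))
  paths <- write_annotation_report(annotations, cfg$out_dir)
  assign_path <- file.path(cfg$out_dir, "family_assignments.tsv")
  utils::write.table(cls$assignments, assign_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tally_path <- file.path(cfg$out_dir, "family_tally.tsv")
  utils::write.table(cls$tally, tally_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, assignments = assign_path, tally = tally_path,
             log = log)
  invisible(list(annotations = annotations, assignments = cls$assignments,
                 tally = cls$tally, paths = paths))
}

#' Run the GPCR triage track
#'
#' Length filter, hydropathy-based 7TM vetting, 7TM-domain extraction,
#' optional nearest-reference family assignment, pairwise distances and a
#' neighbor-joining tree (written as newick when at least three domains are
#' available). A candidate report TSV and run log are written under
#' `cfg$out_dir`.
#'
#' @param cfg Configuration from [pipeline_config()].
#' @return Invisibly, a list with `candidates` (report data frame),
#'   `rejected` (too-short records), `tree` (phylo or `NULL`), `paths`.
#' @export
run_gpcr_track <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(cfg$out_dir, "gpcr_track.log")
  cat("", file = log)
  .log_lines(log, c("npmine gpcr track",
                    paste0("input=", cfg$input),
                    paste0("min_len=", cfg$min_orf_gpcr),
                    paste0("tm_band=", paste(cfg$tm_band, collapse = ",")),
                    paste0("seed=", cfg$seed)))
  proteins <- .track_proteins(cfg, cfg$min_orf_gpcr)
  parts <- filter_by_length(proteins, cfg$min_orf_gpcr)
  .log_lines(log, c(paste0("input_proteins=", nrow(proteins)),
                    paste0("retained=", nrow(parts$retained)),
                    paste0("rejected_short=", nrow(parts$rejected))))
  refs <- if (!is.null(cfg$reference_panel)) {
    read_reference_panel(cfg$reference_panel)
  }
  cands <- lapply(seq_len(nrow(parts$retained)), function(i) {
    cand <- vet_gpcr_candidate(parts$retained[i, ], band = cfg$tm_band,
                               external = cfg$external_tm)
    if (!is.null(refs)) cand <- assign_family(cand, refs)
    cand
  })
  report <- data.frame(
    id = vapply(cands, `[[`, "", "protein_id"),
    length = vapply(cands, `[[`, 0L, "length"),
    n_tm = vapply(cands, `[[`, 0L, "n_tm"),
    passes_7tm = vapply(cands, `[[`, NA, "passes_7tm"),
    family = vapply(cands, function(x) {
      if (is.null(x$family)) NA_character_ else x$family
    }, ""),
    nearest_ref = vapply(cands, function(x) {
      if (is.null(x$nearest_ref)) NA_character_ else x$nearest_ref
    }, ""),
    distance = vapply(cands, function(x) {
      if (is.null(x$nearest_dist)) NA_real_ else x$nearest_dist
    }, numeric(1)),
    margin = vapply(cands, function(x) {
      if (is.null(x$margin)) NA_real_ else x$margin
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  report_path <- file.path(cfg$out_dir, "gpcr_candidates.tsv")
  utils::write.table(report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(report = report_path, log = log)
  domains <- vapply(cands, `[[`, "", "domain_7tm")
  names(domains) <- report$id
  domains <- domains[!is.na(domains)]
  if (!is.null(refs) && nrow(refs)) {
    ref_dom <- refs$seq
    names(ref_dom) <- refs$id
    domains <- c(domains, ref_dom)
  }
  tree <- NULL
  if (length(domains) >= 3L) {
    d <- distance_matrix(domains)
    tree <- nj_tree(d)
    tree_path <- file.path(cfg$out_dir, "gpcr_tree.nwk")
    ape::write.tree(tree, tree_path)
    paths <- c(paths, tree = tree_path)
    .log_lines(log, paste0("tree_leaves=", length(domains)))
  } else {
    .log_lines(log, "tree_leaves=0 (fewer than 3 domains; no tree)")
  }
  invisible(list(candidates = report, rejected = parts$rejected,
                 tree = tree, paths = paths))
}
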