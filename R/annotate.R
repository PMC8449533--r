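#' Annotate a precursor protein end to end
#'
#' Chains the precursor stages: signal-peptide prediction, cleavage-site
#' scanning (runs inside the signal span excluded), fragment excision and
#' PTM processing. Precursors without a predicted signal peptide are
#' annotated with an absent signal rather than rejected.
#'
#' @param protein Protein record row (fields `id`, `seq`).
#' @param signal_cfg Configuration from [signal_config()].
#' @param external_signals Optional external signal-span table
#'   (see [predict_signal_peptide()]).
#' @param rules Cleavage ruleset from [cleavage_rules()].
#' @param ptm Configuration from [ptm_config()].
#' @return A `precursor_annotation` list with `protein_id`, `length`,
#'   `signal`, `sites`, `fragments`, `matures`.
#' @export
annotate_precursor <- function(protein,
                               signal_cfg = signal_config(),
                               external_signals = NULL,
                               rules = cleavage_rules(),
                               ptm = ptm_config()) {
  signal <- predict_signal_peptide(protein, signal_cfg, external_signals)
  sp_end <- if (isTRUE(signal$present)) signal$end else 0L
  sites <- find_cleavage_sites(protein, rules, signal_end = sp_end)
  fragments <- excise_fragments(protein, signal, sites)
  matures <- lapply(seq_len(nrow(fragments)), function(i) {
    apply_ptm(fragments[i, ], ptm)
  })
  structure(
    list(protein_id = protein$id, length = nchar(protein$seq),
         signal = signal, sites = sites, fragments = fragments,
         matures = matures),
    class = "precursor_annotation"
  )
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat("Precursor", x$protein_id, "(", x$length, "aa )\n")
  if (isTRUE(x$signal$present)) {
    cat("  signal peptide: 1-", x$signal$end, " [", x$signal$method, "]\n",
        sep = "")
  } else {
    cat("  signal peptide: absent\n")
  }
  cat("  cleavage sites:", if (nrow(x$sites)) paste0(
    x$sites$basic_run, "@", x$sites$start, collapse = ", ") else "none", "\n")
  for (m in x$matures) {
    cat("  mature:", m$rendered,
        sprintf("(%d-%d, %d C)\n", m$source_start, m$source_end, m$cys_count))
  }
  invisible(x)
}

#' Convert annotations to a flat mature-peptide table
#'
#' @param annotations A list of `precursor_annotation` objects.
#' @return Data frame with one row per mature peptide.
#' @export
mature_table <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    if (length(a$matures) == 0L) return(NULL)
    data.frame(
      protein_id = a$protein_id,
      seq = vapply(a$matures, `[[`, "", "seq"),
      rendered = vapply(a$matures, `[[`, "", "rendered"),
      amidated = vapply(a$matures, `[[`, NA, "amidated"),
      pyroglu = vapply(a$matures, `[[`, NA, "pyroglu"),
      start = vapply(a$matures, `[[`, 0L, "source_start"),
      end = vapply(a$matures, `[[`, 0L, "source_end"),
      cys_count = vapply(a$matures, function(m) as.integer(m$cys_count), 0L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), seq = character(),
                      rendered = character(), amidated = logical(),
                      pyroglu = logical(), start = integer(), end = integer(),
                      cys_count = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write annotation reports
#'
#' Writes a TSV of mature peptides, a JSON report (one object per precursor
#' with signal span, sites, fragments and rendered matures) and GFF3-like
#' feature lines (`signal_peptide` / `cleavage_site` / `mature_peptide`) on
#' protein coordinates.
#'
#' @param annotations List of `precursor_annotation` objects.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_annotation_report <- function(annotations, dir, prefix = "precursors") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, "_matures.tsv"))
  utils::write.table(mature_table(annotations), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, ".json"))
  payload <- lapply(annotations, function(a) {
    list(
      protein_id = a$protein_id, length = a$length,
      signal = if (isTRUE(a$signal$present)) {
        list(start = 1L, end = a$signal$end, score = a$signal$score,
             method = a$signal$method)
      },
      sites = a$sites, fragments = a$fragments,
      matures = lapply(a$matures, function(m) {
        m[c("seq", "rendered", "amidated", "pyroglu",
            "source_start", "source_end", "cys_count")]
      })
    )
  })
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       null = "null")
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  lines <- unlist(lapply(annotations, function(a) {
    feats <- character()
    if (isTRUE(a$signal$present)) {
      feats <- c(feats, paste(a$protein_id, "npmine", "signal_peptide", 1,
                              a$signal$end, a$signal$score, ".", ".",
                              "ID=SP", sep = "\t"))
    }
    if (nrow(a$sites)) {
      feats <- c(feats, paste(a$protein_id, "npmine", "cleavage_site",
                              a$sites$start, a$sites$cut_after, ".", ".", ".",
                              paste0("run=", a$sites$basic_run), sep = "\t"))
    }
    if (length(a$matures)) {
      feats <- c(feats, vapply(a$matures, function(m) {
        paste(a$protein_id, "npmine", "mature_peptide", m$source_start,
              m$source_end, ".", ".", ".", paste0("rendered=", m$rendered),
              sep = "\t")
      }, ""))
    }
    feats
  }))
  writeLines(c("##gff-version 3", lines), gff)
  invisible(c(tsv = tsv, json = js, gff3 = gff))
}
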