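#' Prohormone cleavage ruleset
#'
#' Controls which basic-residue motifs count as convertase cleavage sites.
#' Defaults follow the standard prohormone-processing conventions for
#' arthropod precursors: all four dibasic pairs and tribasic runs are
#' enabled; interior monobasic sites are off (their cleavage is strongly
#' context-dependent) but an isolated K/R within the last `terminal_window`
#' residues of the precursor is accepted, which covers the common
#' near-C-terminal monobasic sites of e.g. agatoxin-like and myosuppressin
#' precursors.
#'
#' @param dibasic Character vector of enabled dibasic pairs.
#' @param tribasic Enable tribasic runs (e.g. RKR).
#' @param monobasic Character vector from `c("K", "R")` enabling interior
#'   monobasic sites (default none).
#' @param terminal_monobasic Accept an isolated terminal K/R.
#' @param terminal_window Number of C-terminal residues within which an
#'   isolated K/R counts as terminal (default 4).
#' @return A named list of rule flags.
#' @export
cleavage_rules <- function(dibasic = c("KR", "KK", "RR", "RK"),
                           tribasic = TRUE,
                           monobasic = character(),
                           terminal_monobasic = TRUE,
                           terminal_window = 4L) {
  stopifnot(all(dibasic %in% c("KR", "KK", "RR", "RK")),
            all(monobasic %in% c("K", "R")))
  list(dibasic = dibasic, tribasic = tribasic, monobasic = monobasic,
       terminal_monobasic = terminal_monobasic,
       terminal_window = as.integer(terminal_window))
}

.empty_sites <- function() {
  data.frame(start = integer(), basic_run = character(), kind = character(),
             cut_after = integer(), stringsAsFactors = FALSE)
}

#' Find prohormone cleavage sites
#'
#' Maximal runs of basic residues (K/R) are matched greedily left to right
#' and classified as monobasic, dibasic or tribasic (runs longer than three
#' are treated as one tribasic-kind site spanning the whole run). A run is
#' reported only if its class is enabled in the ruleset; runs of three with
#' tribasic disabled fall back to a dibasic site on their last two residues
#' when that pair is enabled. Runs starting inside a given signal-peptide
#' span are excluded.
#'
#' @param protein A protein record row (fields `id`, `seq`).
#' @param rules Ruleset from [cleavage_rules()].
#' @param signal_end Last residue of the signal peptide, or 0 for none.
#' @return Data frame with columns `start` (1-based position of the first
#'   basic residue), `basic_run`, `kind`, `cut_after`.
#' @export
find_cleavage_sites <- function(protein, rules = cleavage_rules(),
                                signal_end = 0L) {
  seq <- protein$seq
  len <- nchar(seq)
  m <- gregexpr("[KR]+", seq)[[1]]
  if (m[1] == -1L) return(.empty_sites())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  rows <- list()
  for (i in seq_along(starts)) {
    s <- starts[i]
    L <- lens[i]
    if (!is.na(signal_end) && signal_end > 0L && s <= signal_end) next
    run <- substring(seq, s, s + L - 1L)
    if (L == 1L) {
      # terminal: within the last terminal_window residues AND the final
      # basic run of the sequence (nothing basic downstream)
      terminal <- isTRUE(rules$terminal_monobasic) &&
        s > len - rules$terminal_window && i == length(starts)
      interior <- run %in% rules$monobasic
      if (!terminal && !interior) next
      kind <- "monobasic"
    } else if (L == 2L) {
      if (!(run %in% rules$dibasic)) next
      kind <- "dibasic"
    } else {
      if (isTRUE(rules$tribasic)) {
        kind <- "tribasic"
      } else {
        tail2 <- substring(run, L - 1L, L)
        if (!(tail2 %in% rules$dibasic)) next
        s <- s + L - 2L
        run <- tail2
        L <- 2L
        kind <- "dibasic"
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, basic_run = run, kind = kind,
      cut_after = s + L - 1L, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(.empty_sites())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Excise precursor fragments between signal peptide and cleavage sites
#'
#' Fragments are the maximal residue intervals left after removing the
#' signal span and the basic runs of the cleavage sites; empty intervals are
#' dropped. By default basic runs are consumed (they belong to no fragment);
#' `retain_basics = TRUE` instead keeps each run on the C-terminus of the
#' preceding fragment, for workflows that trim basics during the PTM stage.
#'
#' @param protein Protein record row.
#' @param signal A signal prediction as returned by
#'   [predict_signal_peptide()] (or `NULL` for none).
#' @param sites Cleavage-site table from [find_cleavage_sites()].
#' @param retain_basics Keep basic runs on the upstream fragment.
#' @return Data frame with columns `start`, `end`, `seq`, `role` (all
#'   `"candidate_mature"`; role refinement is downstream bookkeeping).
#' @export
excise_fragments <- function(protein, signal = NULL, sites = .empty_sites(),
                             retain_basics = FALSE) {
  len <- nchar(protein$seq)
  sp_end <- if (!is.null(signal) && isTRUE(signal$present)) signal$end else 0L
  if (nrow(sites) > 1L) {
    o <- order(sites$start)
    sites <- sites[o, , drop = FALSE]
    if (any(sites$start[-1L] <= sites$cut_after[-nrow(sites)])) {
      stop("overlapping cleavage sites for ", protein$id)
    }
  }
  if (nrow(sites) > 0L && sp_end > 0L && any(sites$start <= sp_end)) {
    stop("cleavage site inside signal span for ", protein$id)
  }
  cuts_lo <- c(sp_end, if (retain_basics) sites$cut_after else sites$start - 1L)
  cuts_hi <- c(sp_end, sites$cut_after)
  # fragment i spans (cuts_hi[i] + 1) .. (cuts_lo[i+1]); last runs to the end
  frag_start <- cuts_hi + 1L
  frag_end <- c(cuts_lo[-1L], len)
  keep <- frag_start <= frag_end
  frag_start <- frag_start[keep]
  frag_end <- frag_end[keep]
  if (length(frag_start) == 0L) {
    warning("precursor ", protein$id, " yields no fragments")
    return(data.frame(start = integer(), end = integer(), seq = character(),
                      role = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    start = frag_start, end = frag_end,
    seq = substring(protein$seq, frag_start, frag_end),
    role = "candidate_mature", stringsAsFactors = FALSE
  )
}
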