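#' PTM processing configuration
#'
#' @param pyroglu_from_E Also allow N-terminal glutamate (E) to cyclize to
#'   pyroglutamate (off by default; glutamine-derived pQ is the common case).
#' @param strip_trailing_basics Remove residual C-terminal K/R left by a
#'   basics-retaining excision policy before applying PTM rules.
#' @return Named list of PTM flags.
#' @export
ptm_config <- function(pyroglu_from_E = FALSE, strip_trailing_basics = TRUE) {
  list(pyroglu_from_E = pyroglu_from_E,
       strip_trailing_basics = strip_trailing_basics)
}

#' Render a processed peptide in pQ/amide display notation
#'
#' @param seq Processed peptide string.
#' @param amidated,pyroglu PTM flags.
#' @return Display string, e.g. `"pQLNFSPGWamide"`.
#' @export
render_mature <- function(seq, amidated = FALSE, pyroglu = FALSE) {
  paste0(if (pyroglu) "p" else "", seq, if (amidated) "amide" else "")
}

#' Apply post-translational processing rules to an excised fragment
#'
#' A C-terminal glycine is interpreted as an amide donor: it is removed and
#' the peptide flagged as amidated. An N-terminal glutamine (optionally
#' glutamate) flags pyroglutamate cyclization; the residue stays in the
#' sequence and is displayed with a `p` prefix. Residual trailing basic
#' residues are stripped first when the configuration says so.
#'
#' @param fragment A fragment row (field `seq`, optionally `start`/`end`)
#'   or a plain string.
#' @param rules Configuration from [ptm_config()].
#' @return A list with `seq`, `amidated`, `pyroglu`, `rendered`,
#'   `cys_count`, and (when available) `source_start`/`source_end`.
#' @export
apply_ptm <- function(fragment, rules = ptm_config()) {
  seq <- if (is.character(fragment)) fragment else fragment$seq
  stopifnot(nzchar(seq))
  if (isTRUE(rules$strip_trailing_basics)) {
    seq <- sub("[KR]+$", "", seq)
  }
  amidated <- FALSE
  if (grepl("G$", seq) && nchar(seq) > 1L) {
    amidated <- TRUE
    seq <- substring(seq, 1L, nchar(seq) - 1L)
  }
  first <- substring(seq, 1L, 1L)
  pyroglu <- first == "Q" || (isTRUE(rules$pyroglu_from_E) && first == "E")
  out <- list(
    seq = seq, amidated = amidated, pyroglu = pyroglu,
    rendered = render_mature(seq, amidated, pyroglu),
    cys_count = count_cysteines(seq)
  )
  if (!is.character(fragment)) {
    out$source_start <- fragment$start
    out$source_end <- fragment$end
  }
  out
}

#' Invert the pQ/amide display notation
#'
#' Exact inverse of the rendering applied by [apply_ptm()]: an `amide`
#' suffix restores the donor glycine and a `pQ`/`pE` prefix restores the
#' plain residue, recovering the unprocessed fragment string.
#'
#' @param rendered Display string in pQ/pE/amide convention.
#' @return The unprocessed fragment string.
#' @export
invert_rendering <- function(rendered) {
  m <- regmatches(rendered,
                  regexec("^(p?)([A-Z]+?)(amide)?$", rendered))[[1]]
  if (length(m) == 0L) stop("malformed rendered peptide: ", rendered)
  if (m[2] == "p" && !substring(m[3], 1L, 1L) %in% c("Q", "E")) {
    stop("pyroglutamate prefix must precede Q or E in: ", rendered)
  }
  paste0(m[3], if (m[4] == "amide") "G" else "")
}

#' Count cysteine residues
#'
#' @param m A mature-peptide list (field `seq`) or a plain string.
#' @return Number of C residues.
#' @export
count_cysteines <- function(m) {
  seq <- if (is.character(m)) m else m$seq
  lengths(regmatches(seq, gregexpr("C", seq, fixed = TRUE)))
}
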