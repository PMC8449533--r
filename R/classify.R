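#' Cysteine-skeleton matching parameters
#'
#' The CHH/MIH/ITP superfamily is recognized not by a short linear motif but
#' by its skeleton of six cysteines at loosely conserved spacing on a
#' peptide of hormone length.
#'
#' @param n_cys Required cysteine count.
#' @param len_range Allowed peptide length (residues).
#' @param gap_range Allowed number of residues between consecutive
#'   cysteines.
#' @return Named list of parameters.
#' @export
cys_skeleton_params <- function(n_cys = 6L, len_range = c(50L, 100L),
                                gap_range = c(1L, 35L)) {
  list(n_cys = n_cys, len_range = len_range, gap_range = gap_range)
}

.matches_cys_skeleton <- function(seq, params = cys_skeleton_params()) {
  len <- nchar(seq)
  if (len < params$len_range[1] || len > params$len_range[2]) return(FALSE)
  pos <- gregexpr("C", seq, fixed = TRUE)[[1]]
  if (pos[1] == -1L || length(pos) != params$n_cys) return(FALSE)
  gaps <- diff(pos) - 1L
  all(gaps >= params$gap_range[1] & gaps <= params$gap_range[2])
}

.ptm_gate <- function(required, flag) {
  required == "either" || (required == "yes") == isTRUE(flag)
}

#' Classify a mature peptide against the motif library
#'
#' Every motif is tested under its anchor and PTM constraints. The winner is
#' the matching motif of highest specificity; ties break by longer matched
#' span, then lexical family order. Peptides matching no motif are
#' `"unclassified"`.
#'
#' @param m A mature peptide: a list with `seq`, `amidated`, `pyroglu`
#'   (as produced by [apply_ptm()]) or a rendered display string.
#' @param lib Motif library from [compile_motif_library()].
#' @param skeleton Parameters from [cys_skeleton_params()].
#' @return List with `family`, `score`, `matched_start`, `matched_end`,
#'   `competing` (character vector of runner-up families, best first).
#' @export
classify_peptide <- function(m, lib = compile_motif_library(),
                             skeleton = cys_skeleton_params()) {
  stopifnot(nrow(lib) > 0L)
  if (is.character(m)) m <- parse_rendered(m)
  hits <- list()
  for (i in seq_len(nrow(lib))) {
    row <- lib[i, ]
    if (!.ptm_gate(row$requires_amide, m$amidated)) next
    if (!.ptm_gate(row$requires_pyroglu, m$pyroglu)) next
    if (row$kind == "cys_skeleton") {
      if (!.matches_cys_skeleton(m$seq, skeleton)) next
      span <- c(1L, nchar(m$seq))
    } else {
      re <- switch(row$anchor,
        c_terminal = paste0(row$regex, "$"),
        n_terminal = paste0("^", row$regex),
        full_match = paste0("^", row$regex, "$"),
        anywhere = row$regex)
      hit <- regexpr(re, m$seq)
      if (hit == -1L) next
      span <- c(as.integer(hit),
                as.integer(hit) + attr(hit, "match.length") - 1L)
    }
    hits[[length(hits) + 1L]] <- list(family = row$family,
                                      score = row$specificity, span = span)
  }
  if (length(hits) == 0L) {
    return(list(family = "unclassified", score = 0L,
                matched_start = NA_integer_, matched_end = NA_integer_,
                competing = character()))
  }
  score <- vapply(hits, `[[`, 0L, "score")
  span_len <- vapply(hits, function(h) diff(h$span) + 1L, 0L)
  fam <- vapply(hits, `[[`, "", "family")
  o <- order(-score, -span_len, fam)
  best <- hits[[o[1L]]]
  list(family = best$family, score = best$score,
       matched_start = best$span[1L], matched_end = best$span[2L],
       competing = fam[o][-1L])
}

#' Classify all mature peptides of a set of precursor annotations
#'
#' @param annotations List of `precursor_annotation` objects (or a mature
#'   table from [mature_table()]).
#' @param lib Motif library.
#' @param skeleton Cys-skeleton parameters.
#' @return List with `assignments` (one row per mature peptide, columns of
#'   [mature_table()] plus `family`, `score`, `competing`) and `tally`
#'   (per-family distinct-precursor and peptide counts).
#' @export
classify_all <- function(annotations, lib = compile_motif_library(),
                         skeleton = cys_skeleton_params()) {
  tab <- if (is.data.frame(annotations)) annotations
         else mature_table(annotations)
  if (nrow(tab) == 0L) {
    tab$family <- character()
    tab$score <- integer()
    tab$competing <- character()
    return(list(assignments = tab,
                tally = data.frame(family = character(),
                                   n_precursors = integer(),
                                   n_peptides = integer(),
                                   stringsAsFactors = FALSE)))
  }
  res <- lapply(seq_len(nrow(tab)), function(i) {
    classify_peptide(list(seq = tab$seq[i], amidated = tab$amidated[i],
                          pyroglu = tab$pyroglu[i]), lib, skeleton)
  })
  tab$family <- vapply(res, `[[`, "", "family")
  tab$score <- vapply(res, `[[`, 0L, "score")
  tab$competing <- vapply(res, function(r) {
    paste(r$competing, collapse = ",")
  }, "")
  classified <- tab[tab$family != "unclassified", , drop = FALSE]
  tally <- if (nrow(classified)) {
    agg <- split(classified, classified$family)
    data.frame(
      family = names(agg),
      n_precursors = vapply(agg, function(d) {
        length(unique(d$protein_id))
      }, 0L),
      n_peptides = vapply(agg, nrow, 0L),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    data.frame(family = character(), n_precursors = integer(),
               n_peptides = integer(), stringsAsFactors = FALSE)
  }
  list(assignments = tab, tally = tally)
}
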