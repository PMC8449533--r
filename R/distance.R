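#' Alignment scoring defaults for receptor-domain distances
#'
#' Fixed so that distances are reproducible across runs: BLOSUM62
#' substitution scores with affine gaps (opening 10, extension 0.5).
#'
#' @return Named list with `matrix`, `gap_opening`, `gap_extension`.
#' @export
alignment_scoring <- function() {
  list(matrix = "BLOSUM62", gap_opening = 10, gap_extension = 0.5)
}

#' Identity-based distance from global pairwise alignment
#'
#' Needleman-Wunsch global alignment under the fixed scoring of
#' [alignment_scoring()]; the distance is `1 - identities / alignment
#' length` (gap columns included in the length). Arguments are ordered
#' canonically before aligning so the distance is exactly symmetric.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Distance in `[0, 1]`.
#' @export
pairwise_distance <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  if (a == b) return(0)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  sc <- alignment_scoring()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sc$matrix, gapOpening = sc$gap_opening,
    gapExtension = sc$gap_extension, type = "global"
  )
  ident <- Biostrings::nmatch(aln)
  alen <- Biostrings::nchar(Biostrings::alignedPattern(aln))
  1 - ident / alen
}

#' Pairwise distance matrix over labelled domains
#'
#' @param domains Named character vector of domain sequences (names are
#'   the matrix labels; must be unique).
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(domains) {
  stopifnot(length(names(domains)) == length(domains),
            !anyDuplicated(names(domains)))
  n <- length(domains)
  d <- matrix(0, n, n, dimnames = list(names(domains), names(domains)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- pairwise_distance(domains[[i]], domains[[j]])
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining with negative branch lengths clamped to zero.
#' Ties in the agglomeration are resolved deterministically by label order
#' (rows are kept in the label order supplied).
#'
#' @param d Symmetric distance matrix with labels (at least 3 taxa).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3L)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Assign receptor family by nearest labelled reference
#'
#' Labels are encoded in reference FASTA headers as `id|FAMILY|annotation`
#' (see [read_reference_panel()]). The candidate receives the family of its
#' nearest reference by [pairwise_distance()]; an exact tie between the
#' nearest references of two different families leaves the candidate
#' `"unassigned"` with both families reported in the margin.
#'
#' @param candidate A vetted candidate from [vet_gpcr_candidate()] (needs a
#'   non-`NA` `domain_7tm`).
#' @param refs Reference panel data frame with columns `id`, `family`,
#'   `seq`.
#' @return The candidate list extended with `family`, `nearest_ref`,
#'   `nearest_dist`, `margin` (distance gap to the best other family; `NA`
#'   when only one family is present).
#' @export
assign_family <- function(candidate, refs) {
  out <- candidate
  out$family <- "unassigned"
  out$nearest_ref <- NA_character_
  out$nearest_dist <- NA_real_
  out$margin <- NA_real_
  if (is.null(refs) || nrow(refs) == 0L || is.na(candidate$domain_7tm)) {
    return(out)
  }
  d <- vapply(refs$seq, function(s) {
    pairwise_distance(candidate$domain_7tm, s)
  }, numeric(1))
  best_by_family <- tapply(d, refs$family, min)
  o <- order(best_by_family, names(best_by_family))
  best_fam <- names(best_by_family)[o[1L]]
  i_best <- which(refs$family == best_fam & d == best_by_family[o[1L]])[1L]
  out$nearest_ref <- refs$id[i_best]
  out$nearest_dist <- unname(d[i_best])
  if (length(best_by_family) > 1L) {
    second <- best_by_family[o[2L]]
    out$margin <- unname(second - best_by_family[o[1L]])
    if (out$margin == 0) {
      out$family <- "unassigned"
      out$tied_families <- names(best_by_family)[best_by_family ==
                                                 best_by_family[o[1L]]]
      return(out)
    }
  }
  out$family <- best_fam
  out
}

#' Read a labelled reference GPCR panel
#'
#' Headers follow the `id|FAMILY|annotation` convention (annotation
#' optional).
#'
#' @param path FASTA path.
#' @return Data frame with columns `id`, `family`, `annotation`, `seq`.
#' @export
read_reference_panel <- function(path) {
  set <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("reference headers must be 'id|FAMILY|annotation'")
  }
  data.frame(
    id = vapply(parts, `[`, "", 1L),
    family = vapply(parts, `[`, "", 2L),
    annotation = vapply(parts, function(p) {
      if (length(p) >= 3L) p[3L] else ""
    }, ""),
    seq = toupper(gsub("\\s", "", as.character(set))),
    stringsAsFactors = FALSE
  )
}
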