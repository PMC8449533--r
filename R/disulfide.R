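#' Enumerate disulfide bridge pairings
#'
#' For an even number of cysteines the number of distinct complete pairings
#' (perfect matchings of the labelled cysteines) is the double factorial
#' (n - 1)!!. The matchings themselves are listed for small n.
#'
#' @param cys_count Number of cysteines (non-negative integer). An odd count
#'   is flagged as an unpaired-cysteine condition with a warning; the bridge
#'   count is then `floor(n / 2)` and no matchings are listed.
#' @param list_matchings List the matchings when `cys_count <= 12`
#'   (default); each matching is a two-column matrix of 1-based cysteine
#'   indices in order of appearance.
#' @return List with `bridges`, `n_matchings`, `unpaired` (flag) and
#'   optionally `matchings`.
#' @export
enumerate_disulfide_pairings <- function(cys_count, list_matchings = TRUE) {
  stopifnot(cys_count >= 0L, cys_count == round(cys_count))
  n <- as.integer(cys_count)
  if (n %% 2L == 1L) {
    warning("odd cysteine count (", n, "): one cysteine remains unpaired")
    return(list(bridges = n %/% 2L, n_matchings = NA_real_, unpaired = TRUE))
  }
  # (n - 1)!! = 1 * 3 * 5 * ... * (n - 1); empty product for n = 0
  n_matchings <- if (n == 0L) 1 else prod(seq(1L, n - 1L, by = 2L))
  out <- list(bridges = n %/% 2L, n_matchings = n_matchings, unpaired = FALSE)
  if (isTRUE(list_matchings) && n <= 12L) {
    out$matchings <- .enumerate_matchings(seq_len(n))
  }
  out
}

# All perfect matchings of a label vector: pair the smallest label with each
# remaining label and recurse.
.enumerate_matchings <- function(labels) {
  if (length(labels) == 0L) return(list(matrix(integer(), ncol = 2)))
  first <- labels[1L]
  rest <- labels[-1L]
  out <- list()
  for (j in seq_along(rest)) {
    partner <- rest[j]
    for (sub in .enumerate_matchings(rest[-j])) {
      out[[length(out) + 1L]] <- rbind(c(first, partner), sub)
    }
  }
  out
}

#' Validate a proposed disulfide pairing
#'
#' @param pairing List of length-2 integer vectors (or a two-column matrix)
#'   of 1-based cysteine indices in order of appearance.
#' @param cys_count Total number of cysteines.
#' @return List with `valid` (flag) and `reason` (`NA` when valid).
#' @export
validate_pairing <- function(pairing, cys_count) {
  if (is.matrix(pairing)) {
    pairing <- lapply(seq_len(nrow(pairing)), function(i) pairing[i, ])
  }
  idx <- as.numeric(unlist(pairing))
  if (any(lengths(pairing) != 2L)) {
    return(list(valid = FALSE, reason = "each bridge must pair exactly two cysteines"))
  }
  if (any(idx < 1L | idx > cys_count | idx != round(idx))) {
    return(list(valid = FALSE, reason = "cysteine index out of range"))
  }
  if (anyDuplicated(idx)) {
    return(list(valid = FALSE, reason = "cysteine index used more than once"))
  }
  if (length(idx) != cys_count) {
    return(list(valid = FALSE, reason = "pairing does not cover all cysteines"))
  }
  list(valid = TRUE, reason = NA_character_)
}
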