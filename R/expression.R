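#' Canonical tissue panel
#'
#' The nine-tissue RT-PCR panel: cerebral ganglia (CG), eyestalk ganglia
#' (EG), gill (Gi), hepatopancreas (Hp), heart (Ht), muscle (Ms), ovary
#' (Ov), ventral ganglia (VG) and Y-organ (YO). The central nervous system
#' (CNS) aggregate is the union of CG, EG and VG.
#'
#' @export
CANONICAL_TISSUES <- c("CG", "EG", "Gi", "Hp", "Ht", "Ms", "Ov", "VG", "YO")

#' CNS member tissues
#' @export
CNS_TISSUES <- c("CG", "EG", "VG")

#' Read a transcript-by-tissue presence/absence matrix
#'
#' Expects a TSV whose first column holds transcript ids and whose header
#' row names the tissues; cells must be 0 or 1. Non-canonical tissue names
#' are accepted with a warning.
#'
#' @param path TSV path.
#' @return An `expression_matrix`: a logical matrix with transcript row
#'   names and tissue column names.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicated transcript id: ", ids[duplicated(ids)][1L])
  }
  tissues <- names(tab)[-1L]
  if (anyDuplicated(tissues)) stop("duplicated tissue label")
  extra <- setdiff(tissues, CANONICAL_TISSUES)
  if (length(extra)) {
    warning("non-canonical tissue name(s): ", paste(extra, collapse = ", "))
  }
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- !(cells %in% c("0", "1"))
  dim(bad) <- dim(cells)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-binary cell for transcript '", ids[i[1L]], "', tissue '",
         tissues[i[2L]], "'")
  }
  m <- matrix(cells == "1", nrow = length(ids),
              dimnames = list(ids, tissues))
  class(m) <- c("expression_matrix", class(m))
  m
}

#' Count transcripts expressed in a tissue
#'
#' @param m Expression matrix from [read_expression_matrix()].
#' @param tissue Tissue name (must be a column of `m`).
#' @return Number of transcripts with a positive call.
#' @export
count_expressed <- function(m, tissue) {
  if (!tissue %in% colnames(m)) {
    stop("unknown tissue '", tissue, "'; available: ",
         paste(colnames(m), collapse = ", "))
  }
  sum(m[, tissue])
}

#' Per-tissue summary of an expression matrix
#'
#' @param m Expression matrix.
#' @return List with `tissue_counts` (named vector, one entry per tissue
#'   plus a `CNS` aggregate when any CNS member tissue is present: a
#'   transcript counts as CNS-expressed if called in CG, EG or VG) and
#'   `transcript_tissues` (named list of tissues per transcript).
#' @export
tissue_summary <- function(m) {
  if (nrow(m) == 0L || ncol(m) == 0L) {
    return(list(tissue_counts = integer(), transcript_tissues = list()))
  }
  counts <- colSums(m)
  cns_members <- intersect(CNS_TISSUES, colnames(m))
  if (length(cns_members)) {
    counts <- c(counts,
                CNS = sum(rowSums(m[, cns_members, drop = FALSE]) > 0L))
  }
  list(
    tissue_counts = counts,
    transcript_tissues = apply(m, 1L, function(r) colnames(m)[r],
                               simplify = FALSE)
  )
}
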