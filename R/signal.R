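#' Default configuration for the signal-peptide heuristic
#'
#' The heuristic scores candidate cleavage positions with a three-region
#' model of secretory signal peptides: a short positively charged n-region,
#' a hydrophobic h-region core, and small residues at the -3/-1 positions of
#' the signal-peptidase cleavage context. An external table of spans computed
#' by a dedicated predictor can override the heuristic per id.
#'
#' @param min_len,max_len Allowed cleavage positions (span length bounds),
#'   default 15-40.
#' @param min_protein_len Minimum protein length for heuristic mode.
#' @param h_window Window length used for the hydrophobic-core score.
#' @param min_score Minimum combined score to call a signal peptide.
#' @return A named list of parameters.
#' @export
signal_config <- function(min_len = 15L, max_len = 40L, min_protein_len = 30L,
                          h_window = 8L, min_score = 0.5) {
  list(min_len = min_len, max_len = max_len, min_protein_len = min_protein_len,
       h_window = h_window, min_score = min_score)
}

# Kyte-Doolittle hydropathy values (X scored 0).
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

.kd_values <- function(seq) {
  v <- KD_SCALE[strsplit(seq, "")[[1]]]
  v[is.na(v)] <- 0
  unname(v)
}

# residue preference at the -1 position of the signal-peptidase site
.s1_score <- function(res) {
  if (res == "A") 1 else if (res %in% c("G", "S", "C", "T")) 0.7 else 0
}
# -3 position tolerates small and aliphatic residues
.s3_score <- function(res) {
  if (res %in% c("A", "G", "S", "C", "T", "V", "L", "I")) 1 else 0
}

#' Predict a signal peptide
#'
#' At most one prediction anchored at residue 1 is returned. For each
#' candidate cleavage position k within the configured span bounds the score
#' combines (i) the best `h_window`-mean Kyte-Doolittle hydropathy over the
#' putative h-region (positions 2..k-3), (ii) small-residue preference at the
#' -1 and -3 positions, and (iii) presence of a basic residue in the n-region
#' (positions 1-4). Ties resolve to the smallest k.
#'
#' @param protein A protein record row (fields `id`, `seq`).
#' @param cfg Configuration from [signal_config()].
#' @param external Optional data frame of externally computed spans with
#'   columns `id` and `sp_end`; a matching id is returned verbatim with
#'   `method = "external"` and score 1.
#' @return A list with `present` (flag), `start` (1), `end` (cleavage
#'   position, i.e. span length), `score` in [0,1], and `method`.
#' @export
predict_signal_peptide <- function(protein, cfg = signal_config(),
                                   external = NULL) {
  absent <- list(present = FALSE, start = NA_integer_, end = NA_integer_,
                 score = 0, method = "heuristic")
  if (!is.null(external)) {
    hit <- match(protein$id, external$id)
    if (!is.na(hit)) {
      end <- as.integer(external$sp_end[hit])
      return(list(present = !is.na(end) && end > 0L, start = 1L, end = end,
                  score = 1, method = "external"))
    }
  }
  len <- nchar(protein$seq)
  if (len < cfg$min_protein_len) return(absent)
  res <- strsplit(protein$seq, "")[[1]]
  kd <- .kd_values(protein$seq)
  n_score <- if (any(res[1:min(4L, len)] %in% c("K", "R"))) 1 else 0.4
  best_k <- NA_integer_
  best_score <- -Inf
  for (k in cfg$min_len:min(cfg$max_len, len - 1L)) {
    h_hi <- k - 3L
    if (h_hi - 2L + 1L < cfg$h_window) next
    win_means <- vapply(2L:(h_hi - cfg$h_window + 1L), function(i) {
      mean(kd[i:(i + cfg$h_window - 1L)])
    }, numeric(1))
    h <- max(0, min(1, max(win_means) / 3.5))
    cterm <- 0.6 * .s1_score(res[k]) + 0.4 * .s3_score(res[k - 2L])
    score <- 0.5 * h + 0.3 * cterm + 0.2 * n_score
    if (score > best_score + 1e-12) {
      best_score <- score
      best_k <- k
    }
  }
  if (is.na(best_k) || best_score < cfg$min_score) return(absent)
  list(present = TRUE, start = 1L, end = best_k,
       score = round(min(1, best_score), 4), method = "heuristic")
}
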