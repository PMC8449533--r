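#' Partition proteins by a minimum-length completeness filter
#'
#' Receptor candidates shorter than `min_len` residues are considered too
#' short for reliable topology vetting.
#'
#' @param proteins Protein-record data frame (columns `id`, `seq`).
#' @param min_len Minimum retained length in residues (default 150).
#' @return List with `retained` and `rejected` data frames, input order
#'   preserved.
#' @export
filter_by_length <- function(proteins, min_len = 150L) {
  keep <- nchar(proteins$seq) >= min_len
  list(retained = proteins[keep, , drop = FALSE],
       rejected = proteins[!keep, , drop = FALSE])
}

#' Windowed Kyte-Doolittle hydropathy profile
#'
#' Centered moving average of per-residue hydropathy; edge positions use the
#' shrunken window that fits inside the sequence. X residues score 0.
#'
#' @param protein Protein record row (or plain sequence string).
#' @param window Odd window length (default 19, the classic
#'   transmembrane-scan width).
#' @param scale Named residue-to-score vector (default Kyte-Doolittle).
#' @return List with `values` (length = protein length), `window`, `scale`.
#' @export
hydropathy_profile <- function(protein, window = 19L, scale = KD_SCALE) {
  seq <- if (is.character(protein)) protein else protein$seq
  stopifnot(window %% 2L == 1L, window <= nchar(seq))
  kd <- scale[strsplit(seq, "")[[1]]]
  kd[is.na(kd)] <- 0
  half <- (window - 1L) %/% 2L
  n <- length(kd)
  cs <- cumsum(c(0, kd))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  list(values = unname(values), window = window, scale = scale)
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Maximal runs of positions above `threshold` are found, runs separated by
#' fewer than `min_loop_len` residues are merged, and each run shorter than
#' the smoothing window is expanded symmetrically to the window length
#' (window-mean smoothing shrinks the above-threshold peak of a helix well
#' below its physical span). Runs longer than `max_tm_len` are split into
#' equal parts; segments shorter than `min_tm_len` after these steps are
#' dropped.
#'
#' @param h Profile from [hydropathy_profile()].
#' @param threshold Hydropathy call threshold (default 1.6).
#' @param min_tm_len,max_tm_len Accepted segment lengths (defaults 15-30).
#' @param min_loop_len Minimum loop separating two segments (default 5).
#' @return Data frame with columns `start`, `end`, `mean_score`, ordered
#'   and non-overlapping.
#' @export
predict_tm_segments <- function(h, threshold = 1.6, min_tm_len = 15L,
                                max_tm_len = 30L, min_loop_len = 5L) {
  v <- h$values
  n <- length(v)
  above <- v > threshold
  empty <- data.frame(start = integer(), end = integer(),
                      mean_score = numeric(), stringsAsFactors = FALSE)
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short gaps
  if (nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2L:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L < min_loop_len) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  segs <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]
    e <- runs$end[i]
    len <- e - s + 1L
    if (len < h$window) {
      center <- (s + e) %/% 2L
      half <- (h$window - 1L) %/% 2L
      s <- max(1L, center - half)
      e <- min(n, center + half)
      len <- e - s + 1L
    }
    if (len > max_tm_len) {
      k <- ceiling(len / max_tm_len)
      bounds <- round(seq(s - 1L, e, length.out = k + 1L))
      for (j in seq_len(k)) {
        segs[[length(segs) + 1L]] <- c(bounds[j] + 1L, bounds[j + 1L])
      }
    } else {
      segs[[length(segs) + 1L]] <- c(s, e)
    }
  }
  out <- do.call(rbind, segs)
  out <- data.frame(start = out[, 1L], end = out[, 2L])
  out <- out[out$end - out$start + 1L >= min_tm_len, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$mean_score <- vapply(seq_len(nrow(out)), function(i) {
    mean(v[out$start[i]:out$end[i]])
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Extract the 7TM domain spanned by the predicted segments
#'
#' @param protein Protein record row.
#' @param segments Segment table from [predict_tm_segments()].
#' @return Substring from the first segment start to the last segment end.
#' @export
extract_7tm_domain <- function(protein, segments) {
  if (nrow(segments) == 0L) {
    stop("no transmembrane segments for ", protein$id)
  }
  substring(protein$seq, segments$start[1L],
            segments$end[nrow(segments)])
}

#' Vet a receptor candidate through the 7TM gate
#'
#' Runs the hydropathy profile and segment caller and records whether the
#' segment count falls within the acceptance band (default exactly 7).
#' External per-id TM annotations (data frame with `id`, `n_tm`,
#' `domain_start`, `domain_end`) bypass the heuristic.
#'
#' @param protein Protein record row.
#' @param band Accepted segment counts (default `7L`; e.g. `6:8` for a
#'   looser gate).
#' @param window,threshold Hydropathy parameters.
#' @param external Optional external TM annotation table.
#' @return List with `protein_id`, `length`, `tm_segments`, `n_tm`,
#'   `passes_7tm`, `domain_7tm` (`NA` when no segments).
#' @export
vet_gpcr_candidate <- function(protein, band = 7L, window = 19L,
                               threshold = 1.6, external = NULL) {
  if (!is.null(external)) {
    hit <- match(protein$id, external$id)
    if (!is.na(hit)) {
      n_tm <- as.integer(external$n_tm[hit])
      dom <- substring(protein$seq, external$domain_start[hit],
                       external$domain_end[hit])
      return(list(protein_id = protein$id, length = nchar(protein$seq),
                  tm_segments = NULL, n_tm = n_tm,
                  passes_7tm = n_tm %in% band,
                  domain_7tm = if (nzchar(dom)) dom else NA_character_))
    }
  }
  h <- hydropathy_profile(protein, window = window)
  segs <- predict_tm_segments(h, threshold = threshold)
  list(
    protein_id = protein$id, length = nchar(protein$seq),
    tm_segments = segs, n_tm = nrow(segs),
    passes_7tm = nrow(segs) %in% band,
    domain_7tm = if (nrow(segs)) extract_7tm_domain(protein, segs)
                 else NA_character_
  )
}
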