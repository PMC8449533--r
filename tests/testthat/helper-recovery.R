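# fraction of planted mature peptides found (and correctly classified)
# among the assignments of a neuropeptide-track run on a truth manifest
recovery_rates <- function(truth, assignments) {
  n_mat <- 0L
  n_mat_found <- 0L
  n_fam_found <- 0L
  for (prec in truth$precursors) {
    rows <- assignments[grepl(paste0("^", prec$transcript_id, "_orf"),
                              assignments$protein_id), ]
    for (k in seq_along(prec$matures)) {
      n_mat <- n_mat + 1L
      hit <- which(rows$rendered == prec$matures[[k]])
      if (length(hit)) {
        n_mat_found <- n_mat_found + 1L
        if (prec$families[[k]] %in% rows$family[hit]) {
          n_fam_found <- n_fam_found + 1L
        }
      }
    }
  }
  list(mature = n_mat_found / max(n_mat, 1L),
       family = n_fam_found / max(n_mat, 1L))
}
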