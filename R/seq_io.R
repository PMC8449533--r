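#' Read a FASTA file into a record data frame
#'
#' Records are returned in file order as a data frame with one row per header.
#' Sequences are whitespace-stripped and uppercased on ingestion. Characters
#' outside the declared alphabet raise a parse error naming the offending
#' record.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"nucleotide"` (A, C, G, T, N) or `"protein"`
#'   (the 20 standard residues plus X).
#' @return A data frame with columns `id` and `seq`. For protein input the
#'   columns `source_id` (set to `"direct"`) and `frame` (`NA`) are added so
#'   records are interchangeable with [translate_frame()] output.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate record id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  legal <- if (alphabet == "nucleotide") "^[ACGTN]*$" else "^[ACDEFGHIKLMNPQRSTVWYX]*$"
  bad <- !grepl(legal, seqs)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1L]], "' contains characters illegal for the ",
         alphabet, " alphabet")
  }
  out <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
  if (alphabet == "protein") {
    out$source_id <- rep("direct", nrow(out))
    out$frame <- rep(NA_integer_, nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Write records to FASTA
#'
#' @param records Data frame with columns `id` and `seq`.
#' @param path Output file.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement a nucleotide sequence
#'
#' @param seq Nucleotide string over A, C, G, T, N.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Codon -> amino-acid lookup from the standard code; stops render as "*" and
# any codon containing N renders as X (strict: no fuzzy-codon resolution).
.translate_codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Translate one reading frame of a transcript
#'
#' Frames 1..3 read the forward strand starting at positions 1..3; frames
#' -1..-3 read the reverse complement likewise. Trailing partial codons are
#' dropped, stop codons are rendered as `*` (a sentinel for downstream ORF
#' scanning), and codons containing N translate to X.
#'
#' @param transcript A single-row transcript record (or any list with `id`
#'   and `seq`) holding an uppercase nucleotide sequence.
#' @param frame Integer in `c(-3:-1, 1:3)`.
#' @return A one-row protein record data frame with columns `id`, `seq`,
#'   `source_id`, `frame`.
#' @export
translate_frame <- function(transcript, frame) {
  stopifnot(abs(frame) %in% 1:3)
  nt <- if (frame > 0) transcript$seq else revcomp(transcript$seq)
  nt <- substring(nt, abs(frame))
  data.frame(
    id = paste0(transcript$id, "_frame", frame),
    seq = .translate_codons(nt),
    source_id = transcript$id,
    frame = as.integer(frame),
    stringsAsFactors = FALSE
  )
}

# Map an ORF expressed in coordinates of the (possibly reverse-complemented,
# frame-shifted) reading to 1-based inclusive forward-strand coordinates.
.orf_forward_span <- function(nt_len, frame, off_start, off_end) {
  if (frame > 0) {
    c(off_start + frame - 1L, off_end + frame - 1L)
  } else {
    start_rc <- off_start + abs(frame) - 1L
    end_rc <- off_end + abs(frame) - 1L
    c(nt_len - end_rc + 1L, nt_len - start_rc + 1L)
  }
}

#' Find open reading frames in all six frames
#'
#' Reports maximal ATG-to-stop ORFs: within each stop-delimited block of a
#' frame only the leftmost ATG is reported, so nested shorter ORFs are
#' suppressed. With `require_atg = FALSE`, stop-to-stop stretches are reported
#' instead (for partial precursors). ORFs running off the transcript end
#' (no in-frame stop) are included.
#'
#' @param transcript A transcript record row (fields `id`, `seq`).
#' @param min_len_aa Minimum translated length in residues (stop excluded).
#' @param require_atg Require an ATG start codon (default `TRUE`).
#' @return A protein-record data frame with columns `id`, `seq`, `source_id`,
#'   `frame`, `cds_start`, `cds_end` (1-based inclusive on the forward
#'   strand), ordered by forward start then frame.
#' @export
find_orfs <- function(transcript, min_len_aa = 1L, require_atg = TRUE) {
  stopifnot(min_len_aa >= 1L)
  nt_len <- nchar(transcript$seq)
  rows <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    nt <- if (frame > 0) transcript$seq else revcomp(transcript$seq)
    nt <- substring(nt, abs(frame))
    aa <- .translate_codons(nt)
    if (!nzchar(aa)) next
    codon_chars <- strsplit(aa, "")[[1]]
    stops <- c(0L, which(codon_chars == "*"), length(codon_chars) + 1L)
    stops <- unique(stops)
    for (i in seq_len(length(stops) - 1L)) {
      block <- (stops[i] + 1L):(stops[i + 1L] - 1L)
      if (length(block) == 0L || block[1L] > block[length(block)]) next
      if (require_atg) {
        starts_m <- block[codon_chars[block] == "M"]
        if (length(starts_m) == 0L) next
        first <- starts_m[1L]
      } else {
        first <- block[1L]
      }
      last <- block[length(block)]
      len_aa <- last - first + 1L
      if (len_aa < min_len_aa) next
      # nucleotide offsets within the frame-shifted reading (1-based)
      off_start <- 3L * (first - 1L) + 1L
      off_end <- 3L * last
      span <- .orf_forward_span(nt_len, frame, off_start, off_end)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(transcript$id, "_orf", frame, "_", span[1L]),
        seq = paste0(codon_chars[first:last], collapse = ""),
        source_id = transcript$id,
        frame = frame,
        cds_start = span[1L],
        cds_end = span[2L],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      source_id = character(), frame = integer(),
                      cds_start = integer(), cds_end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cds_start, match(out$frame, c(1, 2, 3, -1, -2, -3))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an ORF table as TSV
#'
#' Columns: id, source_id, frame, start, end, length_aa.
#'
#' @param orfs Output of [find_orfs()] (rows may be concatenated over
#'   transcripts).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(orfs, path) {
  tab <- data.frame(
    id = orfs$id, source_id = orfs$source_id, frame = orfs$frame,
    start = orfs$cds_start, end = orfs$cds_end,
    length_aa = nchar(orfs$seq), stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
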