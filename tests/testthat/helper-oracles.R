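# Independent oracles used to cross-check the package implementation.
# They are written as direct brute-force procedures and deliberately share
# no code with the package internals.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")
random_protein <- function(n, alphabet = AA20) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- six-frame ORF scan ------------------------------------------------
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste0(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

oracle_translate <- function(nt) {
  tab <- Biostrings::GENETIC_CODE
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(nt, 3 * i - 2, 3 * i)
    out[i] <- if (codon %in% names(tab)) tab[[codon]] else "X"
  }
  paste0(out, collapse = "")
}

# every ATG in every frame, extended to the first in-frame stop (or the
# sequence end); nested ORFs sharing a stop are then removed
oracle_find_orfs <- function(seq, min_len_aa) {
  found <- list()
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    nt <- if (frame > 0) seq else oracle_revcomp(seq)
    nt <- substring(nt, abs(frame))
    aa <- oracle_translate(nt)
    chars <- strsplit(aa, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] != "M") next
      j <- i
      while (j <= length(chars) && chars[j] != "*") j <- j + 1
      pep <- paste0(chars[i:(j - 1)], collapse = "")
      if (nchar(pep) < min_len_aa) next
      found[[length(found) + 1]] <- list(frame = frame, start_codon = i,
                                         stop_block = j, seq = pep)
    }
  }
  # maximal only: keep the leftmost start per (frame, stop) pair
  if (length(found) == 0) return(character())
  key <- vapply(found, function(o) paste(o$frame, o$stop_block), "")
  best <- tapply(seq_along(found), key, function(ix) {
    starts <- vapply(found[ix], `[[`, 0, "start_codon")
    ix[which.min(starts)]
  })
  sort(vapply(found[unlist(best)], `[[`, "", "seq"))
}

# --- cleavage scan -----------------------------------------------------
# character-by-character scan, no regex
oracle_cleavage <- function(seq, dibasic, tribasic, monobasic,
                            terminal_monobasic, terminal_window,
                            signal_end = 0) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sites <- list()
  i <- 1
  while (i <= n) {
    if (!(ch[i] %in% c("K", "R"))) { i <- i + 1; next }
    j <- i
    while (j < n && ch[j + 1] %in% c("K", "R")) j <- j + 1
    run <- paste0(ch[i:j], collapse = "")
    L <- j - i + 1
    keep <- FALSE
    s <- i
    kind <- NA
    if (i > signal_end) {
      if (L == 1) {
        no_basic_after <- j == n || !any(ch[(j + 1):n] %in% c("K", "R"))
        if ((terminal_monobasic && i > n - terminal_window &&
             no_basic_after) ||
            run %in% monobasic) { keep <- TRUE; kind <- "monobasic" }
      } else if (L == 2) {
        if (run %in% dibasic) { keep <- TRUE; kind <- "dibasic" }
      } else {
        if (tribasic) { keep <- TRUE; kind <- "tribasic" }
        else {
          t2 <- substring(run, L - 1, L)
          if (t2 %in% dibasic) {
            keep <- TRUE; kind <- "dibasic"; s <- j - 1; run <- t2
          }
        }
      }
    }
    if (keep) sites[[length(sites) + 1]] <-
      data.frame(start = s, basic_run = run, kind = kind,
                 cut_after = s + nchar(run) - 1,
                 stringsAsFactors = FALSE)
    i <- j + 1
  }
  if (length(sites) == 0) {
    return(data.frame(start = integer(), basic_run = character(),
                      kind = character(), cut_after = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, sites)
}

# --- windowed hydropathy ----------------------------------------------
oracle_window_mean <- function(values, window) {
  half <- (window - 1) / 2
  n <- length(values)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(values[lo:hi])
  }, numeric(1))
}

# --- global alignment (Gotoh affine DP with identity traceback) --------
# gap of length L costs open + L * ext, matching the package's scoring
oracle_nw_distance <- function(a, b, open = 10, ext = 0.5) {
  subm <- get(utils::data("BLOSUM62", package = "Biostrings",
                          envir = environment()), envir = environment())
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (x aligned to gap)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- subm[x[i - 1], y[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  # traceback preferring the diagonal
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  ident <- 0
  alen <- 0
  while (i > 1 || j > 1) {
    alen <- alen + 1
    if (state == 1) {
      if (x[i - 1] == y[j - 1]) ident <- ident + 1
      s <- subm[x[i - 1], y[j - 1]]
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      from_m <- isTRUE(all.equal(Ix[i, j], M[i - 1, j] - open - ext))
      state <- if (from_m) 1 else 2
      i <- i - 1
    } else {
      from_m <- isTRUE(all.equal(Iy[i, j], M[i, j - 1] - open - ext))
      state <- if (from_m) 1 else 3
      j <- j - 1
    }
  }
  list(score = max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]),
       distance = 1 - ident / alen)
}

# --- perfect matchings by permutation-free recursion -------------------
oracle_count_matchings <- function(n) {
  if (n == 0) return(1)
  if (n %% 2 == 1) return(0)
  count <- function(left) {
    if (length(left) == 0) return(1)
    tot <- 0
    for (k in 2:length(left)) {
      tot <- tot + count(left[-c(1, k)])
    }
    tot
  }
  count(seq_len(n))
}
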