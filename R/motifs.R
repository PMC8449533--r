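#' Built-in neuropeptide family motif library
#'
#' Family signatures use a position-restricted wildcard dialect: plain
#' letters are fixed residues, `X` matches any residue, `[FL]`-style
#' brackets are alternatives, and `X{m,n}` matches a bounded run of
#' arbitrary residues. `anchor` is one of `c_terminal`, `n_terminal`,
#' `anywhere`, `full_match`; `requires_amide`/`requires_pyroglu` gate
#' matching on the peptide's PTM flags (`yes`/`no`/`either`). The
#' CHH/MIH/ITP superfamily lacks a short linear motif and is encoded as a
#' `cys_skeleton` entry (six cysteines with bounded spacing on a peptide of
#' CHH-like length). Families whose exemplar is not a concrete published
#' peptide carry a synthetic exemplar instantiated from the pattern
#' (`exemplar_source = "synthetic"`).
#'
#' @format Data frame with columns `family`, `kind`, `pattern`, `anchor`,
#'   `requires_amide`, `requires_pyroglu`, `exemplar` (rendered pQ/amide
#'   notation), `exemplar_source`, `provenance`.
#' @keywords internal
builtin_motifs <- function() {
  e <- function(...) data.frame(..., stringsAsFactors = FALSE)
  chh_exemplar <- paste0(
    strrep("A", 6), "C", strrep("S", 15), "C", "AA", "C", strrep("T", 12),
    "C", "AAA", "C", strrep("S", 8), "C", strrep("A", 15))
  rows <- rbind(
    e(family = "ACP", kind = "linear", pattern = "QITFSRSWVPQ",
      anchor = "full_match", requires_amide = "yes", requires_pyroglu = "yes",
      exemplar = "pQITFSRSWVPQamide", exemplar_source = "printed",
      provenance = "conserved decapod AKH/corazonin-related peptide"),
    e(family = "AST-A", kind = "linear", pattern = "XYXFGL",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "AGPYSFGLamide", exemplar_source = "printed",
      provenance = "-YXFGLamide C-terminus of A-type allatostatins"),
    e(family = "AST-B", kind = "linear", pattern = "XWXXXXGXW",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "AGWSSMRGAWamide", exemplar_source = "printed",
      provenance = "W(X6)Wamide signature of B-type allatostatins"),
    e(family = "AST-C", kind = "linear", pattern = "PISCF",
      anchor = "c_terminal", requires_amide = "no", requires_pyroglu = "either",
      exemplar = "pQIRYHQCYFNPISCF", exemplar_source = "printed",
      provenance = "unamidated PISCF C-terminus of C-type allatostatins"),
    e(family = "AST-CCC", kind = "linear", pattern = "SYWKQCAFNAVSCF",
      anchor = "full_match", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "SYWKQCAFNAVSCFamide", exemplar_source = "printed",
      provenance = "amidated AST-C-like (CCC) paralog peptide"),
    e(family = "CCAP", kind = "linear", pattern = "PFCNAFTGC",
      anchor = "full_match", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "PFCNAFTGCamide", exemplar_source = "printed",
      provenance = "crustacean cardioactive peptide nonapeptide"),
    e(family = "CCHamide", kind = "linear", pattern = "XCXX[YF]GHSCXGAH",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "ACAAYGHSCAGAHamide", exemplar_source = "synthetic",
      provenance = "two-cysteine GHSC..GAHamide signature of CCHamides"),
    e(family = "CHH", kind = "cys_skeleton", pattern = "C6",
      anchor = "anywhere", requires_amide = "either", requires_pyroglu = "either",
      exemplar = chh_exemplar, exemplar_source = "synthetic",
      provenance = "six-cysteine skeleton of the CHH/MIH/ITP superfamily"),
    e(family = "CNMamide", kind = "linear", pattern = "VMCHFKICNM",
      anchor = "full_match", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "VMCHFKICNMamide", exemplar_source = "printed",
      provenance = "disulfide-bonded CNMamide decapeptide"),
    e(family = "corazonin", kind = "linear", pattern = "QTFQYSRGWTN",
      anchor = "full_match", requires_amide = "yes", requires_pyroglu = "yes",
      exemplar = "pQTFQYSRGWTNamide", exemplar_source = "printed",
      provenance = "pan-arthropod corazonin undecapeptide"),
    e(family = "DH44", kind = "linear",
      pattern = "NSGLSLSIDASMKVLREALYLEIARKKQRQQLQRAQHNKALLNTI",
      anchor = "full_match", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "NSGLSLSIDASMKVLREALYLEIARKKQRQQLQRAQHNKALLNTIamide",
      exemplar_source = "printed",
      provenance = "CRF-like diuretic hormone 44 mature peptide"),
    e(family = "ETH", kind = "linear", pattern = "DAGHFFAETPKHLPRI",
      anchor = "full_match", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "DAGHFFAETPKHLPRIamide", exemplar_source = "printed",
      provenance = "carcikinin / ecdysis-triggering hormone peptide"),
    e(family = "elevenin", kind = "linear", pattern = "XXXXDCR[KR]FVFAPXCRGIIA",
      anchor = "c_terminal", requires_amide = "either", requires_pyroglu = "either",
      exemplar = "AAAADCRKFVFAPACRGIIA", exemplar_source = "synthetic",
      provenance = "disulfide-bonded elevenin core signature"),
    e(family = "GSEFLamide", kind = "linear", pattern = "XGSEFL",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "AGSEFLamide", exemplar_source = "synthetic",
      provenance = "GSEFLamide C-terminus shared by the multi-copy family"),
    e(family = "HIGSLYRamide", kind = "linear", pattern = "H[IL]GSL[LY]R",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "HIGSLYRamide", exemplar_source = "synthetic",
      provenance = "H-I/L-GSL-L/Y-Ramide multi-copy signature"),
    e(family = "kinin", kind = "linear", pattern = "X[FL][NS]XWA",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "QAFSAWAamide", exemplar_source = "printed",
      provenance = "-F/L-N/S-X-WAamide C-terminus of kinins"),
    e(family = "myosuppressin", kind = "linear", pattern = "QDLDHVFLRF",
      anchor = "full_match", requires_amide = "yes", requires_pyroglu = "yes",
      exemplar = "pQDLDHVFLRFamide", exemplar_source = "printed",
      provenance = "pQDLDHVFLRFamide decapeptide of decapods"),
    e(family = "natalisin", kind = "linear", pattern = "WX{2,13}R",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "WAAGRamide", exemplar_source = "synthetic",
      provenance = "WXXXRamide-type C-terminus of natalisins"),
    e(family = "NPF", kind = "linear", pattern = "RPRF",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "AARPRFamide", exemplar_source = "synthetic",
      provenance = "RPRFamide C-terminus of long neuropeptide F"),
    e(family = "orcokinin", kind = "linear", pattern = "NFDEIDRSXFGFX",
      anchor = "c_terminal", requires_amide = "no", requires_pyroglu = "either",
      exemplar = "NFDEIDRSAFGFA", exemplar_source = "synthetic",
      provenance = "NFDEIDRS..FGF free-acid core of orcokinins"),
    e(family = "proctolin", kind = "linear", pattern = "RYLPT",
      anchor = "full_match", requires_amide = "no", requires_pyroglu = "either",
      exemplar = "RYLPT", exemplar_source = "printed",
      provenance = "RYLPT pentapeptide, fully conserved free acid"),
    e(family = "pyrokinin", kind = "linear", pattern = "F[AS]PR[PL]",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "FAPRPamide", exemplar_source = "printed",
      provenance = "FXPRL/Pamide C-terminus of pyrokinins"),
    e(family = "RPCH", kind = "linear", pattern = "QLNFSPGW",
      anchor = "full_match", requires_amide = "yes", requires_pyroglu = "yes",
      exemplar = "pQLNFSPGWamide", exemplar_source = "printed",
      provenance = "red pigment-concentrating hormone octapeptide"),
    e(family = "RYamide", kind = "linear", pattern = "FYSQRY",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "FYSQRYamide", exemplar_source = "printed",
      provenance = "FYSQRYamide, the decapod RYamide signature"),
    e(family = "SIFamide", kind = "linear", pattern = "GYRKPPFNGSIF",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "GYRKPPFNGSIFamide", exemplar_source = "printed",
      provenance = "GYRKPPFNGSIFamide dodecapeptide"),
    e(family = "sNPF", kind = "linear", pattern = "PXXRLRF",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "APPSMRLRFamide", exemplar_source = "printed",
      provenance = "PXXRLRFamide C-terminus of short neuropeptide F"),
    e(family = "sulfakinin", kind = "linear", pattern = "DYGH[ML]RF",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "EFDDYGHMRFamide", exemplar_source = "printed",
      provenance = "DYGH-M/L-RFamide C-terminus of sulfakinins"),
    e(family = "tachykinin", kind = "linear", pattern = "XPSGFLGMR",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "APSGFLGMRamide", exemplar_source = "synthetic",
      provenance = "XPSGFLGMRamide shared by tachykinin-related peptides"),
    e(family = "trissin", kind = "linear",
      pattern = "STVSCDSCGPECQTACGTKNFRACCFNFL",
      anchor = "full_match", requires_amide = "no", requires_pyroglu = "either",
      exemplar = "STVSCDSCGPECQTACGTKNFRACCFNFL", exemplar_source = "printed",
      provenance = "six-cysteine trissin mature peptide"),
    e(family = "vasopressin", kind = "linear", pattern = "CFITNCPPG",
      anchor = "c_terminal", requires_amide = "yes", requires_pyroglu = "either",
      exemplar = "CFITNCPPGamide", exemplar_source = "printed",
      provenance = "disulfide-cyclized CFITNCPPGamide nonapeptide")
  )
  rownames(rows) <- NULL
  rows
}

# compile the wildcard dialect to a POSIX regex body (no anchors)
.motif_regex <- function(pattern) {
  r <- gsub("X\\{(\\d+),(\\d+)\\}", ".{\\1,\\2}", pattern)
  gsub("X", ".", r, fixed = TRUE)
}

# specificity = number of constrained (non-wildcard) positions; bracket
# alternative groups count as one position each
.motif_specificity <- function(pattern) {
  tmp <- gsub("X\\{\\d+,\\d+\\}", "", pattern)
  groups <- gregexpr("\\[[A-Z]+\\]", tmp)[[1]]
  n_groups <- if (groups[1] == -1L) 0L else length(groups)
  tmp <- gsub("\\[[A-Z]+\\]", "", tmp)
  tmp <- gsub("X", "", tmp, fixed = TRUE)
  nchar(tmp) + n_groups
}

#' Compile the motif library
#'
#' Loads the built-in family signatures and optionally appends user-supplied
#' motifs from a TSV with the same columns as the built-in table (at minimum
#' `family`, `pattern`, `anchor`, `requires_amide`, `requires_pyroglu`).
#'
#' @param user_tsv Optional path to a TSV of additional motifs.
#' @param builtin Include the built-in library (default `TRUE`).
#' @return A motif-library data frame with compiled `regex` and
#'   `specificity` columns, in deterministic (built-in then user) order.
#' @export
compile_motif_library <- function(user_tsv = NULL, builtin = TRUE) {
  lib <- if (builtin) builtin_motifs() else builtin_motifs()[0, ]
  if (!is.null(user_tsv)) {
    usr <- utils::read.delim(user_tsv, stringsAsFactors = FALSE)
    needed <- c("family", "pattern", "anchor", "requires_amide",
                "requires_pyroglu")
    if (!all(needed %in% names(usr))) {
      stop("user motif TSV must provide columns: ",
           paste(needed, collapse = ", "))
    }
    if (is.null(usr$kind)) usr$kind <- "linear"
    if (is.null(usr$exemplar)) usr$exemplar <- NA_character_
    if (is.null(usr$exemplar_source)) usr$exemplar_source <- "user"
    if (is.null(usr$provenance)) usr$provenance <- "user-supplied"
    lib <- rbind(lib, usr[, names(lib)])
  }
  if (anyDuplicated(lib$family)) {
    stop("duplicate family name in motif library: ",
         lib$family[duplicated(lib$family)][1L])
  }
  bad_anchor <- !lib$anchor %in% c("c_terminal", "n_terminal", "anywhere",
                                   "full_match")
  if (any(bad_anchor)) {
    stop("invalid anchor for family ", lib$family[which(bad_anchor)[1L]])
  }
  ok <- lib$kind == "cys_skeleton" |
    grepl("^([A-WY]|X(\\{\\d+,\\d+\\})?|\\[[A-Z]+\\])+$", lib$pattern)
  if (!all(ok)) {
    stop("malformed motif pattern for family ", lib$family[which(!ok)[1L]])
  }
  lib$regex <- ifelse(lib$kind == "linear",
                      vapply(lib$pattern, .motif_regex, ""), NA_character_)
  lib$specificity <- ifelse(lib$kind == "cys_skeleton", 6L,
                            vapply(lib$pattern, .motif_specificity, 0L))
  rownames(lib) <- NULL
  lib
}

#' Write the motif library as TSV
#'
#' @param lib Library from [compile_motif_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_library <- function(lib, path) {
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a rendered peptide string into sequence and PTM flags
#'
#' @param rendered A display string in the pQ/pE/amide convention.
#' @return List with `seq`, `amidated`, `pyroglu`.
#' @export
parse_rendered <- function(rendered) {
  m <- regmatches(rendered,
                  regexec("^(p?)([A-Z]+?)(amide)?$", rendered))[[1]]
  if (length(m) == 0L) stop("malformed rendered peptide: ", rendered)
  list(seq = m[3], amidated = m[4] == "amide", pyroglu = m[2] == "p")
}
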