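---
title: "Mining neuropeptide precursors and their receptors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining neuropeptide precursors and their receptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmine)
```

## The biological model

Neuropeptides are made as prohormone precursors: an N-terminal signal
peptide routes the protein into the secretory pathway and is removed by
signal peptidase; prohormone convertases then cleave the remaining
proprotein at basic-residue sites (most often the dibasic pairs KR, KK, RR,
RK; occasionally tribasic runs or isolated K/R near the C-terminus),
releasing peptide fragments. Two post-translational modifications dominate
the mature forms: a C-terminal glycine is consumed by peptidylglycine
α-amidating monooxygenase to leave a C-terminal amide, and an N-terminal
glutamine (sometimes glutamate) cyclizes to pyroglutamate. Families are
recognizable by short C-terminal signatures (e.g. `-YXFGLamide` for A-type
allatostatins, `PXXRLRFamide` for short neuropeptide F) or, for the
CHH/MIH/ITP superfamily, by a conserved skeleton of six cysteines. Most of
these peptides act through G protein-coupled receptors, whose diagnostic
feature is a bundle of seven transmembrane helices.

`npmine` implements this processing model as a chain of small, separately
testable stages, plus a receptor-vetting track and a synthetic-data
generator that provides exact ground truth for every stage.

## Stage-by-stage design

### ORF extraction

All six reading frames are scanned for maximal ATG-to-stop ORFs; within a
stop-delimited block only the leftmost ATG is reported, so nested ORFs are
suppressed. A `require_atg = FALSE` mode reports stop-to-stop stretches for
C-terminally or N-terminally partial precursors, which do occur in real
assemblies. Codons containing N translate to X, and X never satisfies a
motif's fixed positions downstream. Coordinates are reported 1-based
inclusive on the forward strand throughout the package; any internal
half-open arithmetic is converted at the reporting boundary. The default
minimum ORF length is 50 aa on the neuropeptide track (the shortest real
precursors are shorter than 80 aa but well above 50) and 150 aa on the
receptor track, where shorter fragments cannot carry a full 7TM bundle and
are set aside as unvettable rather than silently scored.

### Signal peptides

Dedicated signal-peptide predictors are neural networks trained on large
curated sets; reimplementing one is out of scope. Instead the package uses
a transparent three-region heuristic and accepts external per-id spans
(`method = "external"`) when a dedicated predictor has been run. For each
candidate cleavage position *k* in the configured 15–40 window the score
combines, with weights 0.5/0.3/0.2:

* the best 8-residue mean Kyte–Doolittle hydropathy over positions
  2..*k*−3 (the h-region core), scaled into [0,1] at 3.5;
* small-residue preference at −1 (A best, then G/S/C/T) and −3
  (small or aliphatic) of the putative peptidase site;
* presence of a basic residue among the first four residues (n-region).

A prediction is emitted only if the best score reaches `min_score` (0.5);
poly-acidic or core-free N-termini therefore yield "absent", and
precursors without signal peptides (some partial and some genuinely
signal-less transcripts) are annotated rather than rejected. The weights
and thresholds are fixed defaults, chosen once so that canonical
signal-anchor-cleavage architectures score near 1 and sequences without a
hydrophobic core score near 0; they are not fitted to any dataset.

### Cleavage sites and excision

Maximal runs of K/R are matched left-to-right and classified by length.
The ruleset enables subsets of the dibasic pairs, tribasic runs, and
monobasic sites. Interior monobasic cleavage is highly context-dependent,
so it is off by default and available as a flag; however, isolated K/R
sites very close to the C-terminus are common in real precursors, so the
default accepts an isolated K/R within the last `terminal_window = 4`
residues *provided it is the final basic run of the sequence*. The second
condition is this package's refinement: without it, any mature peptide
whose own sequence ends in R (tachykinins, sulfakinins, FLRFamides) would
be spuriously cut when it happens to be the last copy before the terminal
cleavage site. Sites are labelled by the 1-based position of their first
basic residue (the `K47R` convention); the cut falls after the last basic
residue and the run is consumed by default (a `retain_basics` option keeps
runs on the upstream fragment for workflows that trim basics during PTM
processing, a convention that also appears in the literature). Fragments
are the maximal intervals left between signal span, basic runs and termini;
the package asserts that these pieces tile the precursor exactly, and a
precursor consisting only of basic residues yields zero fragments with a
warning, not an error.

### PTM processing and rendering

`apply_ptm` strips residual trailing basics (when excision retained them),
removes a terminal amide-donor G and sets the amidation flag, and flags
pyroglutamate for leading Q. Cyclization of glutamate is chemically
possible and supported (`pyroglu_from_E`), but off by default because
glutamine-derived pQ is what is actually observed in the decapod
repertoire. Rendering uses the field's `pQ…amide` display convention and
`invert_rendering` is its exact inverse, so annotations can round-trip
through reports. Note one deliberate ambiguity: "mature peptide length" in
the literature sometimes counts the amide-donor glycine and sometimes does
not; the package reports processed sequences and leaves both lengths
recoverable (`nchar(seq)` and `nchar(invert_rendering(rendered))`).

### Disulfide bookkeeping

Cysteine-rich peptides (agatoxin-like peptide, glycoprotein hormone
subunits, neurophysin, trissin, the CHH superfamily) are summarized by
cysteine count, bridge count `n/2`, and the number of distinct complete
pairings, the double factorial `(n−1)!!`. Pairings are enumerated for
n ≤ 12 and proposed connectivities (e.g. from an external disulfide
predictor) are validated as perfect matchings. The package deliberately
does not score which pairing is chemically correct.

### Family classification

The motif library transcribes each family's published signature into a
small wildcard dialect: letters are fixed, `X` is any residue, `[FL]` is an
alternative set, `X{m,n}` a bounded arbitrary run (used for the
natalisin-type `W…Ramide` signature, encoded as W, then 2–13 arbitrary
residues, then R). Each entry carries an anchor (`c_terminal`,
`n_terminal`, `anywhere`, `full_match`), amide/pyroglutamate requirements,
an exemplar peptide in rendered notation, and a provenance note. Families
whose published account gives a concrete peptide use it as the exemplar;
families described only by a wildcard signature carry a deterministic
synthetic exemplar instantiated from the pattern and are marked
`exemplar_source = "synthetic"`. Exact-sequence families (CCAP, corazonin,
RPCH, myosuppressin, the ecdysis-triggering hormone, proctolin, and
similar) are `full_match` entries; fuzzy (mismatch-tolerant) matching is
deliberately not enabled by default, since cross-species use changes the
false-positive structure and should be a conscious choice. The CHH
superfamily has no short linear motif and is encoded as a cysteine-skeleton
entry: exactly six cysteines, peptide length 50–100, consecutive-cysteine
gaps of 1–35 residues.

The classification score is the number of constrained (non-`X`) positions
of the winning motif — simple, reproducible, and biased toward specific
signatures over degenerate ones. Ties break by longer matched span, then
lexical family order, and runner-up families are surfaced in a `competing`
column rather than silently discarded (engineered chimeras can weakly match
two single-copy-family signatures; real data decides, not the tie-break).

### Receptor triage

The receptor track stands in for an HMM-based topology caller with an
auditable heuristic: a Kyte–Doolittle hydropathy profile (window 19, edge
positions use the shrunken window) is thresholded at 1.6, runs separated by
fewer than 5 residues are merged, and each above-threshold run shorter than
the window is expanded symmetrically to the window length. The expansion
rule matters: window-mean smoothing shrinks the above-threshold peak of a
19–23-residue helix to roughly 11–15 positions, so raw runs would fail any
sensible [15, 30] length band even for perfect helices; expanding each peak
to the smoothing window recovers the physical helix span to within a couple
of residues. Runs longer than 30 are split equally. The 7TM gate accepts a
configurable band of segment counts (default exactly 7; 6–8 is offered
because real topology calling is noisy), and external per-id TM annotations
can bypass the heuristic entirely. Partial receptor ORFs fail the 150-aa
filter and are reported in the rejected partition, never silently aligned.

Domains (first helix start to last helix end) are compared by global
Needleman–Wunsch alignment under fixed scoring — BLOSUM62, gap opening 10,
extension 0.5 — and distance 1 − identities/alignment-length, computed with
canonical argument ordering so the matrix is exactly symmetric. Trees are
built by neighbor joining with negative branch lengths clamped to zero — a
deterministic, desk-scale substitute for maximum-likelihood phylogenetics,
which is declared out of scope. Family assignment (rhodopsin-like A vs
secretin-like B, or any labels the reference panel carries, including LGR
and orphan-receptor clades) is by nearest labelled reference, with the
margin to the best other family reported and exact ties left unassigned.

### Expression summaries

Presence/absence matrices use the nine-tissue panel (CG, EG, Gi, Hp, Ht,
Ms, Ov, VG, YO) with a CNS aggregate defined as the union of the three
ganglia (CG, EG, VG). Published matrices of this kind exist only as gel
images, so no built-in fixture claims to be real data; a user-curated
matrix reproduces published tissue counts as documentation, not as a test.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults encode the
study conditions the pipeline is meant to handle: signal peptides of 19–35
residues; an optional precursor-related spacer peptide (25–40 residues in
generated datasets, which also keeps single-copy precursors above the
50-aa ORF minimum, as real prohormones are); 1–35 mature-peptide copies
each followed by a basic site; amide-donor glycines and N-terminal
glutamines planted via the payloads; receptor-like proteins with 19–23
residue hydrophobic blocks (L/I/V/F/A) separated by polar loops of at least
12 residues (D/E/N/Q/S/T/G/K/R).

Clean mode isolates each rule under test: payload alphabets exclude K and R
(no accidental sites), G at fragment ends (no accidental amidation) and Q
by chance (pyroglutamate only where planted); a payload may end in K/R only
when amidated, because the donor G then separates it from the planted site.
Canonical signals are built as M + K + a hydrophobic core drawn from
L/I/V/F (A excluded so the cleavage context stays unique) + SSA, which the
heuristic recovers exactly. Noise mode substitutes residues at a stated
per-residue rate — from the clean alphabet for precursors (processing
landmarks preserved) and from all 20 residues for receptors — and never
touches planted basic runs. Everything is deterministic under a seed.

What passing tests on these synthetics demonstrate: that every rule is
implemented exactly as stated, end to end (100% recovery of planted
matures, families and 7TM verdicts is asserted, not approximated). What
they do not demonstrate: performance on real data, where signal-peptide
boundaries are not canonical, monobasic cleavage is context-dependent,
motifs drift across species, and assemblies contain frameshifts and
chimeras. The external-override hooks (signal spans, TM annotations, user
motif TSVs, reference panels) exist precisely for that gap.

## Numerical and procedural choices

* Problem sizes in the default test run: 1,000-sequence oracle comparisons
  for cleavage scanning, 1,000 random precursors for the tiling property,
  500 PTM round-trips, matchings up to 10 cysteines against brute force,
  20 random 5–8-leaf additive matrices for topology recovery, and an
  end-to-end dataset of 10 precursors + 5 receptor candidates.
* Randomness: every generator takes an explicit integer seed;
  `generate_dataset` derives per-record sub-seeds below 2^31.
* Degenerate inputs: empty FASTA files flow through both tracks and yield
  empty, well-formed reports; all-basic precursors warn and yield zero
  fragments; odd cysteine counts warn and report floor(n/2) bridges;
  fewer than three tree leaves yields a report without a tree.
* Determinism: re-running a track with the same configuration produces
  byte-identical reports; logs carry counts, not timestamps.

## Known limitations

The signal-peptide and TM heuristics are transparent approximations, not
replacements for dedicated predictors; published repertoire counts from
real transcriptomes depend on assembly depth and reference databases and
are not reproducible from this package alone; homology search, assembly,
and maximum-likelihood trees are out of scope by design.
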