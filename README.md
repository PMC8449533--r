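# npmine

Neuropeptidome and receptor mining for decapod CNS transcriptomes.

Crustacean nervous systems secrete dozens of peptide hormones — allatostatins,
crustacean hyperglycemic hormone (CHH), RPCH, sulfakinins, kinins and many
more — each excised from a larger prohormone precursor and signalling mostly
through G protein-coupled receptors (GPCRs). Mining a transcriptome for this
repertoire is a chain of small, well-defined sequence analyses, and `npmine`
implements that chain as tested, reusable R functions for anyone annotating
neuropeptides and their receptors in arthropod transcriptome assemblies.

## What it computes

**Neuropeptide track.** From a nucleotide (or protein) FASTA:

1. six-frame translation and maximal ATG-to-stop ORF extraction
   (`find_orfs`);
2. signal-peptide prediction (`predict_signal_peptide`) with a three-region
   heuristic — charged n-region, hydrophobic h-region, small residues at the
   −3/−1 cleavage context — plus per-id external overrides;
3. prohormone convertase cleavage-site scanning (`find_cleavage_sites`):
   maximal basic runs classified as monobasic / dibasic (KR, KK, RR, RK) /
   tribasic, with near-C-terminal monobasic sites handled specially;
4. fragment excision (`excise_fragments`) — fragments, signal span and basic
   runs tile the precursor exactly;
5. post-translational processing (`apply_ptm`): a C-terminal Gly becomes a
   C-terminal amide, an N-terminal Gln (optionally Glu) flags
   pyroglutamate; peptides render in the standard `pQ…amide` notation, with
   an exact inverse (`invert_rendering`);
6. disulfide bookkeeping: for `n` cysteines, `n/2` bridges and
   `(n−1)!!` possible pairings, enumerated and validated
   (`enumerate_disulfide_pairings`, `validate_pairing`);
7. family classification (`classify_peptide`) against a built-in library of
   30 family signatures (`compile_motif_library`) in a position-restricted
   wildcard dialect (e.g. kinin `X[FL][NS]XWA`-amide, sNPF
   `PXXRLRF`-amide, sulfakinin `DYGH[ML]RF`-amide), anchored and gated on
   PTM state, scored by fixed-position specificity; the CHH/MIH/ITP
   superfamily is recognized by its six-cysteine skeleton.

**GPCR track.** Candidates shorter than 150 aa are set aside as too short to
vet; Kyte–Doolittle hydropathy profiles (window 19) yield transmembrane
segments, and candidates pass the gate when the segment count falls in the
acceptance band (default exactly 7). 7TM domains (first to last helix) are
compared by global alignment (BLOSUM62, affine gaps) identity distance, a
neighbor-joining tree is written in newick, and candidates are assigned to
the rhodopsin-like (A) or secretin-like (B) class by nearest labelled
reference.

**Expression summaries.** Transcript × tissue presence/absence tables (the
nine-tissue RT-PCR panel CG, EG, Gi, Hp, Ht, Ms, Ov, VG, YO) are parsed and
summarized per tissue, with a CNS aggregate over the three ganglia.

**Synthetic data.** `generate_precursor`, `generate_gpcr_like`,
`reverse_translate` and `generate_dataset` build ground-truthed precursors,
receptor-like proteins and transcripts so that every stage — and the whole
pipeline — can be tested for exact recovery without any downloads.

## Worked example

```r
library(npmine)

truth <- generate_precursor(c("RPCH", "AST-A", "sulfakinin"),
                            signal_len = 25, seed = 42)
ann <- annotate_precursor(truth$protein)
print(ann)
#> Precursor synth_prec_42 ( 60 aa )
#>   signal peptide: 1-25 [heuristic]
#>   cleavage sites: KR@35, KR@46, KR@59
#>   mature: pQLNFSPGWamide (26-34, 0 C)
#>   mature: AGPYSFGLamide (37-45, 0 C)
#>   mature: EFDDYGHMRFamide (48-58, 0 C)

classify_all(list(ann))$assignments[, c("rendered", "family", "score")]
#>          rendered     family score
#> 1  pQLNFSPGWamide       RPCH     8
#> 2   AGPYSFGLamide      AST-A     4
#> 3 EFDDYGHMRFamide sulfakinin     7
```

The generator planted a 25-residue signal peptide and three amidated
peptides, each followed by a dibasic KR site; the annotation chain recovers
the signal span, all three cleavage sites (labelled by the first basic
residue, e.g. `KR@35`), and the processed peptides in `pQ…amide` notation —
an RPCH octapeptide (pyroglutamate + amide), an A-type allatostatin and a
sulfakinin — each classified into its family with the winning motif's
specificity as the score.

For whole files, `run_neuropeptide_track()` and `run_gpcr_track()` (see
`?pipeline_config`) orchestrate the stages and write TSV/JSON/GFF3-like/
newick reports; `inst/scripts/npmine.R` is a thin command-line wrapper with
`annotate`, `gpcr`, `simulate` and `expression` subcommands.

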