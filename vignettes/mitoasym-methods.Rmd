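---
title: "Methods: mitogenome annotation arithmetic, strand asymmetry and heteroplasmy calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome annotation arithmetic, strand asymmetry and heteroplasmy calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mitoasym analyses annotated circular mitochondrial genomes of the kind
produced for teleost fishes: a single ~16-17 kb circle carrying 13
protein-coding genes, 22 tRNAs, 2 rRNAs and one control region, most genes
on the heavy (H) strand and a minority (ND6 and several tRNAs) on the light
(L) strand. The package ships the published annotation of the
*Austrolebias charrua* reference mitogenome (GenBank KP718940, 17,271 bp)
as its worked reference input. This vignette records the models, the
conventions, and the design decisions behind each stage.

## Coordinate model

Coordinates are 1-based, fully closed intervals on the H strand, the
convention of published mitogenome organization tables. Features crossing
the origin of the circle are stored with `end > length` and normalized on
access; the bundled annotation contains none, but the synthetic generator
and the extraction code support them, and adjacency across the origin is
respected by the intergenic-gap computation (the control region ending at
position 17,271 is flush with tRNA-Phe starting at position 1).

Derived quantities are pure arithmetic on the table:

* `length_nt = end - start + 1`;
* protein length: `length_nt/3 - 1` residues for a CDS with a complete
  stop codon (the stop is not a residue), `floor(length_nt/3)` for one
  ending on an incomplete stop (`T--` or `TA-`), the trailing 1-2
  nucleotides being completed to `TAA` by polyadenylation of the
  transcript;
* the intergenic gap attributed to feature *i* is
  `start(i) - end(i-1) - 1`, i.e. the gap *before* each gene, with the
  first feature's gap computed circularly from the last feature's end.
  Negative gaps are overlaps and are reported as such, never clipped. This
  attribution is the one that reproduces the published spacing column
  (e.g. 115 bp before ND3, -10 at the ATPase8/ATPase6 overlap, -7 at
  ND4L/ND4).

The tRNA length z-score uses the population (divide by *n*) standard
deviation by default; the sample convention is available behind an
argument. The reference length set is always an input — the package does
not bundle a database of cyprinodontiform tRNA annotations.

## Genetic code and codon mapping

The vertebrate mitochondrial code (translation table 2) is the default:
`ATA` encodes Met, `TGA` Trp, and `AGA`/`AGG` are stops. The table is
authored in the package (tests cross-check every codon against an
independent implementation) because translation here must also handle
incomplete terminal codons, report internal stops instead of dropping
them, and propagate `N` as `X`.

A mitogenome position maps into a CDS as `gene_pos = pos - start + 1` on
the H strand and `gene_pos = end - pos + 1` on the L strand; the codon
index is `ceiling(gene_pos/3)` and the offset `((gene_pos - 1) mod 3) + 1`.
The acceptance suite checks this mapping against the published
heteroplasmy table (position 4105 is codon 22 of ND2, 6245 is codon 260 of
COI, 15,735 is codon 368 of Cytb). Two published rows are knowingly
inconsistent with their own coordinates (the codon pair printed for
position 5690 shows two substituted bases for a single-nucleotide change,
and the 12,764 change is printed one offset away from where the coordinate
falls); they are excluded from correctness fixtures rather than
hard-coded.

## Composition statistics

Strand asymmetry is summarized by `GCskew = (G - C)/(G + C)` and
`ATskew = (A - T)/(A + T)` computed on the strand supplied (here the H
strand). Note the sign convention: some literature uses `(C - G)/(C + G)`;
this package fixes the convention above and the property suite pins the
antisymmetry `skew(s) = -skew(revcomp(s))`. `N` bases are excluded from
every denominator, and a skew whose denominator is empty is `NA` with an
explicit flag rather than a silent zero.

Codon-position GC (GC1/GC2/GC3) is computed over the concatenation of raw,
unaligned in-frame CDS on their coding strand — not over alignment columns.
Published tables mix both framings; concatenation is the documented
default here and aligned input (gap characters) is accepted behind a flag.
GC1/2/3 are reported in percent and overall coding GC as a fraction,
matching the mixed units such tables print. Terminal complete stop codons
are excluded from codon-position and usage tallies by default; trailing
bases of incomplete stops are always dropped; any codon containing `N` (or
an alignment gap) is excluded whole.

Correspondence analysis is the classical chi-square form: with `P` the
proportion table, `r` and `c` its margins, the standardized residual
matrix `S = D_r^{-1/2}(P - rc')D_c^{-1/2}` is factorized by SVD and rows
and columns are reported in principal coordinates; per-axis inertia is the
squared singular value, and total inertia equals the Pearson chi-square of
the table divided by its grand total. The implementation is ~30 lines of
base linear algebra; tests verify the chi-square identity, the closed-form
2x2 case, reconstruction of `S` from the coordinates to 1e-8, agreement of
eigenvalues with an independent CA implementation (vegan), and that axis 1
of a six-genome GC gradient orders the genomes exactly by coding GC
(|Spearman rho| = 1), mirroring the perfect rank correlation reported for
real cyprinodontiform mitogenomes. Spearman correlations themselves are
delegated to `stats::cor.test`, which gives the exact permutation p-value
for small tie-free samples; a brute-force enumeration over all n! = 720
permutations backs it in the tests.

Third-codon-position stripping (used before phylogenetic re-inference when
third positions are saturated) removes exactly the chosen position's
columns from a codon alignment and refuses widths that are not a multiple
of three. The stripped product is no longer translatable and the package
deliberately offers no translation on it.

## The heteroplasmy caller

The caller consumes samtools-mpileup text (the parser decodes `^`/`$`
read boundaries, case-encoded strands, indel syntax, and tracks read
identities across columns from the boundary markers). An extended dialect
with two extra columns — per-observation read positions, as produced by
`samtools mpileup -O`, and read lengths — supplies distances to the read
ends; without it those distances are unknown and the end-distance filter
passes. Mapping- and base-quality gates (Phred 30/30 by default, the
conventional `-q 30 -Q 30` preprocessing) are applied before any counting,
so "coverage" always means gated depth; this also matches the reported
support fractions, which are quoted against gated totals.

A site becomes a variant when all of the following hold:

1. gated coverage >= 20;
2. there is a single alternative nucleotide. Two distinct alternatives
   each backed by at least two gated reads reject the site as
   multiallelic. The two-read evidence level defining "an alternative
   nucleotide is present" is fixed, which keeps the caller monotone in its
   configurable thresholds: raising `min_coverage`, `min_alt_reads`, the
   end distance or the window can only shrink the accepted set (a property
   the tests fuzz);
3. the alternative is supported by at least two *clean* observations with
   at least one on each mapping strand. An observation is clean when it
   lies at least 5 bp from both read ends and its read matches the
   reference everywhere within +/-5 bp of the site.

The qualitative filter descriptions "far away from the read ends" and
"error-free neighborhood" are quantified here as 5 bp / +/-5 bp; both are
configurable parameters and documented assumptions. They are implemented
as *filters deciding which observations count as support*, not as
site-level vetoes: a deep heteroplasmy at 30% frequency typically has a
few of its ~30 supporting reads near an end, and vetoing the site for that
would make high-frequency sites undetectable. The flank check uses all
observations of the supporting read, including low-quality ones.

Rejection is a value with a machine-readable reason (`min_coverage`,
`multiallelic`, `min_alt_reads`, `support_filtered`,
`strand_requirement`), never an error. Indels are parsed but excluded from
calling; substitutions only. Effects are classified on the coding strand
(alleles complemented for L-strand genes) into synonymous / non-synonymous
/ nonsense, with Ts/Tv labelling; the classification is a pure function of
the two codons and is exhaustively verified over all 64 x 9
single-nucleotide codon changes.

The cross-sample report merges per-sample calls by site, prints
`alt/total` support strings, and flags sites shared across samples and
sites where the reference individual itself carries the alternative
(reference heteroplasmy): mapping siblings against one sibling's assembly
means a maternal variant can be present in the reference itself, and such
sites are surfaced through the flag rather than suppressed.

## The synthetic generator

The generator exists so every stage is testable without downloads; its
defaults are the study conditions of the reference mitogenome. The default
layout is the full published 38-feature organization, the default base
composition the measured one (fA 0.284, fC 0.222, fG 0.146, fT 0.348), and
the default control-region duplication the published 180 bp internal
tandem repeat. Sequence outside genes is drawn iid from the target
composition; CDS bodies are random non-stop codons in the gene's own
frame, started and terminated per the annotation (including trailing
`T`/`TA` of incomplete stops written literally at the boundary).
Overlapping genes are reconciled in two passes: annotated start/stop
codons are re-imposed after all bodies are written (real mitochondrial
overlaps, such as an upstream stop inside the downstream gene, are
mutually compatible and verified to be so), then an iterative repair
replaces any stop codon introduced into an overlapped frame, touching only
positions outside annotated start/stop codons. Generation is byte-identical
under a fixed seed.

The read simulator emulates a short single-end deep-coverage run (66 bp
reads by default): uniform placement on the circle (reads crossing the
origin are emitted as two segments, as a linear aligner would report
them), 50/50 strand choice, planted heteroplasmies carried independently
per read at the planned frequency, and a positional error model — a flat
per-base rate with a multiplier over the last 5 bases of the read, so that
errors concentrate where the read-end filter looks. Base qualities are
drawn from two normal profiles (mean Q37 for correct calls, mean Q15 for
errors, both clipped to [2, 41]), reflecting the strong quality/error
correlation of Illumina base calling; this is what makes the Phred-30 gate
meaningful on simulated data. What the simulator does *not* model: PCR
duplicates, strand-biased error spectra, alignment artefacts around
indels, and contamination — so passing recovery tests demonstrate the
filter cascade's arithmetic, not robustness to every real-data pathology.

The recovery experiment plants 10 sites at a chosen frequency and
coverage on a 1.2 kb toy genome and scores sensitivity and false
positives per replicate. At 100x coverage, 0.1% error and 30% frequency
the cascade recovers >= 9/10 sites with zero false sites in each of 20
seeded replicates; at a frequency where the expected alternative support
is below two reads, recovery is zero by threshold arithmetic. Problem
sizes in the test suite (toy genomes of 0.7-2.4 kb, coverages of 25-200,
20 replicates) were chosen to give stable binomial expectations at
interactive runtimes.

## Numerical and degenerate-input choices

* Ties between two alternative bases at equal support reject the site as
  multiallelic (single-alternative rule).
* All-`N` sequences, zero-variance z-score references, constant vectors in
  rank correlation, all-zero CA rows/columns, and rank-0 CA tables raise
  errors rather than returning NaN.
* Unknown read-end distances and unknown mapping qualities pass their
  gates (they are unknowable in the plain pileup dialect, and failing them
  would silently disable calling on standard input).
* The caller's per-sample totals are gated depth; published support
  strings are reproduced under this reading.

## Command-line interface

The R functions are the primary interface. A thin Rscript front-end at
`inst/cli/mitoasym.R` exposes `annotate-stats`, `composition`, `ca`,
`call`, `simulate` and `run` subcommands over them; `run` executes the
full pipeline from a YAML config and writes TSV/JSON artifacts plus a
manifest embedding the configuration and its hash, so a run is
reproducible from its own manifest. Reports carry no timestamps; identical
config and seed give byte-identical output.

## Known limitations

* Reproducing the published whole-genome composition row requires the
  KP718940 sequence itself, which is not redistributed here; the
  composition layer is instead pinned by hand-computable micro-sequences
  and the skew/reverse-complement property suite.
* The GenBank reader is minimal (simple `start..end` and
  `complement(start..end)` locations; no `join`), sufficient for typical
  mitogenome records.
* Read tracking across pileup columns assumes mpileup's stable read
  ordering; files truncated mid-read are tolerated but their first
  partial column cannot contribute flank information.
* The caller detects substitutions only, and multi-chromosome pileups are
  not supported (mitogenomes are single circles).
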