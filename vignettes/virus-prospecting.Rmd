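---
title: "Prospecting divergent RNA viruses in metatranscriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prospecting divergent RNA viruses in metatranscriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nonaxenic microalgal cultures sequenced as total-RNA metatranscriptomes
yield assemblies dominated by host transcripts, rRNA remnants and
bacterial/phage material, with any RNA viruses hidden among them.
Because RNA virus hallmark genes — above all the RNA-dependent RNA
polymerase (RdRp) — can sit at 25–40% amino-acid identity to their
closest relatives, straightforward similarity search misses a large part
of the virosphere, and a substantial fraction of contigs ends up with no
annotation at all ("dark matter"). `rdrprospector` implements a staged
discovery procedure for exactly this regime, together with a synthetic
metatranscriptome generator that makes every stage testable against a
known truth table.

## The procedure

1. **Evidence tiers.** Every contig's longest reading frames are
   searched against a labelled protein reference set (Smith–Waterman,
   BLOSUM62, gap 11/1, Karlin–Altschul e-values). Contigs partition into
   `strong_hit` (e < 1e−05), `weak_hit` (1e−05 ≤ e < 1e−03),
   `orphan_long_orf` (no hit below 1e−03 but an ORF of ≥ 200 amino
   acids) and `dark_matter`. ORFs here are maximal stop-free regions in
   any of the six frames: no start codon is required and partial ends
   are retained, because assembled viral contigs are routinely truncated.
   The 200-aa gate is shorter than most RdRps yet long enough to carry
   an evolutionary signal.
2. **Profile screen of orphans.** Orphan ORFs are scored against
   profile HMMs of the RdRp family and against *decoy* profiles (phage
   and cellular families). The scorer is a local (free entry/exit into
   match states) profile Viterbi in bit units, with a forward variant
   over the same path set; e-values come from a Gumbel fit to a
   shuffled-sequence null.
3. **Decoy arbitration.** A contig is a candidate virus iff the single
   best-scoring hit — across viral profiles, decoy profiles and
   reference targets — is viral. A phage decoy winning the comparison
   rejects the contig with reason `phage-like`. This is a
   winner-takes-all reading of "best hit", which keeps the rule
   deterministic (ties break lexicographically).
4. **Catalytic-motif gate.** Candidate ORFs are scanned for the RdRp
   palm motifs in order: A (`D-x(2,4)-D`), B (`G-x(1,3)-[N/T]`) and the
   catalytic C tripeptide (canonical GDD/SDD/GDN; variants such as GFD
   are reported but non-canonical). A full A < B < C architecture marks
   the candidate `confirmed`; anything less leaves it `unresolved` but
   *retained* — absence of motif evidence is treated as reduced
   confidence, not refutation.
5. **Frameshifts and genetic codes.** The GGAUUUU (DNA `GGATTTT`)
   slippery heptamer is located on both strands; overlapping ORFs one
   frame apart can be fused by the −1 frameshift rule (translate ORF1
   through the heptamer's last complete codon, resume one nucleotide
   back in the −1 frame). ORF prediction runs under both the standard
   code (table 1) and the protozoan mitochondrial code (table 4, UGA =
   Trp), since some algal viruses only reveal an intact replicase under
   table 4.
6. **Abundance.** Per-contig read counts are expressed as percent of
   the library's non-rRNA reads; 0.01% anchors "average" and 1.2%
   "very high" abundance (boundaries closed on those anchor values).
7. **Demarcation.** Candidate RdRps are compared all-against-all with
   Needleman–Wunsch global identity (terminal-gap columns trimmed,
   internal gaps counted as mismatched columns), clustered into species
   by single linkage at a demarcation threshold (90% for partiti-like,
   50% for narna-like RdRps), placed against intra-/inter-genus identity
   distributions (PASC-style), and summarised as a neighbor-joining tree
   on 100 − identity distances.

## The synthetic-data generator

`library_plan()` fixes a mock nonaxenic algal library; its defaults are
the study conditions used throughout the tests and the acceptance
script:

* 30 host-like contigs (450–2400 nt). Half derive from reference host
  proteins (mutated to ~85% identity, so they produce strong nonviral
  hits); the rest are random codon strings with a stop frequency of
  0.012 per codon, which leaves a realistic fraction of hosts carrying
  ORFs ≥ 200 aa — the orphan tier must be populated for the decoy logic
  to be tested at all.
* 6 rRNA-like tandem-repeat contigs (60-mer × 12), excluded from the
  non-rRNA read total.
* 4 bacteriophage decoy contigs encoding proteins at ~70% identity to
  the decoy-profile seeds; they are deliberately absent from the
  reference set so they land in the orphan tier and exercise
  arbitration.
* 3 planted viruses covering the architectures and the abundance
  classes: a single-ORF virus at 80% identity to its source
  (1000 reads), a −1 frameshift virus under the protozoan mitochondrial
  code at 60% identity (25 000 reads ≈ 1.25%, "very high"), and a
  two-ORF virus at 40% identity whose source is *not* in the reference
  set (200 reads = 0.01%, "average") — the novel clade only the profile
  route can find.
* Read counts: planted viruses keep their planned counts; the remaining
  non-rRNA total (2 × 10⁶ by default) is spread over host and phage
  contigs with log-normal weights (meanlog 4, sdlog 1.5).

Divergence is substitution-only: `mutate_protein()` replaces exactly
`round(L·(1−t/100))` positions with BLOSUM62-exchangeable residues, so
realized identity sits within rounding of the target. The 13 residues of
the planted catalytic motifs are protected, mirroring the conservation
of catalytic sites in real homologs. Back-translation picks synonymous
codons uniformly (codon bias is out of scope). No sequencing-read
simulation is performed — counts are drawn directly, because assembly
and quantification are upstream of the logic this package owns.

What the generator does **not** emulate: sequencing error, chimeric
contigs, strain mixtures, rRNA secondary structure, codon bias, and real
database heterogeneity. Passing tests therefore demonstrate that the
decision rules are implemented faithfully and are recoverable under
controlled divergence — not that the pipeline's sensitivity on real
libraries equals the synthetic recall.

## Numerical choices

* **Profile model.** Profiles built from a single seed protein emit
  residue *a* at a column with seed residue *b* proportionally to
  `bg(a)·2^(B62[a,b]/2)` — roughly half-bit BLOSUM scores, tolerant down
  to the 25–40% identity regime. Core transitions are MM 0.97 / MI 0.02
  / MD 0.01, insert emissions equal the background. Local alignment
  enters and exits match states at zero cost and the empty alignment
  scores 0, so Viterbi scores are nonnegative and forward ≥ Viterbi by
  construction.
* **Calibration.** Each profile's null is 200 background sequences of
  350 aa (a typical ORF length); a Gumbel is fitted by the method of
  moments. The calibration is a property of the profile, not of a
  library, so it is computed once per profile under a fixed seed and
  cached.
* **Statistics.** The similarity layer uses fixed gapped-BLOSUM62
  Karlin–Altschul constants (λ = 0.267, K = 0.041) with search space
  m·n over the whole reference set.
* **Boundaries.** Tier bounds are half-open: e < 1e−05 strong,
  [1e−05, 1e−03) weak. Abundance classes are closed on their anchors
  (≤ 0.01 average, ≥ 1.2 very high). Identity denominators exclude
  terminal-gap columns but count internal gaps — a declared convention;
  absolute identities from other aligners will differ slightly, which is
  why demarcation logic, not absolute identity values, is the tested
  contract.
* **Degenerate inputs.** Codons containing N translate to X and never
  terminate a stop-free region (conservative extension). Empty hit
  lists arbitrate to "no hits", an empty tier summary has zero rows, and
  a single-sequence identity matrix is the 1×1 matrix of 100.

## Open design points, resolved

* Whether frameshift-overlap scanning was systematic or manual in the
  original procedure is unknowable from the outside; here every heptamer
  inside any −1-frame ORF overlap is a candidate, and the fusion rule is
  fixed as stated above so the generator and the detector agree exactly.
* The 200-aa gate is applied only on the orphan route; similarity search
  uses the three longest frames per contig at ≥ 80 aa, since short hits
  are the similarity stage's job to rank, not the gate's to exclude.
* Motif definitions are conservative minimal consensus patterns rather
  than PSSMs: motif verification in the field is commonly done by manual
  alignment inspection, which these patterns operationalise; they are a
  declared approximation and the `unresolved` outcome never discards a
  candidate.
* A candidate found by both routes is reported once with the
  winner-takes-all route recorded; synthetic candidates keep their truth
  names only in the truth table — report names are contig-derived.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
200 random contigs (≤ 3 kb) against the brute-force ORF oracle,
exhaustive alignment/path enumeration up to 6 residues and 4 match
states, 20 replicate libraries (43 contigs each) for recovery and
false-positive measurement in the suite, and 10 libraries plus a
byte-level determinism re-run in the acceptance script. These sizes were
chosen to keep a desk-scale run comfortable while leaving every decision
rule exercised end to end.

## Known limitations

* Bit scores are not HMMER-comparable; only the relative ordering and
  the package's own calibrated e-values are meaningful.
* The similarity stage is protein-level only; nucleotide-level evidence
  (the 1e−10 BLASTn regime) is folded into the single protein threshold.
* Single-linkage demarcation can chain clusters when identities sit
  exactly at the threshold; the tests only assert partitions where
  planted identities straddle thresholds by ≥ 5 points.
* The neighbor-joining tree is descriptive plumbing, not a substitute
  for maximum-likelihood phylogenetics.
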