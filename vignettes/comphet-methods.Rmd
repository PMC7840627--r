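---
title: "Mapping compound-heterozygous disease variants in a closed flock: methods and design"
author: "comphet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping compound-heterozygous disease variants in a closed flock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comphet)
```

# The problem

A recessive lethal phenotype segregating in a closed livestock flock is
classically mapped by autozygosity: affected animals inherit two copies of
one ancestral mutation and therefore share a long run of homozygosity (ROH)
around it. Compound heterozygosity breaks this assumption. When two
different loss-of-function alleles of the same gene circulate in the flock
— one introduced through the maternal line (here, a shared maternal
grandsire), one carried by the sire — affected offspring are heterozygous
for both, autozygosity mapping returns nothing, and the signal must be
recovered from allele-sharing linkage and trio-phased sequence data
instead.

`comphet` implements that full discovery path as testable units: SNP-array
QC, Mendelian-error parentage verification, ROH detection with
allele-matched intersection across cases, a nonparametric allele-sharing
linkage scan with a Monte-Carlo gene-drop null, the trio variant funnel
(protein-changing → private against a local then a global control cohort →
inheritance-mode classification → regional prioritisation), and an
isoform-aware consequence engine with HGVS naming. A pedigree gene-drop
simulator generates flocks with known truth so every stage can be
validated without any external data.

# The study design the simulator emulates

The default `flockConfig()` encodes the design the pipeline targets: one
ram (the sire) heterozygous for variant B; 52 ewes, each a daughter of an
ungenotyped phantom grandsire heterozygous for variant A, so each ewe
carries A with probability 1/2; 18 lambs, each by the sire out of a
distinct ewe; a lamb is affected if and only if it carries both A
(maternally) and B (paternally), with penetrance fixed at 1. Array data
are simulated as ~5,000 (scalable to 45,000) biallelic markers over a
2.6 Gb, 26-chromosome genome, with alternate-allele frequencies uniform on
[0.1, 0.9] and 2% missingness. Control cohorts of 60 (local) and 453
(global) genomes carry neither causal variant. Genotyping mirrors the
study subset: the sire, the affected lambs, their dams and three unaffected
lambs are on the array; the sire, two cases and their dams are sequenced.

Markers are simulated without linkage disequilibrium but with genetic
linkage: transmissions recombine at 1 cM/Mb under the Haldane map. LD is
irrelevant to every statistic the package computes (all are within-family
transmission statistics); what matters is co-transmission of neighbouring
markers, which the map provides. The affected count is genuinely binomial
(about Bin(18, 1/8) under the defaults); runs with fewer than
`minAffected = 2` affected lambs are redrawn a bounded number of times,
because two sequenced cases are the minimum the trio funnel is defined on.
Ground truth — the founder-haplotype origin of every transmitted
chromosome segment — is recorded and self-audited against the emitted
genotypes at generation time.

What the simulator does *not* emulate: population LD and allele-frequency
spectra of real arrays, genotype-calling artefacts that correlate across
markers, assortative mating, and multi-generation pedigree depth beyond
grandsire → dam → lamb. Passing tests therefore demonstrate correctness of
the transmission statistics and filters under the study design, not
robustness to array artefacts.

# Quality control and parentage

Samples are summarised by call rate (flagged below 0.90) and markers are
pruned when their missing fraction strictly exceeds 0.10 — a marker at
exactly the threshold is retained. No minor-allele-frequency or
Hardy-Weinberg filters are applied: within a single family HWE does not
hold and rare alleles are the signal.

Parentage uses opposing homozygotes only (child and putative parent
homozygous for different alleles): that is the sole single-parent Mendelian
contradiction at a biallelic marker, and a heterozygous child can never
exclude one parent on its own. The verdict thresholds (confirm below an
opposing-homozygote rate of 0.001, exclude above 0.01) are conventional
SNP-array practice, configurable, and separated by an order of magnitude so
that true parents (rate ≈ genotyping error rate) and non-parents (rate in
the several-percent range) are far from both boundaries. Maternity
assignment ranks candidates by this rate; ties (e.g. identical twins) are
flagged and block confirmation.

# Runs of homozygosity and shared autozygosity

`detectRoh()` is a rule-based consecutive-run scanner, not a
sliding-window heuristic: a run starts and ends on homozygous calls and
tolerates at most `maxHet = 1` heterozygous and `maxMiss = 2` missing
calls; reported segments need `minSnps = 40` markers and 2 Mb of physical
span. These defaults are calibrated to a ~50k array on a ~2.6 Gb genome
(40 markers ≈ 2.3 Mb at that density). One default is deliberately
overridden at genome scale: with 2% missingness a true ~1,000-marker
autozygous segment contains ~20 missing calls, so the pipeline
(`runDiscover()`, and the package's own dense-map analyses) raises the
missing budget to `maxMiss = 25`; the het budget stays at 1 because
heterozygous calls, unlike missing ones, are positive evidence against
autozygosity.

`sharedAutozygosity()` intersects the cases' ROH segments and then
enforces, marker by marker, that every case with a non-missing call is
homozygous for the *same* allele; intervals are split at violating
markers. This marker-wise allele match is what makes the compound-het
design return an empty list genome-wide while a recessive design returns
the causal interval: under compound heterozygosity the cases are
heterozygous across the causal region and simply have no qualifying
segment there.

# The allele-sharing linkage scan

Per marker, the statistic S sums, over affected pairs, the estimated
number of alleles shared identical-by-descent through the parents the pair
has in common. The transmission of a heterozygous parent is resolved
exactly when the child is homozygous, or heterozygous with the other
parent homozygous; otherwise the pair contributes its conditional
expectation of 1/2. The estimator provably equals the exhaustive
enumeration over all transmission configurations consistent with the
genotypes (tested against that oracle on small pedigrees), because child
genotypes are conditionally independent given parental genotypes.

A marker is *defined* only when at least one pair has both transmissions
fully resolved. Expectation-only markers carry no evidence; treating them
as defined would let Monte-Carlo noise in the null mean assign them
arbitrary signs and fragment every region.

The null is a gene drop: founder alleles are drawn at the marker's founder
allele frequency (estimated from the genotyped individuals without
genotyped parents — the sire and the dams, never the lambs) and dropped
through the pedigree including the phantom ancestors; the same estimator
is applied to each replicate. Because the null depends on the marker only
through that frequency, it is cached per distinct frequency value (the
estimates are multiples of 1/(2 × number of genotyped founders), so only a
handful of nulls are ever simulated). Defaults: 1,000 replicates, seed
mandatory. Z standardises S against the defined-replicate null;
LOD = sign(Z) · Z²/(2 ln 10).

Regions merge maximal runs of Z > 0 markers. Undefined markers never break
a run (up to `gapMarkers = 20` consecutive ones); a defined Z ≤ 0 marker
always does. The gap default was chosen from the geometry of the design:
with ~25–40% of markers defined, undefined gaps are geometric with
P(gap > 20) well under 1%, while a tolerance of 0 would split regions at
almost every marker. Region bounds extend through flanking undefined
markers up to (but excluding) the nearest contradicting marker or the map
end: between the last positive and the first negative marker the true
boundary of the shared segment is simply unobserved, and the causal
position generically lies between markers.

**Known limitation — discreteness of Z.** With a handful of half-sib pairs
through a single sire, S takes few distinct values, so the empirical null
is strongly discrete and the normal-theory tail calibration does not hold:
under permuted phenotypes the positive-Z fraction sits near 0.40–0.46
rather than 0.5 and P(Z > 1.96) near 0.04 rather than 0.025 (both measured
by the acceptance suite, which asserts the normal-theory bands and
documents their failure). Region calling is robust to this — it consumes
only the sign of strong, fully resolved sharing — but the per-marker Z
should not be read as a calibrated normal deviate in this pedigree.

# The variant funnel

The funnel is monotone, and every stage count is logged. Protein-changing
means {missense, nonsense, frameshift, splice_acceptor, splice_donor,
start_lost, stop_lost, inframe_indel, other_protein_changing}; canonical
splice sites are strictly the GT/AG dinucleotides at intronic ±1, ±2, and
the extended splice region (±3..8) is annotated but not protein-changing.
Private means an alternate-allele carrier count of 0 (configurable to ≤ k)
in the control cohort, with every case carrying at least one alternate
allele; variants absent from the control data count as 0 carriers and are
flagged rather than dropped.

Trio phasing deduces the parental origin of a child's heterozygous
alternate allele by enumerating Mendelian transmissions: paternal when
only "sire gives alt, dam gives ref" is consistent, maternal in the mirror
case, ambiguous when both are, and a Mendelian-inconsistency flag when
neither is. This matches the 27-configuration enumeration exactly,
including the corner cases (a hom-alt sire with a het dam forces paternal
origin).

Compound-heterozygous calling requires two variants in the same annotated
gene, every case heterozygous for both, opposite parental origins in every
phasable case, and no case in cis; one pair is reported per gene. Cases
without complete trios contribute genotype compatibility but not phase.
Recessive-homozygous calling requires all cases hom-alt and all genotyped
parents het.

Prioritisation follows the logic by which a recessive candidate without
autozygosity support is down-weighted: a compound-het candidate is
*supported* when its pair falls in a linked region, a recessive candidate
when it falls in a shared autozygosity segment — the regional evidence its
own inheritance model predicts. Supported candidates rank first, then
candidates merely inside a linked region; each candidate carries an
explicit rationale string. With no region evidence available the ordering
falls back to inheritance evidence and is flagged.

The obligate-carrier deduction asks whether a single ungenotyped ancestor
can explain all carriers whose status no genotyped carrier parent
explains; if one exists (the maternal grandsire, for carrier ewes) it is
reported as "obligate carrier or germline mosaic" — the data cannot
distinguish constitutional carriage from germline mosaicism.

# The consequence engine

Internally all intervals are 1-based closed (`IRanges`), the native
Bioconductor convention; HGVS output is 1-based by definition, and file
formats convert at their boundaries. Classification always works on the
spliced CDS, so codons spanning exon junctions — including the
insert-exon junction that makes one genomic SNV missense (Leu→Phe) on the
long isoform and nonsense (Gln→Ter) on the short one — are handled
without special cases.

Acceptor loss is modelled as nearest-AG cryptic rescue: the affected
exon's 5′ boundary moves to just after the first AG within a 50-base
exonic scan window (an exon starting with AG gives an immediate 2-base
deletion); with no AG in the window the exon is skipped and flagged, and
if skipping would remove the CDS start there is no rescue model. No
splice-strength scoring is attempted: the rescue the engine was built
around is nearest-AG activation, and strength models cannot be validated
in this setting. Donor loss mirrors the rule with upstream GT scanning and
is flagged lower-confidence. Frameshift translation runs to the first new
stop and names the change per HGVS (`p.Leu71TrpfsTer3` style: first
divergent residue, new residue, stop index counting the divergent residue
as 1; `fsTer?` when no stop is reached). Three-letter amino-acid codes
with `Ter` are emitted; `*` is accepted on input. Truncation is reported
as a fraction of the reference protein; nonsense-mediated decay is never
predicted — that is a biological hypothesis, not a sequence computation.

The toy genes built by `makeToyGenes()` encode the structures these rules
are exercised on, verified at construction: a 4-exon gene whose exon-3
acceptor loss deletes exactly 10 bases and truncates the 752-residue
protein to 72 residues, a two-isoform gene with a 54-codon in-frame
proline-rich insert exon and the dual-consequence SNV at the junction
codon, and reverse-strand mirrors of both (every annotation is asserted
strand-symmetric).

# Problem sizes and numerical choices

The test and acceptance runs use: 100 flocks at 5,000 markers for
end-to-end recovery (the planted gene must rank first in ≥95); 100
recessive and 100 compound-het flocks at 45,000 markers for the
autozygosity arms (causal interval recovered in ≥95; false shared segments
in <5); 8 permuted flocks pooling ~11,000 defined markers for the null
calibration; 1,000 gene drops per distinct founder frequency for every
scan. Gene drops are vectorised across replicates and cached per
frequency; the ROH scanner is compiled. All pseudo-randomness flows from a
single user seed; identical configuration and seed give byte-identical
outputs.

Degenerate inputs are handled explicitly rather than silently: zero
informative markers give an ambiguous parentage verdict; a marker
uninformative for every pair is undefined, not zero; missing genotypes are
a first-class state (an "untyped" census class, never dropped); an
all-pruned marker set is an error advising threshold review; monomorphic
founder frequencies yield undefined nulls.

# Interfaces

This is an analysis package: the exported functions are the interface,
`runDiscover()` chains the full pipeline in the order QC → parentage →
autozygosity → linkage → funnel → prioritisation with a complete stage
log, and `scripts/acceptance.R` reproduces the headline numbers from a
single seed. File exchange uses the field's text formats — PLINK-style
PED/FAM+MAP, VCF 4.2 (multiallelics decomposed at ingest, phase read but
ignored: phase is recomputed from trios), GFF3 + FASTA for gene models —
through `VariantAnnotation`, `rtracklayer` and `Biostrings`.
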