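# comphet

Disease-gene discovery for closed livestock flocks in which a recessive
phenotype is caused not by a single homozygous mutation but by **compound
heterozygosity**: two different loss-of-function alleles of one gene, one
per homolog, jointly abolishing its function. The package is written for
geneticists working with SNP-array plus trio whole-genome-sequencing
designs — the setting of a single sire, a cohort of related dams, and a
lambing season's affected offspring — where autozygosity mapping comes up
empty and the causal pair must be recovered from allele-sharing linkage
and trio-phased variant filtering.

## What it computes

Let the affected offspring be pairs *(i, j)* sharing a parent. At each
marker the scan computes the allele-sharing statistic

S = Σ_{i<j} Σ_{P ∈ shared parents} Pr(transmission_i = transmission_j | genotypes),

the expected number of alleles shared identical-by-descent, with each
transmission resolved from parental genotypes where unambiguous and set to
its conditional expectation ½ otherwise. S is standardised against a
Monte-Carlo **gene-drop null** (founder alleles dropped through the
pedigree at the marker's founder allele frequency, the same estimator
applied), giving Z and a signed LOD = Z²/(2 ln 10); maximal runs of Z > 0
markers form candidate linked regions.

In parallel, runs of homozygosity are detected per case (consecutive-run
scan with heterozygous/missing tolerances) and intersected across cases
with a marker-wise same-allele requirement, and trio sequence variants are
funnelled: protein-changing → private against a local and then a global
control cohort → inheritance-mode classification (recessive-homozygous vs
compound-heterozygous with trans phase required in every phasable trio) →
prioritisation by the regional evidence each mode predicts (linked region
for a compound-het pair, shared autozygosity for a recessive variant). An
isoform-aware consequence engine maps variants to HGVS c./p. names,
including canonical splice-site loss with nearest-AG cryptic-acceptor
rescue and frameshift translation.

A pedigree simulator (`simulateFlock`) generates the whole design — a
phantom grandsire heterozygous for variant A siring the ewes, the ram
heterozygous for variant B, lambs affected iff they carry both — with
recombination, missingness, control cohorts and full transmission truth,
so every stage is testable with no external data.

## Worked example

```r
library(comphet)

fl  <- simulateFlock(flockConfig(seed = 42))   # synthetic flock, known truth
res <- runDiscover(fl, seed = 7)               # QC -> parentage -> ROH ->
                                               # linkage -> funnel -> report
res$report[, c("rank", "candidateId", "mode", "inLinkedRegion", "supported")]
#>   rank     candidateId          mode inLinkedRegion supported
#> 1    1 GENE_CH:comphet  compound_het           TRUE      TRUE
#> 2    2  9:12345678:A:G recessive_hom           TRUE     FALSE
```

The planted compound-het pair ranks first: it sits in a linked region, the
evidence its inheritance model predicts, while the recessive decoy — in a
linked region by chance — lacks the shared-autozygosity support a
recessive allele would require (`res$sharedRoh` is empty under the
compound-het design). The run log records the funnel counts
(`10 -> 8 -> 6 -> 6 -> 4` variants through effect, local-privacy,
inheritance and global-privacy filters) and sire confirmation for all 7
genotyped lambs (`res$log`).

The consequence engine on the built-in toy gene, whose intron-2 acceptor
variant activates a cryptic splice site:

```r
tg <- makeToyGenes(seed = 1)
v  <- tg$variants[1, ]   # the acceptor-loss SNV
annotateAllIsoforms(v$pos, v$ref, v$alt, tg$models["TOYA.1"])
#>   transcriptId     effectClass      hgvsC            hgvsP mutantProteinLength
#> 1       TOYA.1 splice_acceptor c.211-2A>G p.Leu71TrpfsTer3                  72
```

The rescue deletes 10 bases at the exon's 5′ end, shifting the frame at
residue 71 (Leu→Trp) with a stop two codons later: a 72-residue protein,
over 90% of the reference lost.

The two-variant census over the 71-animal flock fixture
(`encodeFig2aFixture()` + `segregationCensus()`) cross-tabulates every
animal: 5 double heterozygotes, all of them the affected lambs; 27 of 52
ewes carrying only the maternal-line variant; no animal unaccounted for.

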