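---
title: "Genotype-first screening with GenePy scores and CNV integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-first screening with GenePy scores and CNV integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Recessive *NPHP1* disease (nephronophthisis and its retinal and
neurological syndromic forms) is classically caused by a recurrent
whole-gene deletion at 2q13. Two properties of short-read cohort data
make the SNV contribution hard to see: cohorts are unphased, so
compound-heterozygote candidates cannot be resolved without parental
genomes, and a heterozygous whole-gene deletion makes any variant on the
retained chromosome *look* homozygous, so deletion+SNV compound
heterozygotes are invisible unless the CNV calls are joined to the SNV
calls. This package implements a genotype-first screen that addresses
both: a per-individual gene pathogenicity score that pools SNVs, indels
and deletions, followed by rule-based biallelic classification with
trio-based phasing.

## The score

For individual $h$ and gene $g$,

$$S_{gh} = -\sum_{i=1}^{k} D_i \log_{10}(f_{i1} \cdot f_{i2})$$

over biallelic variant loci $i$, with $D_i$ the CADD PHRED
deleteriousness and $f_{i1}, f_{i2}$ the population frequencies of the
two alleles the individual actually carries: $(f, 1-f)$ for a
heterozygote, $(f, f)$ for a homozygous alternate, $(1-f, 1-f)$ for a
homozygous reference. The score is additive over loci, monotone in
deleteriousness and rarity, and invariant in *ranking* under any linear
rescaling of $D$ (tested as properties).

Three design points were genuinely open and are resolved as follows:

- **$D$ is used on the raw CADD PHRED scale**, not renormalised to
  $[0,1]$. The deletion rule assigns $D$ directly as a maximal CADD
  score, which only makes sense on the raw scale, and ranking — the
  quantity the screen consumes — is invariant to linear rescaling. Other
  GenePy releases normalise deleteriousness internally; `gene_score()`
  accepts any annotation columns, so a user can pre-scale `cadd_phred`
  if they need score-level compatibility.
- **Homozygous-reference genotypes contribute** their (tiny)
  $-D\log_{10}((1-f)^2)$ term by default, reading "observed zygosity"
  literally; `include_homref = FALSE` zeroes them. At the default rare
  frequencies these terms are orders of magnitude below one carrier
  term and never perturb the carrier ranking.
- **Frequency floor.** How unobserved (novel, or zero-frequency) alleles
  enter the log term is unstated anywhere authoritative; they must be
  floored for finiteness. The default floor is $10^{-5}$ — about one
  allele among tens of thousands of genomes — with a symmetric ceiling
  $1 - 10^{-6}$ guarding the reference-allele factor. Both are
  arguments of `join_annotations()`.

### CNV integration

A whole-gene deletion is one extra biallelic locus: $D_{\mathrm{cnv}}$
is the maximal CADD PHRED among stop-gain variants in the gene's
annotation set (`derive_d_cnv()`; the deletion is at least as damaging
as the worst premature stop, and a configured fallback of 45 is used
with a warning when no stop-gain is annotated), and
$f_{\mathrm{cnv}} = 1.798 \times 10^{-3}$, the reference
structural-variant deletion frequency, itself reproducible as $39 /
21{,}694$ from the reference carrier counts. A homozygous deletion
contributes $-D\log_{10}(f^2)$, a heterozygous one
$-D\log_{10}(f(1-f))$. Duplications are excluded with a warning — only
deletions are integrated. A heterozygous deletion co-occurring with a
heterozygous SNV contributes two independent terms; no interaction term
is modelled.

## Quality control

Thresholds (all configurable in `qc_thresholds()`), applied in a fixed,
composable order — genotype level first, so the site-level statistics
see the post-filter missingness:

| parameter | default | meaning |
|---|---|---|
| `min_gq` | 20 | genotype kept iff GQ **>** 20 (strict) |
| `min_dp` | 10 | genotype kept iff DP **>** 10 (strict) |
| `min_site_mean_gq` | 35 | site mean GQ over non-missing genotypes **>** 35 |
| `max_missingness` | 0.70 | site missing fraction **≤** 0.70 (inclusive ceiling: "maximum" denotes an allowed value) |
| `min_cadd_phred` | 15 | scoring eligibility, CADD **>** 15 (the median CADD of canonical splice and non-synonymous changes) |

Strict-versus-inclusive boundaries follow the printed conventions of the
standard VCF filtering tools and are pinned by boundary tests (GQ = 20
fails; missingness = 0.70 passes). Multi-allelic records are decomposed
to biallelic records at read time; genotypes carrying a third allele are
treated as missing for the record under consideration. Coordinates are
1-based inclusive throughout.

## Classification and phase

Per sample, in priority order: copy number 0 → `homCNV`; copy number 1
plus *any* alternate allele at an eligible site → `compHet_CNV_SNV`
with phase forced `confirmed_trans` (hemizygosity leaves only the other
chromosome — note the variant will present as homozygous-appearing, which
is why the CNV table is consulted before the homozygous-SNV rule);
homozygous eligible SNV → `homSNV`; two or more eligible heterozygotes →
`compHet_SNV_SNV`, phased with `resolve_phase()` over all pairs, the
sample counting as in-trans if any pair confirms.

`resolve_phase()` is deliberately conservative: cis requires both
variants heterozygous in exactly one parent and absent from the other;
trans requires exactly one variant in each parent; anything else —
missing parent, missing genotype, a carrier parent homozygous, both
parents carrying both — is `unresolved`, never guessed, and a variant
absent from both parents is flagged possible de novo. A brute-force
haplotype-enumeration oracle over all nine two-het-parent
configurations confirms the rule decides exactly the decidable cases.
Two asymmetries are worth noting:

- configurations a full enumeration could resolve but the rule leaves
  unresolved (e.g. carrier parent homozygous at one site with the other
  parent a non-carrier) are kept unresolved by design — the cost of a
  false "possible" is small, a false cis exclusion is not;
- when a trio child's pair is confirmed cis, the identical unresolved
  pair in the transmitting parent is also marked cis
  (`classify_cohort()`): the child's double heterozygosity with a
  non-carrier other parent proves both alleles arrived on the one
  transmitted haplotype, so the parent's pair is in cis by the same
  evidence. Phase information flows both ways through a trio.

`count_biallelic()` excludes confirmed-cis pairs and reports unresolved
compound heterozygotes in a separate "possible" column — they remain in
the biallelic total, matching how a screen without cohort-wide phasing
must report them.

Joint ranking uses the minimum-rank convention (a score's rank is one
plus the number of strictly greater scores); display ties are broken by
sample identifier, which never affects the rank itself.

## Cohort deletion accounting

`summarize_cnv()` reports the headline allele frequency as
`allele_count / n_individuals`. The per-individual denominator is the
only arithmetic that reproduces the published carrier tables
($349/62{,}898 = 5.55\times10^{-3}$, $85/15{,}152 = 5.61\times10^{-3}$,
$39/21{,}694 = 1.80\times10^{-3}$); whether that denominator was chosen
deliberately is unknowable from the text, so the conventional
per-chromosome frequency is emitted alongside in a clearly labelled
column, and both are tested.

## Reverse phenotyping

Phenotype codes (HPO / ICD-10-like) map to disease classes through an
editable YAML table; the shipped default is a small illustrative set,
because the real clinical query set behind any given screen is not
published. "Phenotype-positive" for the SNV-share computation means
renal **or** retinal flag true. Ages at first record are taken as
supplied and overestimate onset when episode data begin at recruitment;
that caveat is documentation, not a model.

## Structural triage

The five damage criteria over precomputed wild-type/mutant residue
features: (1) buried charged residue replaced by an uncharged one;
(2) all wild-type side-chain H-bonds disrupted; (3) as (2) with the
burial requirement — the two printed criteria overlap, so both flags
are computed and reported separately; (4) cavity volume change
$\geq 70$ Å³, absolute (expansion or contraction) and inclusive at the
boundary; (5) a buried wild-type salt bridge (N–O distance $\leq 5.0$
Å) lost in the mutant. Burial is consumed as a boolean computed by the
upstream modelling tool at its own accessibility threshold, since no
numeric definition of "buried" is printed; the rule engine is a pure
function of the feature table. Features are never computed from 3-D
coordinates here — the reproducible content is the decision rule, and
the shipped feature table is synthetic, encoding the hallmark buried
Arg→Trp substitution (all five criteria, cavity contraction 90.504 Å³)
alongside tolerated controls.

## The synthetic cohort generator

`generate_cohort()` emulates the screened cohort at desk scale. Defaults
— chosen once as the study conditions, not tuned: 2,000 samples, 30
trios, the GRCh38 *NPHP1* interval (chr2:110,123,335–110,205,062), 56
background sites (30% common, $f \sim U(0.01, 0.5)$, CADD below the
eligibility cut; 70% rare, $f = 10^{U(-5, -2.4)}$, CADD $U(10, 35)$ —
the rare tail matches pathogenic SNVs all having $f \le 4\times10^{-3}$),
planted variant frequencies in $2\times10^{-4}$–$4\times10^{-3}$ with
CADD 18–28.9 for missense and 47 for the stop-gain, background
heterozygous deletion carriers at the published per-individual carrier
rate $424/78{,}050$, and the planted composition of
`default_planted()`: 26 true biallelic genotypes (10 homCNV + 8
phenotype-positive SNV-based + 8 phenotype-negative) plus two in-cis
decoy trios and five lone-heterozygous-deletion decoys, with 8 of the
18 phenotype-positive carriers marked as previously reported.

Mechanics that matter for interpreting test results:

- Generation is haplotype-based: founders draw alleles per site at the
  true frequency, trio children inherit one haplotype per parent (no
  recombination — reasonable within one gene), so Mendelian consistency
  holds everywhere by construction, planted sites included. No de novo
  variant is ever planted.
- File conventions mirror a real caller stack: homozygous deletions emit
  `./.` at every gene site; inside a heterozygous deletion the retained
  allele is emitted homozygous-appearing. Two sentinel sites are planted
  to fail the site-level QC filters (low mean GQ; 80% missingness), one
  site has a recorded frequency of zero (exercising the floor) and one
  is absent from the annotation table (exercising the unannotated
  drop).
- **Exact-truth repair.** After background sampling, the generator
  removes, at the haplotype level (preserving transmission), any
  accidental pattern that the classifier would call biallelic in an
  unplanted sample — two eligible heterozygotes, an eligible homozygote,
  or an eligible allele in a deletion carrier — and strips stray
  eligible alleles from planted samples, trio parents and deletion
  carriers. At 2,000 samples with tens of rare eligible sites, random
  collisions into "possible compound heterozygote" calls would
  otherwise occur in a handful of samples per cohort; the repair makes
  the truth table exhaustive, so recovery tests assert exact counts
  rather than approximate ones, for every seed.
- Quality fields: GQ $\sim N(72, 10)$ capped at 99 with a 2% low-GQ
  admixture, DP $\sim$ Pois(35) (halved inside heterozygous deletions);
  planted carrier genotypes are pinned to GQ 99 / DP 50 so a mechanism
  is never lost to simulated noise.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: linkage disequilibrium and recombination,
population structure and relatedness beyond the planted families, the
segmental-duplication mechanism of the recurrent deletion, caller
artefacts correlated across sites or samples, and realistic phenotype
code richness. The generator validates the *logic* of the pipeline
(filters, score arithmetic, phase rules, set accounting), not its
performance characteristics on real cohort noise.

## Problem sizes and runtime

Unit tests run on cohorts of 100–300 samples with ~30 sites; the
end-to-end recovery check and the acceptance script use the full default
2,000-sample configuration, which generates, writes, parses, scores and
classifies in a few seconds. Score arithmetic is checked against a
brute-force per-locus oracle at $10^{-9}$ relative tolerance on fixtures
of up to 20 loci; ranks against a count-strictly-greater oracle; phase
against exhaustive haplotype enumeration.

## Known limitations

- Phase resolution uses parents only; offspring-based phasing beyond
  the cis-propagation rule, duos, and statistical or read-backed
  phasing are out of scope.
- Scores for one configured gene at a time; no exome-wide batching.
- The annotation join is exact-key; no normalisation of indel
  representations.
- ACMG classification, splice prediction and conservation scoring are
  deliberately outside the package: annotations are consumed as tables.
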