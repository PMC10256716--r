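# genepyscreen

Genotype-first screening of a recessive disease gene across a sequenced
cohort, built around the *NPHP1* locus (nephronophthisis, Senior–Løken and
Joubert syndromes). Most *NPHP1*-related disease is attributed to a
recurrent whole-gene deletion at 2q13; single-nucleotide variants and small
indels are harder to ascertain because short-read cohorts are unphased and
deletion carriers hide hemizygous variants. This package implements the
full genotype-to-phenotype workflow for users who want to screen a cohort
VCF plus a CNV call table for biallelic recessive genotypes without
starting from cases:

- **GenePy gene pathogenicity scores.** For individual *h* and gene *g*,

  S_gh = − Σ_i D_i · log10(f_i1 · f_i2)

  summed over biallelic variant loci *i*, where D_i is the CADD PHRED
  deleteriousness and f_i1, f_i2 are the population frequencies of the two
  observed alleles (zygosity-aware: het → f(1−f), hom-alt → f²). Rare,
  deleterious genotypes give large scores.
- **CNV integration.** A whole-gene deletion enters the score as one extra
  biallelic locus with D equal to the maximal stop-gain CADD in the gene's
  annotation set and allele frequency f = 1.798 × 10⁻³ (population SV
  reference); homozygous deletions contribute −D·log10(f²).
- **Quality control** exactly as a cohort screen applies it: genotypes kept
  iff GQ > 20 and DP > 10, sites kept iff mean GQ > 35 and missingness
  ≤ 70%, scoring restricted to CADD PHRED > 15.
- **Joint ranking and biallelic classification**: tied scores share the
  minimum rank; homozygous deletions, homozygous SNVs, deletion+SNV
  compound heterozygotes (in-trans forced by hemizygosity) and SNV–SNV
  compound heterozygote candidates phased against parental genomes, with
  confirmed in-cis pairs excluded and unresolved pairs retained as
  "possible".
- **Cohort CNV accounting** (het/hom carrier counts, allele counts, allele
  frequencies under both the per-individual and per-chromosome
  conventions), **reverse phenotyping** against HPO/ICD-10-style code
  tables, and a **five-criterion structural-damage rule engine** over
  precomputed wild-type/mutant residue features.
- **A synthetic cohort generator** that plants every genotype class
  (including in-cis decoys and single-heterozygote decoys) with an exact
  truth table, so the whole pipeline is testable without access-controlled
  data.

## Worked example

The `analysis/` directory holds the numbered workflow. Stage 1 simulates
the default cohort (2,000 samples, 30 trios) into `results/cohort/`;
stages 2–6 score, classify, summarise, reverse-phenotype and triage:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_score_gene.R
Rscript analysis/03_classify_biallelic.R
Rscript analysis/04_cnv_cohort_summary.R
Rscript analysis/05_reverse_phenotype.R
Rscript analysis/06_structural_triage.R
```

Stage 3 prints, for the default seed:

```
biallelic recessive genotypes: 26  (excluded in-cis pairs: 4)

       mechanism confirmed possible
          homCNV        10        0
          homSNV         4        0
 compHet_SNV_SNV         1        7
 compHet_CNV_SNV         4        0

sensitivity to planted biallelic genotypes: 26/26
decoys wrongly called: 0
```

Twenty-six individuals carry a biallelic recessive genotype: ten
homozygous whole-gene deletions, four homozygous SNVs (two of them the
stop-gain sibling pair), four deletion+SNV compound heterozygotes, one
trio-confirmed in-trans pair and seven possible (unresolved) pairs. The
four excluded in-cis calls are the two planted decoy trio children plus
their transmitting fathers, whose pair the classifier phases as cis from
the same trio evidence. Stage 5 then reports the reverse-phenotyping
headline: 18 of the 26 have a renal or retinal phenotype, of which 8
(44%) involve an SNV — the screen's case for historical under-reporting
of SNV-driven disease. Stage 4 reproduces the published carrier
arithmetic from printed counts: allele counts 349, 85 and 39; allele
frequencies 5.55 × 10⁻³, 5.61 × 10⁻³ and 1.80 × 10⁻³; pooled carrier
percentage 0.54%. Stage 6 flags the buried Arg→Trp substitution on all
five structural criteria (cavity contraction 90.504 Å³).

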