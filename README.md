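# casevar

Case-exclusive variant discovery for Mendelian traits in small cohorts.

## The problem

When a rare, presumably monogenic phenotype appears in a handful of related
animals, the standard discovery design is to sequence the genomes of a few
cases and filter their variants against a large panel of control genomes:
keep only variants that every case carries under the assumed inheritance
model — heterozygous for a dominant trait, homozygous-alternate for a
recessive one — and that no control carries at all. The handful of
surviving protein-changing variants are then prioritized by gene function,
checked for segregation in the family, for cross-species conservation of
the affected residue, and for genotype–phenotype association in a larger
genotyping cohort.

`casevar` implements that whole analysis as tested, reusable R functions:

- **`case_exclusive_variants()` / `summarize_filter()`** — the core filter.
  For a variant *v* with per-sample alternate-allele counts *g(s)*, the
  dominant-heterozygous model keeps *v* iff *g(s) = 1* for every case *s*
  and *g(s) = 0* for every control; the recessive model requires
  *g(s) = 2* in cases. Missing control calls are treated as non-carriage
  by default (`missing_control = "ref"`) or discard the variant in strict
  mode (`"drop"`); a missing case call always fails the sharing
  requirement.
- **`annotate_snv()`** — transcript-aware SNV consequence annotation:
  CDS coordinate mapping on both strands across exon boundaries, codon
  substitution, effect classes (synonymous / missense / nonsense /
  start-loss / stop-loss / intronic / intergenic) and HGVS-style names on
  the cDNA (`c.1658G>A`) and protein (`p.(Arg553Gln)`) levels.
- **`column_conservation()`** — binary identity conservation of the
  affected residue's column in a protein multiple alignment.
- **`check_dominant_segregation()` / `association_table()`** —
  full-penetrance dominant compatibility checks on a pedigree and the
  genotype × phenotype count table with a perfect-association predicate.
- **`rank_candidates()`** — an explicit linear prioritization score
  (severity + conservation + optional gene-knowledge prior).
- **`simulate_fixture()`** — a deterministic synthetic-cohort generator
  that emits a complete desk-scale study (reference FASTA, GFF3 gene
  models, multi-sample VCF, sample sheet, pedigree, protein alignment,
  truth table) so the entire pipeline can be exercised end to end.
- **`run_discovery()`** — one-call orchestration writing the report
  tables; a thin command-line wrapper ships in
  `inst/cli/casevar.R` (verbs `simulate`, `filter`, `annotate`,
  `conserve`, `segregate`, `discover`).

## Worked example

Simulate the default discovery cohort — 2 heterozygous cases against 20
controls, with 1030 heterozygous and 36 homozygous case-exclusive variants
planted (10 and 0 protein-changing, respectively), plus control-carried
background variants and private singletons — and run the filter and
annotator over it:

```r
library(casevar)

spec <- cohort_sim_spec(seed = 1)
fx   <- simulate_fixture(spec, "fixture")

sheet <- read_sample_sheet(fx$paths$sample_sheet)
gm    <- read_vcf(fx$paths$vcf, sheet)$matrix
tms   <- read_transcripts_gff3(fx$paths$gff3)
eff   <- annotate_matrix(gm, tms, fx$reference)
summarize_filter(gm, sheet, eff$effect_class)
#> Filtering step                         Het     Hom
#> Case-exclusive variants               1030      36
#> Case-exclusive protein-changing         10       0
#> Total case-exclusive: 1066
```

The filter recovers exactly the planted counts: 1066 variants exclusively
shared by the two cases, of which 10 heterozygous and no homozygous ones
change the protein. The planted causal variant annotates as the expected
missense change in the 600-codon `PCK2`-like gene:

```r
cz <- fx$causal
annotate_snv_multi(tms, fx$reference, cz$contig, cz$pos, cz$ref, cz$alt)
#> PCK2 c.1658G>A p.(Arg553Gln) missense [tx-PCK2, codon CGA>CAA]
```

i.e. the G>A substitution at coding position 1658 turns the strictly
conserved arginine 553 (codon `CGA`) into glutamine (`CAA`). The bundled
protein alignment scores that residue as fully conserved, and a validation
cohort of 4 heterozygous cases vs 632 homozygous-reference controls shows
a perfect genotype–phenotype association:

```r
res <- column_conservation(read_alignment(fx$paths$alignment), "dog", 553)
#> conservation: column 553, fraction_identical 1.00, strictly_conserved TRUE

cohort <- simulate_genotyping_cohort(4, 117, 515)
tab <- association_table(cohort$genotypes, cohort$sheet)
tab
#>         case control
#> hom_ref    0     632
#> het        4       0
#> hom_alt    0       0
is_perfectly_associated(tab)
#> [1] TRUE
```

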