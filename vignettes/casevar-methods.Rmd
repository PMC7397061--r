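---
title: "Methods: case-exclusive variant discovery with casevar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-exclusive variant discovery with casevar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The discovery model

`casevar` addresses the classic design for a rare, presumably monogenic
trait segregating in a small family: whole-genome sequence a few cases,
call variants against the reference assembly, and intersect them with a
large panel of control genomes. The genetic model is explicit and strict:

* **Dominant-heterozygous model** — the causal variant is carried in one
  copy by every affected, sequenced individual and by no control.
* **Recessive-homozygous model** — every case is homozygous for the
  alternate allele; no control carries it at all.

For a biallelic variant with per-sample alternate-allele counts
$g(s)\in\{0,1,2\}$, the filter keeps the variant iff $g(s)=k$ for every
case (with $k=1$ or $k=2$ by model) and $g(s)=0$ for every control. No
allele-frequency, genotype-quality or population-model thresholds are
applied: the filter is pure presence/absence, which is what makes its
result exactly recoverable on planted fixtures. The underlying assumptions
— full penetrance, a single shared causal allele, and the completeness of
the control panel — are assumptions of the *design*, not adjustable knobs;
when they fail (phenocopies, reduced penetrance, a carrier control) the
causal variant is silently lost, which is why the package also reports the
policies in force in every run log.

Both model sets are disjoint by construction (a case genotype cannot be
both het and hom-alt), so the headline "case-exclusive total" is their
sum.

## Missing genotypes

Control panels assembled from many sequencing projects routinely contain
missing calls, and what "not present in the controls" means for them is a
genuine policy choice. Both defensible readings are implemented:

* `missing_control = "ref"` (default): a missing control call is treated
  as non-carriage; the variant may survive. Rationale: absence of a call
  is not evidence of carriage, and the alternative silently conditions
  the result on panel call rate.
* `missing_control = "drop"`: any missing control call discards the
  variant — the conservative reading in which exclusivity must be
  *observed* in every control.

A missing call in a **case** always fails the sharing requirement under
either policy: sharing must be observed, never imputed.

# Variant representation

All set operations identify a variant by its normalized
`(contig, pos, ref, alt)` tuple. `normalize_variant()` applies the
standard left-alignment procedure (trim shared trailing bases, extending
left from the reference when an allele would empty; then trim shared
leading bases keeping one anchor base), which makes comparisons
representation-independent and is idempotent. For an indel inside a
homopolymer this yields the leftmost representation anchored on the base
*before* the run — the same convention as the widely used normalization
tools — and the test suite checks it against a brute-force
smallest-representation search. Multiallelic records are split into
per-ALT biallelic records whose calls count only that allele; haploid or
higher-ploidy genotypes are rejected because the target analysis is
autosomal diploid. Coordinates are 1-based inclusive throughout,
including the 6-column transcript TSV reader (its layout is BED-like but
its coordinates are not 0-based half-open; the GFF3 path is the primary
interface).

# Consequence annotation

The annotator is deliberately SNV-only: the discovery analysis it serves
prioritizes substitutions, and indel/frameshift consequence calling adds
large complexity (transcript-level realignment, 3'-rule shifting) without
being exercised by the package's fixtures. Indels pass through the filter
but receive no coding-effect class; the limitation is intentional and
documented. Splice-region effects are likewise not modeled — a variant
between CDS intervals reports `intronic` regardless of distance to the
junction — and UTRs are not represented in the transcript model, so
"non-coding inside the transcript span" and `intronic` coincide.

Annotation assembles the affected codon from the CDS geometry (codons may
span exon boundaries), complements alleles on minus-strand transcripts,
substitutes, and classifies by the amino-acid pair: synonymous, missense,
nonsense (gain of stop), stop-loss, and start-loss (residue 1 methionine
lost). "Protein-changing" is defined as
{missense, nonsense, stop-loss, start-loss}; this class set is a package
decision — the upstream annotation tools it replaces expose impact
*categories*, not this exact set. HGVS-style names are emitted at both
levels, `c.<pos><REF>><ALT>` in CDS-strand alleles and `p.(Xxx<n>Yyy)`;
the parenthesized predicted form is the default and a flag yields the
bare spelling, since both circulate in the literature. With multiple
overlapping transcripts the most severe class is reported. Only the
standard genetic code is supported.

Correctness is established against an independent oracle: translating the
entire reference and mutant CDS and diffing the protein sequences, over
hundreds of random transcripts on both strands, plus a strand-mirror
symmetry property (annotating a variant and its reverse-complemented
mirror fixture yields identical results).

# Conservation

`column_conservation()` scores binary identity of the alignment column
holding a reference residue: the fraction of non-gap rows matching the
reference residue, with the reference row included in the denominator and
gap rows excluded from it. No substitution-matrix similarity or
phylogenetic weighting is used: the claim the score supports is *strict*
conservation, and binary identity keeps it interpretable. The
residue-to-column mapping counts non-gap characters and errors beyond the
ungapped length.

# Segregation and association

`check_dominant_segregation()` checks a genotyped (possibly partially
genotyped) pedigree against a fully penetrant dominant model: affected
individuals must carry the allele, unaffected individuals must not, and
each genotype must be Mendelian-achievable given the genotyped parents
(an ungenotyped parent can transmit either allele). Unknown-phenotype
individuals never trigger phenotype violations, and
`allow_nonpenetrant = TRUE` downgrades unaffected-carrier violations to
warnings for pedigrees where penetrance is uncertain. The checker is
validated against an exhaustive rule table over all trio genotype ×
phenotype combinations.

`association_table()` tabulates genotype class against case/control
status; `is_perfectly_associated()` is true iff every case carries the
allele and no control does. A two-sided Fisher exact test on the carrier
× phenotype collapse is available for reporting, but no p-value
participates in any acceptance decision — with four cases the design is
descriptive, not inferential.

# The synthetic cohort generator

`simulate_fixture()` produces a complete desk-scale study as a
deterministic function of its spec (identical bytes per spec, verified by
hashing): reference FASTA, multi-exon gene models as GFF3, multi-sample
VCF, sample sheet, pedigree, protein alignment, and a truth table.

Default study conditions (chosen once, to mirror the discovery setting
the package re-implements):

* 2 cases vs 20 controls. The filter's semantics are control-count
  independent — a planted case-exclusive variant survives any number of
  clean controls — so a 20-genome panel stands in for a much larger one
  at seconds of runtime.
* Planted counts 1030 heterozygous and 36 homozygous case-exclusive
  variants, of which 10 and 0 are protein-changing; the zero
  protein-changing homozygous category is realized by planting homozygous
  variants only at intergenic, intronic or synonymous sites.
* 400 background variants carried by at least one control and 10 private
  singletons per sample. These counts are not part of the emulated
  design's published summary; they are desk-scale-realistic decoys whose
  only role is to give the filter something to reject on every path
  (control carriage, failed sharing), and they are guaranteed not to
  collide with planted loci.
* 2 contigs × 500 kb of i.i.d. uniform background sequence, 10 genes per
  contig (2–4 exons, introns 100–300 bp), at least one minus-strand gene
  per contig, and one designated 600-codon causal gene hosting an
  arginine `CGA` codon at residue 553 whose middle base is substituted
  G>A — so the causal variant annotates as the missense Arg553Gln at
  c.1658 by construction.

Generated genes carry a start and a stop codon but their interiors are
random sequence: in-frame internal stop codons occur and no codon-usage,
GC-content, LD or demographic realism is claimed. Consequently, passing
tests demonstrate the *logic* of the pipeline — exact count recovery,
correct coordinate arithmetic and classification — not robustness to the
messiness of real genomes (alignment artifacts, low-complexity regions,
genotyping error), which no desk-scale simulation can establish.

The generator refuses impossible geometry (contigs too short for the
requested genes) and requires at least two cases, since with a single
case its private singletons would be indistinguishable from
"case-exclusive shared" variants and exact parameter recovery could not
hold.

`simulate_msa()` builds the protein alignment from the causal gene's own
translated CDS: non-reference rows receive random substitutions at 10%
per column and occasional 4-residue gap runs, never touching the target
column, which is kept identical in all rows (or mutated in a stated
number of rows when a non-conserved fixture is requested).

# Prioritization

The final choice among a handful of protein-changing candidates in a real
study is expert biological judgment. `rank_candidates()` deliberately
does not pretend otherwise: it exposes an explicit linear score —
`severity * rank + conservation * fraction + prior * in_gene_list` with
fixed severity ranks (nonsense/start-loss/stop-loss 3, missense 2, else
0) — and ships with the gene-list prior **off**. Under severity-only
weights a stop-gain outranks every missense candidate; a
metabolism-knowledge candidate reaches the top only when a gene-list
prior is switched on, and the documentation says so rather than
laundering judgment as computation. Ties break lexicographically by
(gene, contig, pos) on a stable sort, so ranking is invariant under input
order.

# Orchestration and interfaces

`run_discovery()` composes the tested stages and writes the filter
summary, ranked candidate table, association table, segregation verdict,
conservation result and a log of every policy in force; stage failures
propagate with the stage name and leave no partial summary. The
command-line wrapper (`inst/cli/casevar.R`) is a thin argument parser
over these functions with exit codes 0/1/2 (ok / usage / data error);
its `filter` and `annotate` verbs run the discovery orchestration, whose
reports include those stages' outputs.

# Problem sizes and determinism in the test suite

The suite exercises: full-scale fixtures (1066 planted case-exclusive
variants, 22 samples, ~1700 records) once; reduced fixtures (52 planted,
8 samples) for multi-seed parameter-recovery and determinism checks over
five seeds; 200+ random SNVs against the translate-and-diff oracle on
both strands; exhaustive trio rule tables; and brute-force normalization
searches. These sizes were chosen so the whole suite completes in about a
minute while every oracle comparison remains exhaustive at its scale. All
randomized tests run under fixed seeds; the generator's byte-determinism
is itself a tested contract.

# Known limitations

* SNV-only consequence annotation; no splice, UTR or regulatory classes.
* No structural variants (and none larger than ~25 bp contemplated), no
  genotype likelihoods, no BCF/CRAM.
* Hemizygosity is unmodeled: sex-chromosome records are processed like
  autosomes.
* The dominant check assumes full penetrance unless explicitly relaxed;
  X-linked and compound-het models are out of scope.
* Synthetic cohorts validate logic, not robustness to real-data noise.
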