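---
title: "Comparing a gene subfamily across two lineages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing a gene subfamily across two lineages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagediv)
```

## The problem

Plant enzyme families such as the aldehyde dehydrogenases often carry
several closely related isoforms per genome, and the same subfamily can
look quite different in monocots and dicots. When isoforms from the two
lineages are pooled into one alignment, three questions recur:

1. **Membership** — which sequences belong to the same family or
   subfamily under percent-identity nomenclature rules?
2. **Selection** — is the subfamily evolving under purifying selection,
   and how much nucleotide divergence separates the lineages?
3. **Lineage-diagnostic sites** — which alignment columns are fixed for
   different amino acids in the two lineages (for example an active-site
   phenylalanine/tyrosine dimorphism), and which merely overlap?

`lineagediv` implements this workflow end to end on user-supplied
sequences: it never aligns (a pre-computed protein alignment is taken
as-is) and never fetches data.

## Family and subfamily clustering

Nomenclature-committee rules are pairwise: proteins with more than 40%
amino-acid identity share a family, more than 60% a subfamily. A pairwise
rule does not by itself define a partition, so `assign_families()` uses
single-linkage clustering — connected components of the graph whose edges
join pairs above the threshold. This is the weakest consistent reading of
the rule: any other clustering (complete linkage, say) would split groups
the pairwise criterion joins. Because subfamily edges are a subset of
family edges, the subfamily partition provably refines the family
partition. "More than 40%" is read as a strict inequality.

Identity comes from a deterministic global Needleman–Wunsch alignment
(BLOSUM62, gap open 10, gap extend 0.5 — the classical defaults, all
configurable) rather than from a local-alignment search, whose identity
values depend on the search tool and version. The default denominator is
the aligned span excluding terminal-gap columns, so a short fragment is
not penalised for length; the shorter-sequence denominator is available
behind a flag. Ambiguous residues (`X`) count as mismatches, never as
matches. Curated nomenclatures built on local-alignment identities can
therefore differ near the thresholds; that deviation is inherent to
making the rule reproducible.

## Codon alignments and the partial-deletion filter

All codon statistics run on a codon alignment built by back-translation:
each row of the protein alignment is threaded with the codons of its CDS
(`back_translate()`), so a protein gap becomes `---` and every non-gap
codon translates to the residue above it — this invariant is checked and
violations are reported with the sequence id and residue number.

`partial_deletion()` mirrors the common "partial deletion, 95% site
coverage" option of alignment software: columns whose non-gap fraction is
below the coverage cut-off are dropped. Codon columns are atomic (a codon
containing any gap character is a gap), ambiguous characters count as
coverage, the filter is idempotent at a fixed threshold, monotone in the
threshold, and the surviving original column indices are retained so every
report stays in the 1-based coordinates of the input alignment.

## Site classification

A column is **parsimony-informative** when at least two states each occur
in at least two sequences; gaps and ambiguity codes are never states. The
default universe for lineage-site reporting is the informative columns of
the protein alignment, matching how such tables are usually compiled;
`sites = "all"` overrides this.

At each column the residue sets of the two lineages are compared.
Disjoint sets split into three cases — both lineages fixed
(`strictly_dimorphic`), one fixed and one variable (`fixed_in_A_variable_in_B`),
both variable (`disjoint`) — while any shared residue makes the column
`overlapping`. The overlap rule is deliberately the weakest one (any
non-empty intersection); a column variable in both lineages with one
shared residue is thus "overlapping", not "disjoint". Residue sets are
printed by descending frequency with alphabetical tie-breaks, a fixed
deterministic order. A lineage that is entirely gapped at a column cannot
be classified and is reported `non_informative` with a warning.
`column_to_residue_number()` converts a shared alignment column into each
isoform's own residue numbering (the "Y465 in one isoform, F464 in
another" style of report).

## Composition, codon usage, and the t test

Nucleotide composition is computed per sequence at codon positions 1, 2
and 3 over the filtered site universe (informative nucleotide columns by
default), as percentages that sum to 100 within each position — gaps are
excluded from numerator and denominator alike. Amino-acid composition
works the same way over the 20 residues. Group contrasts use the pooled
two-sample Student's t test (Welch's version behind a flag); spread is
reported as the standard error per the "mean ± SE" convention, with the
SD also emitted because printed tables are often ambiguous about which is
shown. Zero-variance cells are handled explicitly: equal means give
t = 0, p = 1; unequal means are flagged degenerate with p = 0.

RSCU is a codon's count divided by the mean count of its synonymous
family; values average 1 within each family, stop codons and one-codon
families (Met, Trp) are excluded, and a family absent from the data
yields flagged `NA`s rather than 0/0.

## Selection statistics

**Divergence.** Pairwise nucleotide distances use pairwise deletion and
default to the p-distance (the model behind published divergence tables
is often unstated; Jukes–Cantor is available and every report names the
model used). Within- and between-lineage means are averaged over all
intra- and inter-group pairs, with standard errors from a seeded
bootstrap over nucleotide sites (1000 replicates by default).

**Nei–Gojobori counting.** Synonymous site fractions exclude single-base
changes that create stop codons, so S + N = 3 × (compared codons)
exactly; S is averaged over the two sequences of a pair. Codons differing
at several positions average their synonymous/nonsynonymous difference
counts over all minimal mutational pathways, excluding pathways through
stop codons (with a fall-back to all pathways in the degenerate case
where every pathway is blocked). Columns containing a gap or stop in
either sequence of a pair are excluded for that pair only. The
Jukes–Cantor correction is undefined at p ≥ 0.75 and such values are
flagged, never silently truncated.

**Z-test.** The codon-based Z-test compares mean dS and mean dN over
sequence pairs, with variances estimated by a seeded bootstrap over codon
sites (1000 replicates by default, configurable; at least 100):
Z = (mean dS − mean dN)/√(Var dS + Var dN), with one-tailed normal
p-values for the purifying (dS > dN) and positive (dN > dS) alternatives.
An invariant alignment is flagged and returns p = 1.

**Per-site dN/dS** averages the pair counts within each codon column and
categorises the ratio (Nd/N)/(Sd/S). A column with differences but no
synonymous ones has an infinite ratio and is counted `gt1`; a column with
no differences is `undefined`; a ratio of exactly 1 gets its own `eq1`
bucket so the category counts always sum to the number of columns. This
is a counting approximation — tree-aware per-site engines will differ in
detail, so per-site splits reproduce published counts only approximately.

**Tajima's D** uses the standard coefficients (a1, a2, b1, b2, c1, c2,
e1, e2) with complete deletion by default — every column containing a gap
or ambiguity is dropped before counting segregating sites and mean
pairwise differences — matching the usual default for this statistic.
θ (Watterson) and π are reported per site. The sign of D always equals
the sign of π − θ. Pairwise deletion is offered but approximate, since
the site universe then differs between pairs.

## The simulator and what it does (not) show

`simulate_lineages()` provides ground truth for every stage without any
download. A shared ancestral CDS is drawn codon-wise with the
third-position base biased toward the midpoint of the two lineage GC3
targets; two lineage ancestors evolve from it along a split branch, and
each tip evolves independently from its lineage ancestor — a star
phylogeny within each lineage, which creates within-group variation and
between-group divergence without tree machinery. Substitutions follow a
continuous-time codon model: each synonymous single-base change has rate
1 (third-position choices re-weighted toward the lineage GC3 target),
each nonsynonymous change rate ω, stop codons rate 0. Events are drawn
Gillespie-style — codons are hit proportionally to their total
substitution rate — which is what makes the third-position stationary
frequencies actually match the GC3 target; with uniform event timing the
realized GC3 measurably undershoots it. Under this model the
Nei–Gojobori estimator recovers ω, which the tests verify (ω = 0.2
recovered within ±0.1 over 20 replicates of 300 codons).

Branch depths are expected substitutions per codon. The defaults —
8 + 15 sequences of 423 codons, ω = 0.1, GC3 targets 0.41/0.87, depths
1.1/0.9 within and 1.7 to the split, one strictly dimorphic and three
fixed/variable injected sites — were chosen once so that the synthetic
data reproduce the broad structure of a published dicot/monocot enzyme
subfamily comparison: within-lineage nucleotide divergence near 0.3,
between-lineage near 0.5, strongly positive Tajima's D (the deep
two-clade split creates intermediate-frequency variants), an
overwhelmingly `lt1` per-site dN/dS spectrum, and a GC3 contrast between
the lineages.

The GC3 convergence check runs at depth 2.5 within lineages: the
ancestor starts at the GC3 midpoint by construction, so each
third-position site needs several substitutions before its distribution
approaches the lineage's stationary bias; at shallow depths the realized
GC3 necessarily lags its target. Residual offsets from one-codon families
(Met, Trp are always GC-ending) and the isoleucine family remain below
the ±0.05 tolerance used in the tests.

What passing these tests does **not** show: the simulator has no indels
(gap handling is exercised on hand-built fixtures instead), no rate
heterogeneity among sites beyond the injected columns, no codon-model
likelihood structure (GY94-style frequency parameterisation), and star
phylogenies instead of realistic trees. Results on real data additionally
depend on the upstream aligner, which is outside this package's scope.

## Numerical and interface conventions

* All alignment columns are reported 1-based in the coordinates of the
  input alignment, also after filtering.
* All randomised procedures (bootstraps, simulation) take explicit seeds
  and record them; identical seeds give byte-identical pipeline bundles.
* Degenerate inputs are flagged, not silently patched: JC at p ≥ 0.75,
  invariant alignments in the Z-test, zero-variance t cells, S = 0 in
  Tajima's D, empty synonymous families in RSCU.
* `run_pipeline()` orchestrates the stages, writes TSV/JSON reports plus
  a manifest of every parameter, removes partial output on failure, and
  names the failing stage in its error. When an alignment has no
  parsimony-informative column the composition tables fall back to all
  sites rather than failing the run.
* Problem sizes in the test-suite simulations (300–500 codons, 3–6
  sequences per lineage, 10–200 replicates) are the smallest at which the
  checked properties are statistically stable; the defaults users see are
  the full study-sized conditions described above.
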