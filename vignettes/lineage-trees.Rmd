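---
title: "Reconstructing somatic cell lineage trees from multi-sample VAF matrices"
author: "snvphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing somatic cell lineage trees from multi-sample VAF matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvphylo)
```

## The inference problem

All cells of an individual are related by a bifurcating lineage tree whose
root is the zygote. A somatic single-nucleotide variant (SNV) that arises in
an ancestral cell is inherited by all of that cell's descendants, so when
many tissue samples from one patient are sequenced deeply at a panel of
somatic SNV positions, each variant's presence/absence vector across the
samples — its *phylogenetic pattern* — identifies the branch on which it
arose. A set of patterns is representable as clades of a single rooted tree
exactly when it is a *laminar family*: any two patterns are nested, disjoint
or equal. Patterns that *conflict* (overlap without nesting) signal either
noise or a genuinely mixed-lineage sample, a lesion containing cells from
two independent ancestral lineages.

`snvphylo` implements this inference as a pipeline of composable stages:

1. **Assay QC** (`flag_pcr_failures`, `vaf_from_counts`): assays with fewer
   than 1,000 reads in total across a patient's samples are PCR failures and
   are excluded outright. The variant allele frequency (VAF) of an ordinary
   site is alt / (ref + alt); at declared hotspot sites all four nucleotides
   are tabulated so co-occurring changes at one position are quantified
   independently. A cell with zero informative reads is *missing*, never 0.
2. **Presence calling** (`call_presence`): a cell is positive when its VAF is
   at least the cutoff (default 0.02, inclusive). Curated overrides may
   reverse individual calls; a record that agrees with the threshold call is
   rejected as redundant, and every override is logged in the provenance
   matrix.
3. **Categorization** (`categorize_assays`): assays present in every sample
   are germline, assays present in none are false positives of the original
   discovery, and the remainder are somatic. Only somatic assays continue.
4. **Phylogenetic classes** (`group_classes`, `assess_robustness`): somatic
   SNVs are partitioned by *exact* pattern identity. A class is *robust* when
   it has at least two members whose VAFs agree across samples; single-SNV
   classes are admitted only under a strict exception (below); everything
   else is *ambiguous* and excluded from treebuilding. Hotspot assays are
   routed to the recurrence stage and never influence the tree.
5. **Treebuilding** (`resolve_mixed_lineages`, `build_tree`): conflicts are
   resolved by duplicating samples into two leaf components placed
   independently; the resulting laminar family's containment hierarchy *is*
   the tree. Multifurcations are retained, never arbitrarily resolved, and
   samples carrying no assayed somatic SNV attach at the root.
6. **Mixture validation** (`vaf_sum_check`): for a genuine two-lineage
   sample, the lineage-specific VAF means must sum to the ancestral mean;
   the ratio of each component's mean to the ancestral mean estimates its
   mixing proportion.
7. **Recurrence** (`min_origins`): on the fixed tree, the minimum number of
   independent origins of a recurrent mutation is the number of maximal
   *pure* nodes (nodes whose entire descendant set is positive). The count
   is a parsimony minimum — "at least N" — and a flag marks positives
   attached at multifurcations, where unresolved branching order may hide
   additional events.

## Resolving mixed-lineage samples

The key structural fact the resolver exploits: a conflicting pair of
patterns can never become nested by splitting a sample, because each side
keeps private members. The only way to resolve a conflict is to make the
pair disjoint, which requires splitting *every* sample in its overlap and
placing the two patterns on opposite components throughout. Consequently the
minimum set of samples to split is exactly the union of all
conflicting-pair overlaps — there is nothing to search over split sets.

What remains is the assignment of classes to components. Classes that
conflict with another class at a split sample must take opposite single
components there (a 2-coloring of their conflict graph; a non-bipartite
graph means more than two lineages would be required, which is reported as
an error rather than resolved silently). Classes containing a split sample
but unconflicted there default to covering both components — they are
ancestral to the split — but nesting can force them onto a single side; a
deterministic backtracking search with laminarity pruning finds the
assignment, preferring the ancestral interpretation wherever it is
consistent. Component labels are pinned canonically (the conflicted class
with the smallest pattern key takes component `.1`) so identical inputs
always give byte-identical output.

Private SNVs of a split sample are a special case: both components project
onto the same singleton pattern, so their class cannot be attributed to one
component by pattern at all. The package keeps them as a *joint private*
pool annotated on the rejoined sample, excluded from the laminarity
universe and from the component means of the VAF-sum check. This is the one
place a robust class does not map to a single branch; assigning the pool
arbitrarily to one component would bias both the branch counts and the
mixing-proportion estimates.

This resolver was validated against an independent brute-force search — all
split sets, all per-pattern component assignments — on *every* set of at
most six distinct patterns over at most five samples (942,648 instances,
enumerated as 10,848 representatives of the sample-relabeling orbits), for
feasibility, minimum split count and topology uniqueness; and the origin
counter against an exhaustive minimum disjoint-clade cover on 200 random
trees of up to ten leaves. Both comparisons live in the test suite.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `min_total_reads` | 1000 | PCR-failure threshold on an assay's read total (strict less-than, taken literally from the assay design's quantification floor). Interpreted per assay summed over the patient's samples. |
| `vaf_cutoff` | 0.02 | Presence cutoff, inclusive. An order of magnitude above the sequencing-error background (below 1 in 1,000), and half the lowest VAF a clonal heterozygous variant can show under the contamination levels considered. |
| `consistency_tolerance` | 0.15 | Maximum within-class, per-sample VAF spread (max pairwise difference among members) for a multi-SNV class to be robust. Wide enough for binomial noise and modest copy-number distortion; narrow enough to separate full-VAF from half-VAF (mixed-lineage) levels at typical depths. |
| `clearly_positive_threshold` | 0.05 | Minimum positive VAF for the single-SNV exception: 2.5 times the cutoff, far above background. The exception additionally requires that including the class does not increase the number of split samples. |
| `vaf_sum_tolerance` | 0.10 | Allowed discrepancy between the ancestral mean VAF and the sum of the two component means of a split sample. |
| `max_splits` | 6 | Guard on the number of split samples; real patients show conflicts at only a handful of lesions, so a larger demand indicates corrupt input. |
| attribution `margin` | 0.01 | Two candidate hotspot-VAF levels closer than this are treated as indistinguishable (about twice the binomial standard error at depth 10^4) and disambiguated by parsimony on the fixed tree. |

All thresholds are recorded in the run report, so an analysis is fully
reproducible from its inputs and report alone.

## The simulator and what it does (not) emulate

`simulate_patient()` generates ground-truthed allele-count tables that mimic
the statistical structure of multi-sample targeted deep resequencing of
breast-neoplasia cases: 11 samples per patient (one normal control, two
contralateral and eight ipsilateral lesions spanning CCL/AH/FEA/UDH through
DCIS and IDC), 181 informative SNVs distributed over the branches of a
random binary lineage tree with an early bilateral split, log-normal
per-cell depths with median 10,000, symmetric per-read error 5×10⁻⁴,
per-sample normal-cell contamination drawn around 50%, a 1-in-10
mixed-lineage rate among lesional samples with near-equal mixing
proportions (drawn on a 1% grid between 0.40 and 0.60), two independent
hotspot origins on disjoint clades, and three germline, nine
false-positive and one PCR-failure assay per patient. Every SNV is
heterozygous and fully clonal in its lineage, so the expected VAF is
0.5 × (1 − contamination) × (fraction of the sample's cells in the
carrying lineage). Reads are multinomial; the `"expected"` sampling mode
replaces the draw by deterministic expected counts at fixed depth, giving
the exact noise-free limit in which the VAF-sum identity holds to machine
precision.

Each branch carries at least two SNVs, with the remainder allocated
preferentially to leaf-proximal branches where tumor evolution concentrates
cell divisions; per-branch counts are a modeling choice, not a fit. Two
structural validity checks are applied to the generated truth, with
rejected configurations redrawn: the conflicts induced by mixed samples
must force exactly those samples to be split, and no two distinct branches
may project onto the same sample-level pattern (apart from the private
pools of one mixed sample). Without these the generated "truth" would be
unrecoverable *in principle* from presence patterns — not because of noise,
but because two different trees explain the same pattern matrix — and
recovery rates would measure the frequency of degenerate draws rather than
pipeline performance. Real data can of course contain such collisions;
there they surface as VAF-inconsistent (hence ambiguous) classes, which is
the correct conservative behavior, and resolving them would require
VAF-level modeling that pattern parsimony deliberately avoids.

The simulator does not model copy-number alterations (which perturb VAFs of
affected SNVs), FFPE damage, primer performance differences,
amplicon-correlated depth ("PCR jackpots"), subclonal structure within a
lesion beyond the two-lineage mixture, or more than two lineages per
sample. Passing recovery tests therefore demonstrates correctness of the
inference under the stated generative model, not robustness to those
artifacts.

## Numerical and procedural choices

- Classes are keyed by exact pattern identity; near-identical patterns are
  never merged. Disagreements are resolved by explicit overrides or remain
  separate classes.
- Population (n-denominator) standard deviations are reported for class
  VAFs, because classes are small; single-member classes report 0 by
  convention.
- Mixing proportions shown on the tree are the normalized VAF-ratio
  estimates; when a split sample has no ancestral class, the check is
  skipped and reported as such rather than guessed.
- Tie-breaks everywhere are deterministic (lexicographic identifiers,
  canonical component pinning, ancestral-first assignment order), so reruns
  are byte-identical.
- Degenerate inputs: an empty somatic set yields a star tree and a valid
  report; empty positive sets yield zero origins; a fully-missing VAF row is
  retained and flagged, never imputed.
- The single global random generator is seeded once per simulated patient;
  all validation problem sizes (10,848 canonical resolution instances, 200
  random trees, 100 default-condition patients, 25 noise-free patients, 20
  background patients) are the package's validation choices, chosen to give
  sub-percent resolution on the rates they estimate.

## Known limitations

- At most two lineages per sample are modeled; three mutually conflicting
  classes at one sample abort with an explicit error.
- The origin count is a parsimony minimum on the inferred tree. When a
  mixture is close to 50:50, the hotspot VAF cannot identify the carrying
  component, and the parsimony disambiguation can under-count origins that
  truth placed on the less parsimonious component — the price of the
  "at least N" semantics.
- Branch lengths are SNV counts, not time or cell divisions; no bootstrap or
  other support values are computed.
- Pattern-level parsimony cannot separate two branches with identical
  sample-level patterns; such classes fail the VAF-consistency check and are
  excluded as ambiguous rather than mis-placed.

## A worked example

```{r example}
sim <- simulate_patient(sim_config(seed = 42))
res <- run_patient(sim$counts, sim$sites, sim$samples)
res

# recovered structure versus the generative truth
score <- score_recovery(res, sim$truth)
unlist(score[c("topology_ok", "mixed_ok", "origins_ok")])

# the mixture validation and estimated proportions
res$vaf_sums[, c("sample_id", "mean_ancestral", "mean_1", "mean_2",
                 "delta", "pass", "prop_1", "prop_2")]

# independent origins of the hotspot mutation on the fixed tree
res$recurrences[[1]]
```
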