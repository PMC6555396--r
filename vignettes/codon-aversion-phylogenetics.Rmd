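---
title: "Recovering phylogenies from codon aversion motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering phylogenies from codon aversion motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camphy)
```

## The character state

Synonymous codon usage is biased: organisms, genes, and even regions
within a gene prefer some codons over their synonyms, driven by tRNA
supply, translational efficiency, and neutral processes such as
GC-biased gene conversion. An extreme of this bias is *codon aversion*
-- a codon that a gene never uses at all. camphy treats the **codon
aversion motif** of a gene, the set of codons absent from its coding
sequence, as a heritable character state and uses nothing else: no
alignment, no ortholog annotation, no model of sequence evolution.

For each species we collect the motifs of all its genes into a set of
unique motifs (occurrence counts are kept for the summary statistics
but ignored by the distance). A gene that uses all codons except AAA
and ATA has the motif `(AAA, ATA)`; four genes with motifs
`(AAA, ATA)`, `(AAA, ACG, CTC)`, `(AAA, ATA)`, `(CGC)` give the
species the unique-motif set `{(AAA,ATA), (AAA,ACG,CTC), (CGC)}`.

Two conventions matter and are worth stating precisely:

* **The codon universe is all 64 codons, stop codons included.** A gene
  that never terminates with TGA genuinely averts TGA. Since a typical
  gene uses the start codon and exactly one of the three stops, 61
  codons are free to vary, giving a motif space of $2^{61}$ (versus
  $2^{20}$ for amino-acid motifs — one reason codon motifs resolve
  relationships more finely than amino-acid motifs).
* **Codons containing ambiguity characters (N, R, Y, ...) mark no codon
  as used.** An `NNN` is evidence for no specific codon; treating it as
  usage of anything would fabricate signal. Trailing incomplete codons
  are dropped with a warning rather than rejected, because partial gene
  annotations are legitimate input.

The empty motif (a gene using all 64 codons) is a valid motif and
enters the species set like any other; the distance's set semantics
handle it without special cases.

## The distance

For species $A$ and $B$ with unique-motif sets $a$ and $b$,

$$\mathrm{Dist}(A,B) \;=\; 1 - \frac{|a \cap b|}{\min(|a|, |b|)},$$

one minus the overlap coefficient. Normalizing by the *smaller* set
lets a 500-gene genome be compared against a 20,000-gene genome without
the size difference masquerading as divergence.

When the shared fraction $s = |a\cap b| / \min(|a|,|b|)$ falls below a
minimum-overlap threshold (default 5%), the overlap is deemed
uninformative and the distance is clamped to exactly 1: a species with
very few genes will share a handful of motifs with anything by chance,
and those coincidences should not pull it toward an unrelated clade.
Two consequences are load-bearing and are property-tested: every
distance lies in $[0,1]$, and no emitted value falls strictly inside
$(1 - \texttt{min\_overlap},\, 1)$. The threshold is exposed
(`min_overlap`, set 0 to disable) because the natural sensitivity check
is to turn the rule off. We interpret the threshold against
$\min(|a|,|b|)$ — the same denominator as the distance — which is the
reading that makes the rule scale-free; it is configurable rather than
hard-coded for exactly this reason.

## Tree reconstruction

Distances are combined by canonical Saitou–Nei neighbor-joining with
the Studier–Keppler $O(n^3)$ update, implemented in the package rather
than delegated, so that behavior is fully specified: ties in the
$Q$-criterion are broken by the lexicographically smallest pair of
cluster representatives (making output byte-identical across platforms
and label orders), negative limb lengths are kept internally — they are
what makes the additive-matrix recovery property exactly testable — and
clamped to zero only at serialization, and the unrooted result is
anchored at the final trifurcation for writing. `ape::nj()` serves as
an independent cross-check in the test suite, never as the
implementation.

On any matrix that is additive on a binary tree, the implementation
recovers that topology exactly and reproduces every leaf-to-leaf path
length to within $10^{-9}$; the test suite verifies this on hundreds of
random trees of 4–16 leaves, and verifies on random quartets that the
chosen split agrees with exhaustive evaluation of the join criterion.

## Tree comparison

Recovered trees are scored against a reference by **edge similarity**:
after pruning both trees to their shared leaf set (references rarely
cover exactly the analyzed species), the percentage of the source
tree's non-trivial bipartitions that also occur in the reference. The
metric is unrooted, ignores branch lengths, and tolerates polytomies —
an unresolved node simply contributes fewer bipartitions, and a
multifurcation's splits are matched by exact set identity, the simplest
defensible reading of a branch being "present" in the other tree. We
normalize by the source tree's split count because the question asked
is "how much of the recovered tree is right?"; the `denominator`
argument flips the orientation since both conventions exist in the
wild. A source tree with no internal structure at all scores 100 by
convention (with a warning): it asserts nothing false.

## What the simulator emulates — and what it does not

The simulator exists so the whole pipeline is testable without
downloads. It emulates exactly one assumption: codon aversion is
phylogenetically conserved, so motif sets diverge with evolutionary
distance.

* An ancestral genome of `n_genes` genes receives aversion sets by
  excluding each non-start codon independently with probability
  `aversion_rate` (at least one stop codon is always kept usable).
* Sets are copied down a user-supplied tree; on each branch each gene
  is perturbed with probability `min(1, flip_rate × branch length)` by
  adding or removing one uniformly chosen eligible codon.
* Each leaf is realized as CDS FASTA in which every non-averted codon
  of a gene appears at least once, so the realized motif *equals* the
  intended set. This coverage guarantee decouples pipeline tests from
  sampling noise; closure (extracted motif = intended set) is itself a
  test.

Defaults are chosen to look like real coding data: `aversion_rate =
0.23` puts the mean motif size near 14.5 codons, matching the
genome-scale average of roughly 14.5 with standard deviation of about
8.7 observed across species; `n_genes = 100` and gene lengths of
80–150 codons keep simulations cheap while leaving motif collisions
rare; `flip_rate = 0.15` per unit branch length keeps the expected
shared-motif fraction of the most distant pair in a unit-branch-length
16-leaf balanced tree near $0.85^8 \approx 0.27$, above the 5% clamp
so every pair remains informative.

The simulator is a test harness, not a biological claim. It does not
model codon substitution processes (GY94 and relatives), indels,
GC-biased gene conversion, gene gain/loss, or rate heterogeneity across
genes; real genomes also violate the coverage guarantee (a real gene's
motif includes codons avoided by chance, correlated with gene length).
Passing the synthetic recovery tests therefore shows the machinery is
correct and the statistic behaves as designed under its own
assumptions — not that codon aversion carries this much signal in any
particular real clade.

## Numerical and degenerate-input choices

* Distances are simple double-precision ratios of small integers,
  emitted as 6-decimal text; matrix parsing averages asymmetries within
  $10^{-6}$ and rejects anything larger, as well as ragged rows and
  lower-triangle-only PHYLIP variants.
* A matrix with all off-diagonal entries equal is a legitimate input;
  the tie rule makes the (arbitrary) resolved topology deterministic.
* Fewer than 3 species (distance matrix), fewer than 4 shared leaves
  (tree comparison), empty motif sets, and mixed codon/amino-acid
  profiles are errors, not silent degradations.
* Isoform collapsing keeps the longest sequence per `gene=` header key,
  first-seen on ties; records without the key are never collapsed.
  Exception and partial flags come from configurable header substrings
  (`exception`/`transl_except`, `partial`), since annotation practice
  varies; defaults drop exceptions and keep partials.

## Problem sizes in the checks

The bundled verification uses batteries sized to be decisive yet quick:
10,000 random motif-set pairs (plus an exhaustive small-universe sweep)
for the distance bounds and clamp gap; several hundred random additive
matrices of 4–16 leaves for neighbor-joining; and 10–20 seeded
replicates of a 16-species, 100-genes-per-species simulation for
end-to-end recovery. These sizes are the package's own choice of a
convincing demonstration; nothing in the method depends on them.

## A worked pipeline

```{r pipeline}
cfg <- sim_config("((A:1,B:1):2,(C:1,D:1):2);", n_genes = 50, seed = 42)
sim <- evolve_along_tree(cfg)
profiles <- sim_profiles(sim)
profiles[["A"]]

m <- cam_distance_matrix(profiles)
m

tree <- nj_tree(m)
write_newick(tree)

edge_similarity(tree, sim$tree)
```

With four species there is a single non-trivial split, and moderate
divergence leaves it easy to recover: the similarity printed above is
100 when the cherry `(A,B)` survives the pipeline.

## Limitations

Edge similarity conventions differ between toolkits (normalization
orientation, polytomy credit); ours are documented above and are not
claimed to be bit-identical to any particular implementation. The
genetic-code table is selected per run, not per species, so mixing
organisms under different codes requires separate runs. And the method
inherits the field's caveat for alignment-free approaches generally:
distances are not substitution counts, so branch lengths are
comparative, not temporal.
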