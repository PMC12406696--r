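---
title: "Mining phytate-hydrolysis genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining phytate-hydrolysis genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytascan)
```

This vignette explains the science implemented in `phytascan`: the models
behind each stage, the parameters that matter and their defaults, what the
synthetic-data generators emulate (and deliberately do not), and the design
choices made where the underlying methodology left the design open.

## The problem

Phytate (InsP6) stores six phosphate groups on a *myo*-inositol ring and is
a substantial component of dissolved organic phosphorus in coastal seas.
Four enzyme families release that phosphorus: alkaline β-propeller phytases
(BPP) and the acid families HAP, CP and PAP. Finding their genes in
environmental protein sets is a three-stage decision problem — homology
search, conservation screening, abundance quantification — followed by
community-level ecology and enzyme-level biochemistry.

## Reference catalog and clade model

The catalog (in `inst/extdata/table1_catalog.tsv`) lists one representative
per clade of validated phytases with its conserved motifs and their 1-based
anchor positions, plus the accessions of homologs grouped with it. A clade
is a set of validated sequences sharing more than 28 % pairwise identity;
at that threshold the validated set forms 4 BPP, 8 HAP, 2 CP and 2 PAP
clades.

**Identity definition.** The grouping rule names only a threshold, not an
algorithm, so the package fixes the conventional definition: identical
residues over aligned columns of a global (Needleman–Wunsch) alignment
under BLOSUM62 with gap opening 10 and extension 0.5, counting internal gap
columns and excluding terminal overhangs. Because co-optimal alignments
can differ between argument orders, `pairwise_identity()` canonicalizes
the orientation so the measure is exactly symmetric.

**Clustering linkage.** Whether the >28 % rule is applied against the
representative or all members is not specified; `cluster_into_clades()`
uses representative linkage with greedy seeding in descending length order.
This is deterministic, reproduces the published clade structure, and makes
the membership invariant "every member exceeds the threshold against its
representative" true by construction.

**Reference sequences.** The validated sequences are referenced by
accession and are not redistributed. `synthetic_reference_set()` builds
clearly labelled synthetic stand-ins: background-composition random
sequences long enough to host each clade's motifs, with every motif written
at its printed anchor, and one synthetic homolog per listed accession at a
controlled identity (default 0.7) to its representative. These stand-ins
preserve exactly the properties the pipeline's logic depends on — motif
anchors, within-clade identity above threshold, between-clade identity
below it — but they are not the biological sequences, so analyses that
depend on real evolutionary distances (e.g. tree topology among families)
are structural checks only.

## Profile search and E-values

Profiles are position-specific log-odds matrices: per-column residue
probabilities against a UniProt-like background, in bits. Columns with
more than 50 % gaps are dropped (match-column rule).

**Pseudocounts.** Column probabilities are
$(c_a + w\,b_a)/(n + w)$ with $w = 1$ by default — pseudocounts
proportional to the background $b_a$, not a flat +1 per residue. With the
single-sequence and few-sequence profiles this pipeline builds, flat
Laplace smoothing compresses the log-odds scores so strongly that even a
60 %-identity homolog cannot reach the E-value cutoff; background-
proportional pseudocounts keep the observed residue dominant while still
regularizing unseen residues, preserving the intended decision semantics
(score → E-value → cutoff).

**Scanning.** A candidate is scored by its best ungapped placement of the
profile (compiled scanner), requiring at least 30 columns of overlap.
Ungapped placement is a deliberate simplification: the screening stage
realigns every hit globally anyway, and planted-homolog benchmarks show
full sensitivity at 40–80 % identity.

**E-value calibration.** Maximal-placement scores of random background
sequences follow an extreme-value (Gumbel) law; `calibrate_evalues()` fits
it by the method of moments over `n_random` (default 200) seeded random
sequences and reports $E(s) = N \kappa e^{-\lambda s}$ scaled to the
scanned database size $N$, the convention of standard profile-search
tools. The cutoff (default `1e-30`) is applied per profile–query pair,
and the best clade per family is kept for each query. Because genuine
homologs sit hundreds of bits above the null tail, the large extrapolation
inherent in a `1e-30` threshold separates cleanly: across seeded
benchmarks, all planted homologs pass and no background sequence does.

## Motif screening

Motif patterns use a small grammar: fixed residues, `X` (any standard
residue, never a gap), bracketed alternatives `[D/E]`, and whole-motif
alternates (`HD/HAE` — either form qualifies). Each motif's anchor is
projected from the representative onto the candidate through the global
alignment column map; the candidate is searched within a
`tolerance_window` of 10 residues around the projected start, nearest
offsets first. The window absorbs small indels while keeping the chance
of a spurious match low; with it set to 0 the screen would reject
legitimate homologs with insertions, and with a much larger window short
motifs like `DG` would begin to match by chance.

A sequence qualifies only if **all** of its clade's motifs are found
(`min_motifs` exposes a quorum for exploration). Sequences shorter than
the earliest anchor minus the window are rejected as "sequence too
short". For clades lacking validated structures the neighbor-joining tree
(`build_nj_tree`, non-negative branch lengths) is an advisory screen:
candidates outside the validated members' subtree should be flagged for
inspection rather than auto-excluded, which is the conservative reading
of tree-based screening.

## Abundance and taxonomy

Relative abundance is gene count divided by the mean count of 10 universal
single-copy bacterial marker genes in the same sample (the package
defaults to the ribosomal-protein/tRNA-synthetase COGs COG0012, COG0016,
COG0018, COG0172, COG0215, COG0495, COG0525, COG0533, COG0541, COG0552;
the set is configurable since the normalization source does not list
them). The quotient is exactly invariant to uniform depth scaling, and
counts may be fractional. Metatranscriptome tables are normalized by the
same rule and flagged as such in output metadata.

Best-hit taxonomy consumes a precomputed hit table (maximal bitscore, ties
by E-value then subject id; unresolvable lineages become "unclassified" and
are retained). Class frequencies are normalized to 1 within each sample
type; shared-class counts use exclusive Venn-region semantics, so regions
partition the union of class sets.

## Community ecology and the stochasticity ratio

Bray–Curtis dissimilarities, PCoA (Lingoes correction when negative
eigenvalues arise, variance fractions on corrected eigenvalues), richness
with two-sided rank-sum group tests, Hellinger-transformed RDA, and
distance decay of similarity against log10 haversine distance are all thin,
tested surfaces over the standard vegan/ape machinery.

The normalized stochasticity ratio (NST) is implemented in the package.
For each within-group pair, the observed dissimilarity $D$ (quantitative
Jaccard/Ružička by default; incidence Jaccard available — the variant is
recorded in the output) is compared with its null expectation $E$ under a
richness-preserving, occupancy-proportional taxa shuffle: each null sample
keeps its own richness and abundance values, re-draws which taxa are
occupied with probability proportional to regional occurrence frequency,
and permutes its values onto them. The pairwise normalized stochasticity is
$(1 - D)/(1 - E)$ when $D > E$ and $D/E$ otherwise, so a pair at its null
expectation scores 1 and extreme determinism scores 0; the group NST is
the pairwise mean × 100, with 50 % as the interpretive boundary. The
taxa-shuffle null is essential: a null that refills abundances from
regional means regenerates environmentally filtered communities and cannot
detect their determinism. 1000 replicates (default) give a Monte-Carlo
standard error on NST well under one percentage point at 20 samples; the
seed is mandatory and results are exactly reproducible.

## Biochemistry

Monoisotopic masses use C 12, H 1.0078250319, O 15.9949146221,
P 30.97376151 and proton mass 1.00727646688; an InsP$_n$ species has
formula C6H(12+n)O(6+3n)Pn and negative-mode m/z
$(M - |z| m_p)/|z|$. Dephosphorylation is modelled as a per-class removal
order over ring positions; the orders are configurable because only the
initial-site class and the terminal products are firm contracts — BPP
strips alternate phosphates from InsP6 down to Ins(2,4,6)P3 (3 released),
the acid phytases continue to Ins(2)P (5 released); the 2-phosphate is
never removed by these enzymes. Defaults: BPP 3→1→5, HAP 3→4→5→6→1,
CP 5→4→6→3→1, PAP 5→6→4→3→1.

Kinetic constants default to the double-reciprocal (Lineweaver–Burk)
method — ordinary least squares of $1/v$ on $1/S$, $K_m$ = slope/intercept,
$V_{max}$ = 1/intercept — because that is the method used at the bench; a
direct nonlinear least-squares fit is provided as a labelled alternative
and never silently substituted (under heteroscedastic noise the two
disagree, and both are reported). $k_{cat} = V_{max} \cdot M_w / 60000$
converts a specific activity in µmol·min⁻¹·mg⁻¹ to s⁻¹ per total protein
(whether published values used total or active protein is not stated; the
contract here is per-total-protein). The degradation-rate helper fits a
least-squares slope to the concentration series, subtracts an optional
abiotic blank slope, and normalizes by sample mass.

## What the generators emulate — and what passing tests show

The synthetic generators reproduce the *decision structure* of real data:
background proteomes with planted homologs at controlled identity and
known motif status; Poisson count tables with known per-genome-equivalent
abundances and uneven depths; community matrices under neutral
(metacommunity sampling with Dirichlet drift, concentration 10) versus
selective (one fixed composition) assembly; Michaelis–Menten data with
optional truncated Gaussian noise. They do not emulate compositional
biases of real proteomes, domain shuffling, chimeric assemblies, lineage-
correlated residue usage, or spatially structured metacommunities — so
green tests demonstrate that the pipeline's logic and calibration are
correct, not that its sensitivity/specificity trade-offs transfer
unchanged to ocean metagenomes (at desk scale they cannot: the original
survey spanned hundreds of metagenomes and a live non-redundant protein
database).

Problem sizes in the tests and drivers (1000-protein proteomes, 20-sample
communities, 1000 null replicates, 108 reference sequences) were chosen as
the smallest sizes at which each statistic is stable and the ground-truth
counts are unambiguous.

## Known limitations

* The search engine is a calibrated PSSM scan, not a full profile HMM with
  insert/delete states; an external profile-HMM engine can stand behind
  the same hit contract where available.
* Synthetic reference stand-ins preserve anchors and identity structure
  but not real phylogeny; clade counts and motif localization on them are
  structural, not biological, validations.
* NST here implements one abundance-based variant with one null model
  family; published stochasticity estimates depend measurably on the
  variant, which is why the output records it.
* E-values at `1e-30` are extrapolations far beyond the calibration range;
  they are decision thresholds, not frequentist tail probabilities.
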