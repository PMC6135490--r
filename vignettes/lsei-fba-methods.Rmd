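---
title: "Lsei-FBA: model, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lsei-FBA: model, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lseifba)
```

## The scientific problem

Metabolic fluxes in small brain regions and specific neuronal
populations cannot be measured in patients; gene expression in the same
material can. Lsei-FBA predicts the complete steady-state flux
distribution of brain central energy metabolism in two stages: a
flux-balance-analysis (FBA) solution for the healthy state anchored to
measured whole-brain uptake and release rates, and a
constrained-least-squares re-estimation for the diseased state driven by
case/control expression fold changes. The working hypothesis is that
relative flux changes tend to parallel expression changes at the level
of the connected network, not of individual enzymes; the least-squares
stage is exactly the mechanism that lets strongly connected reactions
override their own (noisy or discordant) gene evidence.

## The packaged network

`default_brain_network()` returns a manually curated model of 69
reactions over 78 metabolites in three compartments (extracellular,
cytosolic, mitochondrial): glycolysis (10 steps), a lumped pentose
phosphate pathway, lactate dehydrogenase and monocarboxylate transport,
pyruvate carboxylase and both malic enzymes, the full TCA cycle with
GDP-linked succinyl-CoA ligase and mitochondrial NDP kinase, the
electron transport chain and ATP synthase with explicit matrix-proton
stoichiometry, adenine-nucleotide/phosphate/dicarboxylate carriers, the
malate-aspartate and glycerol-phosphate redox shuttles, the GABA shunt,
the glutamine-glutamate cycle with ammonium transport, a
glutathione/NADPH antioxidant demand chain, alanine transamination and
release, an inner-membrane proton leak, and a lumped cytosolic ATP
demand (ion pumping). All fluxes are in micromol per gram wet brain per
minute. Reactions carry HGNC gene symbols, including the
mitochondrially encoded ETC subunits (ND1-ND6, CYTB, COX1-COX3,
ATP6/ATP8), which matter for disease datasets where mtDNA transcripts
move differently from nuclear ones.

Boundary handling: metabolites exchanged with blood (glucose, lactate,
glutamine, pyruvate, O2, CO2, water, ammonium, alanine) live in an
extracellular pool that is *not* mass-balanced; the membrane
transporters are therefore the uptake/release reactions, with uptake
positive and release negative (glucose uptake is the fixed 0.203 on the
glucose transporter). Matrix protons are balanced exactly — this is
what ties ATP synthesis to the respiratory chain — while cytosolic
protons are deliberately left unbalanced so that the many
proton-releasing cytosolic reactions do not over-constrain a
one-compartment-pH model.

### Proton bookkeeping and calibration

The printed healthy-state target (5.39 micromol ATP/g/min produced by
the mitochondrial ATP synthase) is fully determined by the matrix-proton
ledger once the exchange rates and flux ratios are fixed, so the
curation of proton-coupled steps is the model's calibration. The
packaged choices, each physiologically standard:

* complex I translocates 4 H+ per NADH (plus the chemical matrix proton
  of the NADH redox pair), complex III 4 H+ per ubiquinol (2 of them
  taken from the matrix), complex IV 2 H+ pumped plus 2 chemical per
  2 e-; ATP synthase consumes 3 H+ per ATP and the phosphate carrier 1,
  giving the textbook P/O of about 2.5 (NADH) and 1.5 (FADH2);
* the aspartate/glutamate carrier of the malate-aspartate shuttle is
  electrogenic and proton-compensated (1 H+ into the matrix per cycle),
  which is why the shuttle yields slightly less ATP per cytosolic NADH
  than matrix NADH and why the glycerol-phosphate shuttle (ubiquinol
  entry, no proton cost, lower yield) is strictly dominated at the
  optimum — the LP predicts it inactive;
* the glutamate/OH- antiporter exports matrix glutamate at the cost of
  one matrix proton; pyruvate and ammonium transport are modeled
  proton-neutral; pyruvate carboxylase is written with CO2 (no
  bicarbonate/carbonic-anhydrase proton);
* NAD-linked dehydrogenases are written in BiGG convention (malate
  dehydrogenase and succinate-semialdehyde dehydrogenase release the
  chemical matrix proton; pyruvate, isocitrate and alpha-ketoglutarate
  dehydrogenases and malic enzyme do not carry a free proton).

With the measured constraints (glucose uptake 0.203; lactate, glutamine
and pyruvate release 0.0092, 0.011 and 0.0024; pentose phosphate flux
6.9% of hexokinase; pyruvate carboxylase 13%, glutamine-glutamate
cycling 62% and GABA shunt 32% of glucose uptake) this ledger closes at
an ATP synthase flux of 5.3890 and an oxygen:glucose uptake ratio of
5.59 — the oxygen deficit relative to 6 comes from the carbon leaving as
lactate, glutamine, pyruvate and the pentose-shunt CO2, plus the NADPH
drained to antioxidant demand. The value can be reproduced by hand from
the reaction table: sum the matrix NADH and ubiquinol production, apply
the proton stoichiometries above, subtract the carrier costs, divide
by 4.

The exact composition of the historical 69-reaction list is not
published in machine-readable form; this package's model is a
re-curation from BiGG-style reactions to the stated pathway scope,
calibrated to reproduce the printed healthy solution, and should be read
as *equivalent*, not identical. Reaction count, pathway coverage,
reversibility assignments and the headline fluxes match; individual
side-reactions (the antioxidant chain, alanine release, the proton leak,
the dicarboxylate carrier, cytosolic malic enzyme) are standard brain
reactions whose healthy fluxes are either zero or pinned by linear
chains, so they do not perturb the calibrated optimum.

## Healthy-state FBA and uniqueness

`solve_fba()` maximizes ATP synthase flux subject to mass balance of the
68 internal metabolites, the fixed exchanges, the flux-ratio equalities
and irreversibility. "Maximize ATP synthesis" is the appropriate
objective for adult brain (no net growth); glycolytic substrate-level
ATP is tracked but not part of the objective, which the matrix-proton
balance ties to oxidative phosphorylation.

The equality system is rank-deficient (conserved moieties: NAD(H) and
NADP(H) pools per compartment, CoA, adenine and guanine nucleotides,
ubiquinone, cytochrome c, glutathione); dependent rows are dropped by
pivoted QR before solving and re-checked afterwards, so an inconsistent
(infeasible) system is detected rather than silently projected. The LP
itself is solved by the package's dense two-phase revised simplex with
Bland's anti-cycling rule: the general-purpose simplex routines
available to R failed with internal errors on this degenerate,
rank-deficient polytope, and a ~150-line deterministic implementation
that is tested against closed-form toy solutions was the more auditable
choice at this scale (about 60 rows by 110 columns after splitting
reversible fluxes). Feasibility tolerance is 1e-10 relative, chosen
well below the smallest meaningful bound displacement (1e-7, see below)
and well above phase-1 roundoff.

`flux_variability()` pins the objective at its optimum and
minimizes/maximizes every reaction over the remaining feasible set,
working in the null space of the pinned equality system so only
reactions with genuine degrees of freedom need LP solves. The packaged
model's optimum is a single point (every span below 1e-6; in fact the
pinned null space is empty, because the only feasible degree of freedom
— the split between the two redox shuttles — is fixed by optimality).
An error of a missing bound (a "leak") surfaces as an unbounded LP with
an explicit message; infeasible constraint sets are reported with a
greedy irreducible subset of the named constraints.

## Fold changes and the diseased-state program

Per-gene fold changes are computed on the log2 scale
(`2^(mean patient - mean control)`), making them invariant to global
normalization shifts and exactly reciprocal under label swap; per
reaction they are aggregated as the arithmetic mean of the linear fold
changes of the matched genes (isozymes and complex subunits weighted
equally — the source procedure states a plain average, so no min/max
gene-association logic is applied). Reactions without matched genes get
fold change 1, coverage 0.

The diseased program minimizes the weighted squared deviation from
`v0 = healthy * fc` over the steady-state cone. Two weight policies are
implemented: `"coverage"` (default) gives weight 0 to reactions without
expression evidence, so boundary exchanges and spontaneous transport
steps are set purely by network balance rather than pulled back to their
healthy values; `"uniform"` weights everything. The choice is recorded
in every output header. No exchange rates are fixed in the diseased
program — predicted uptake and release changes are outputs.

The solver parameterizes the feasible set by an orthonormal null-space
basis of S (computed once per problem and reused across the thousands of
re-solves of a permutation test) and runs a primal active-set iteration
over the bound constraints, with minimum-norm steps on flat directions
(the weight-0 coordinates make the quadratic only positive
*semi*-definite) and smallest-index tie-breaking, so repeated solves are
bit-identical. The independent check in the test suite is a Dykstra
alternating-projection solver — a genuinely different algorithm — which
agrees to better than 1e-6 on a hundred random toy problems.

### The displacement uniqueness certificate

For each reaction the program is re-solved with that flux forced below
and above the solution by `max(1e-5 * |v|, 1e-7)`; the solution is
certified unique when every perturbed minimum cost strictly exceeds the
original. Two numerical choices matter. First, zero fluxes are
displaced by the absolute floor 1e-7 (a purely relative rule would never
test them); a displacement that is infeasible — pushing an irreversible
zero flux negative, or fighting a coupled chain — counts as infinitely
costly. Second, the strictness margin is 1e-16: a displacement of size
d can raise a strictly convex quadratic cost by as little as order d^2,
i.e. ~1e-14 for floor displacements (and for any flux below 0.1), while
the solver's noise in the cost is around 1e-20, so the margin must sit
between the two; margins of 1e-12 or larger would misclassify genuinely
unique solutions as non-unique. On the packaged model the smallest
genuine cost increase observed across all displacements is about 1e-14.

## Statistics

Reactions in unbranched chains carry identical flux and are completely
dependent, so testing is per fully-coupled set. Coupling is detected
structurally (rows of a null-space basis equal up to sign) and verified
on 50 random interior points, which separates reactions whose healthy
fluxes merely coincide numerically. The packaged model partitions into
42 sets; the count is a property of the network and is reported, not
imposed.

Per study, significance of each reaction's predicted change is assessed
by sample-label permutation: group labels are shuffled (sizes
preserved), the entire fold-change-to-LSEI pipeline is re-run, and the
two-tailed add-one p-value `(1 + #{|d_perm| >= |d_obs|}) / (n_perm + 1)`
is reported; when the number of distinct relabelings is at most `n_perm`
they are enumerated exhaustively and the p-value is the exact fraction.
The default is 100,000 permutations; the bundled demo and tests use
hundreds. Across studies, one-sample t-tests compare the per-study
predictions of each set representative against the healthy value
(zero-variance sets are flagged degenerate), and the per-study
permutation p-values are combined with Fisher's method (`X = -2 sum log
p` against chi-square with 2k df; exact zeros are rejected, which the
add-one estimator guarantees). The family-wise error rate over sets is
controlled by Holm's step-down; at 31 sets and alpha 0.05 the rank-1
threshold is 0.05/31 = 0.0016.

One calibration subtlety is documented because it shapes how the
package's own checks are built: within one study the per-reaction
permutation p-values are strongly dependent — coupled sets share p-values
exactly, the least-squares projection couples everything else, and all
reactions share the same permutation draws. The marginal distribution
is exactly calibrated (measured null rejection rate 0.053 at nominal
0.05 over 200 studies), but a binomial band for the pooled rejection
fraction is only valid across independent studies, so the packaged
type-I-error check samples one set-representative p-value per
independent synthetic null study (60 studies at 999 permutations).

## The synthetic-data generator

`generate_study()` emulates an RMA-normalized case/control microarray
study: per-gene baseline log2 intensities N(8, 1.5), patient-group
shifts equal to log2 of the reaction-level true fold change, i.i.d.
gaussian log2 noise per sample (default sd 0.2, typical of post-mortem
brain arrays after normalization), default 10+10 samples and 3 genes per
reaction (isozyme/subunit multiplicity). Two gene modes: unique
synthetic symbols per reaction (the ground truth is exactly expressible
at the gene level — used for recovery and calibration experiments), or
the network's real gene lists, where a shared gene (e.g. DLD in both
dehydrogenase complexes) gets the mean log2 fold change of its reactions
— realistic blur that the exact-recovery results deliberately avoid.

Ground-truth fold changes come from `feasible_disease_profile()`:
healthy fluxes are scaled per subsystem and projected back onto the
steady-state cone. The projection is sign-preserving (each nonzero flux
keeps at least 5% of its healthy magnitude on the same side of zero) and
pins zero-healthy reactions at zero, because a multiplicative fold
change can encode neither a sign reversal nor an activation from zero;
with those guards the implied diseased vector is exactly `healthy * fc`
and a noise-free study is recovered to machine precision by the full
pipeline. What the generator does *not* emulate: batch and platform
effects, probe-level artifacts, cell-type composition shifts, and
dependence between genes beyond shared reaction membership — so passing
recovery tests demonstrate correctness of the estimation machinery, not
robustness to the full mess of real microarray data.

Problem sizes used by the packaged checks (chosen as comfortable
desk-scale experiments): 100 random toy programs for the oracle
equivalence; 20 replicates at noise 0.1 for delta-correlation recovery;
60 independent null studies at 999 permutations for type-I calibration;
20 synthetic studies for the uniqueness-certificate sweep.

## Known limitations

* The network is a lumped single-tissue model: neurons and glia share
  one cytosol, so cell-type-specific exchange (the vesicular
  glutamate/GABA cycles as inter-cellular loops) is representable only
  as net chemistry, and predictions are averages over the sampled
  tissue.
* The 69-reaction curation is calibrated to the printed healthy
  solution but is not the authors' exact table; per-reaction
  identifiers and gene maps may differ in detail.
* The proportionality hypothesis between expression and flux is a
  network-level tendency; individual reactions (especially transporters
  regulated post-translationally) can violate it, and the least-squares
  stage will then redistribute their deviation onto neighbors.
* Fold-change aggregation ignores gene-protein-reaction boolean
  structure (no AND/OR logic) and treats all isozymes equally.
* The LP/QP machinery is dense and deterministic, sized for
  ~10^2-reaction models; genome-scale reconstructions would need sparse
  factorizations and a production solver.
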