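---
title: "Methods: binding promiscuity analysis with bindscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding promiscuity analysis with bindscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bindscape` analyses structurally resolved small-molecule binding events:
which compounds bind many unrelated protein pockets (promiscuous) versus
one or two (selective), and how this relates to compound physicochemistry,
target enzyme diversity, and pathway membership. This vignette documents
the model and procedure, every tunable that matters, the numerical
choices, what the synthetic-data generator does and does not emulate, and
known limitations.

## Pipeline model and assumptions

The analysis treats a crystal structure as ground truth for a physical
binding event. Its stages, with the admission rules applied in order:

1. **Structure admission.** Only X-ray structures with a recorded
   resolution at or below 2.0 Å are used ("2 Å or better" is read as an
   inclusive bound; entries without a resolution record, such as NMR
   models, cannot satisfy it and are dropped). Only the first model of a
   multi-model file is read; alternate atom locations are resolved to the
   highest-occupancy copy, ties to the first in file order.
2. **Ligand admission.** A HETATM group is an analyzable ligand when its
   weight lies in [30, 1000] Da, its component code is not on the
   ion/solvent exclusion list, and it is not covalently bound. Crystal
   models rarely contain hydrogens, so the weight of a ligand *instance*
   is summed over the atoms present (a heavy-atom weight); the compound
   records used for library matching carry full weights with implicit
   hydrogens. The exclusion list shipped as
   `default_ligand_exclusions` is a curated approximation (water, MES,
   DMSO, glycerol, 2-mercaptoethanol, common ions, cryoprotectants) and
   is user-overridable, since no exhaustive canonical list exists.
   Covalency is decided by a geometric heuristic: any ligand heavy atom
   closer than 1.9 Å to a protein heavy atom — the conventional ceiling
   for a covalent bond length — flags the instance as covalent.
3. **Pocket definition.** A binding pocket is the set of residues of one
   chain with at least one heavy atom within 5.0 Å (closed ball; the
   boundary case is included, and an epsilon of 1e-9 Å absorbs floating
   point noise) of any ligand heavy atom, requiring at least three such
   residues. Chains are independent targets, so a ligand wedged between
   two chains yields up to two pockets; whether cross-chain contacts
   should pool into one pocket is genuinely open, and the per-chain
   choice matches treating every chain as a separate target. No
   crystallographic symmetry expansion is performed. Residues outside
   the 20 standard types count toward the three-residue threshold but
   contribute nothing to the 20-dimensional composition vector, which is
   defined over the standard amino acids only.
4. **Redundancy reduction.** Pockets of one compound on one protein
   (chains with 100% identical sequence) are clustered by complete
   linkage under the Bray-Curtis dissimilarity of their composition
   vectors and cut so that every cluster's merge height is ≤ 0.3; one
   representative survives per cluster. The representative rule — most
   residues, ties broken lexicographically by structure and chain id —
   is a determinism choice; the method itself does not prescribe one.
   Targets of a compound are then single-linkage clustered at ≥ 30%
   pairwise identity with ≥ 95% alignment coverage on at least one
   member, and only pockets on the representative protein of each
   cluster are kept. Identity is computed from global Needleman-Wunsch
   alignments (BLOSUM62, gap open 10, extend 0.5) as identical positions
   over alignment length. This is a reproducible stand-in for
   Blastclust's score-based coverage clustering; borderline pairs near
   the 30% threshold may cluster differently than Blastclust would.
5. **Promiscuity.** Compounds with ≥ 3 non-redundant pockets are
   promiscuous, 1–2 selective. Compounds with zero events are excluded
   and logged.

## Compound classification and descriptors

Structure-derived compounds are matched to reference libraries by near
identity: weights within ±1 Da *and* fingerprint Tanimoto similarity
strictly above 0.95. Matches only in the drug library give class `drug`,
only in a metabolite library `metabolite`, in both `overlapping`, in
neither `unassigned`. The fingerprint is a 1024-bit hashed linear-path
fingerprint over the heavy-atom graph (paths up to 5 atoms, labeled by
elements and bond orders, orientation-canonicalized). It is configurable
and deliberately engine-neutral: the matching rule needs any
fingerprint for which near-identical molecules score near 1, not a
specific bit layout.

Descriptors that are pure functions of the molecular graph (atom and
ring counts, rotatable bonds, sp³ carbon fraction, donor/acceptor
counts, Wiener, Balaban, Platt indices, vertex adjacency information
magnitude `1 + log2(bonds)`) are computed internally; "relative"
variants divide by heavy-atom count. Descriptors that require 3D
geometry or empirical models (logP, pKa, pI, TPSA, ASA) are expected
from a user-supplied table (`load_descriptor_table()`), which also
overrides any computed column — this decouples the statistics from any
one chemistry engine. A crude additive logP estimator exists solely to
give synthetic molecules a plausible hydrophobicity scale and is labeled
approximate.

## Propensity statistics

For a descriptor `t` and class selection `c`, the pooled
promiscuous-plus-selective values are split into `n_bins = 10`
equal-count intervals (edges at midpoints between order statistics, so
tie-free occupancies differ by at most one; tied edges merge with a
warning). Per bin,

* `f_i = q_i / Σq` (promiscuous relative frequency),
* `g_i = s_i / Σs` (selective relative frequency),
* propensity `P_i = f_i / g_i`, reported as `log10 P_i`,
* `se_i = (1/g_i) · sqrt(f_i (1 − f_i) / Σq)`.

Ten bins reflect the granularity at which such profiles are typically
displayed; the count is configurable. Binning on pooled values (rather
than per label group) is what makes "equal counts" well defined for the
profile as a whole. If any bin count is zero, 0.5 is added to every
count of the profile (a Haldane–Anscombe-style correction) so the log is
finite; affected bins are flagged. The standard error covers sampling
noise in the promiscuous frequencies only; bins whose `P_i` sits within
about two such errors of 1 should not be over-interpreted.

The same ratio over residue types — pocket counts against counts in
non-binding-site parts of the chains — gives the amino-acid composition
propensities, groupable by compound class or by promiscuity label. The
background always excludes residues belonging to *any* pocket, not just
the analyzed group's.

## Target diversity

**EC entropy.** A compound's targets are counted over seven categories:
top-level EC classes 1–6 plus "None" for unannotated chains; a chain
with several top-level classes counts once in each. Counts are divided
by the background size of each category in the full ingested target set
(`w_i = c_i / N_i`), normalized to probabilities, and summarized as
Shannon entropy in natural log units, ranging 0 to ln 7 ≈ 1.946. The
background weighting prevents abundant classes (e.g. hydrolases) from
dominating the entropy; the unweighted variant is available via
`weighted = FALSE` because the double-normalization phrasing admits both
readings. Compounds need ≥ 3 distinct targets, counted at the protein
(not pocket) level.

**Pocket variability.** `PV = Σ σ_i²/μ_i` over residue types present in
at least one of the compound's pockets, with the sample variance
(`n − 1`), computed across its non-redundant pockets (≥ 3 required).
`PV = 0` exactly when all pockets share one composition; the
variance-to-mean form makes it insensitive to compound size. The
`diversity_table()` report includes the four-quadrant classification
with default thresholds EC ≥ 2 / < 1 and PV ≥ 1.2 / < 0.8.

## Prediction models

PLS regression (via mixOmics, predictors standardized — descriptor
scales span orders of magnitude, so unscaled fits would be dominated by
the largest columns) is fit for log10 pocket count, PV, and EC entropy.
The component count (≤ 10) minimizes the 10-fold cross-validated RMSEP;
the reported `r` correlates measured values with leave-one-out
predictions at that count. Loadings of the first two components are
exposed, each oriented so its score correlates positively with the
response (PLS signs are otherwise arbitrary, which would make loading
signs meaningless across runs). The SVM classifier standardizes
variables and reports stratified 5-fold cross-validation error for
linear, RBF and polynomial kernels. The CART tree is grown permissively
(cp = 1e-4) and pruned to the split count within 3–10 minimizing the
cross-validated error; the reported error is the cross-validated
relative error rescaled by the root misclassification rate. All fold
assignments derive from a recorded seed.

## Enrichment

Each annotation term yields a 2×2 table of promiscuous/selective ×
in-term/not-in-term over the mapped-compound universe, tested two-sided
with Fisher's exact test so enrichment and depletion are both reported
(the sample cross-product ratio is the effect size). Within each
category a "Not assigned" pseudo-term collects universe compounds with
no term there. BH correction is applied within each (category, level)
family — mirroring separately reported collective and detailed tables —
with a global-family alternative behind a flag. Categories annotating
fewer than 20 unique compounds are dropped as too sparse to test.

## The synthetic-data generator

The generator's job is to produce every input the pipeline consumes with
known ground truth, at conditions resembling the real structural corpus:

* **Class mixture** 38% drug / 21% metabolite / 31% overlapping / 10%
  unassigned — the observed class shares of structure-derived compounds,
  with a slice left unmatched to exercise the `unassigned` path.
* **Descriptors** are class-conditional: molecular weight log-normal
  around medians 330.2 Da (drugs) and 238.7 Da (metabolites), logP
  normal around 1.43 vs −0.3, and analogous anchors for pKa, pI, TPSA
  and ASA, matching reported medians for real drug and metabolite sets.
  Molecules are assembled from ring/chain/heteroatom templates sized to
  the sampled weight (drugs ring-richer and more aromatic, hence lower
  sp³ fractions); graph descriptors are then *computed*, not sampled, so
  they covary with size realistically.
* **Identity.** Every molecular graph is unique, and a generation-time
  check guarantees no two molecules of different classes are mutually
  matchable under the ±1 Da / Tanimoto > 0.95 rule (offenders are
  perturbed by added substituents). Library SDFs contain exactly the
  drug-class + overlapping molecules (drug library) and metabolite-class
  + overlapping molecules (metabolite libraries) under library ids, so
  class recovery has a single correct answer.
* **Events.** The non-redundant pocket count is `1 + Poisson(exp(β₀ +
  β·z))` over standardized descriptors, default β₀ = −0.25 with a
  negative molecular-weight and positive rotatable-bond effect; at these
  defaults about one compound in five ends up promiscuous, matching the
  fraction seen in the real corpus (observed 19.6–21% across seeds).
  Every compound has at least one event, as in an analysis conditioned
  on binding.
* **Structures.** A pool of 150 unrelated sequences (length 60, natural
  amino-acid frequencies; a rejection step regenerates any pair reaching
  28% identity so that distinct pool proteins can never cluster) hosts
  the events: each event gets a chain whose planted pocket residues lie
  at heavy-atom distances 3.5–4.6 Å from the ligand and all other
  residues beyond 6 Å, with ~10 chains per PDB file offset 40 Å apart.
  With probability 0.3 an event is deposited twice on the same protein
  with the same residue set — redundancy the pipeline must collapse.
  Pocket sizes are 4 + Poisson(4) residues. EC classes attach to pool
  proteins from a configurable background (26/21/24/8/5/5% for EC 1–6,
  11% unannotated).
* **Statistical fixtures.** For stages that do not need geometry,
  `generate_binding_events()` also emits per-compound EC label draws
  (Dirichlet-categorical with concentration `ec_alpha`) and pocket
  composition matrices (Dirichlet-multinomial around a compound base
  composition, with per-compound concentration log-normal around
  `pocket_conc = 30`; the recorded dispersion `1/conc` is the ground
  truth against which PV's rank behavior is tested).
  `generate_pathway_annotations()` plants configurable odds-ratio
  enrichments (default: one OR = 3 term among promiscuous compounds at
  baseline membership 0.12).

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: physically realistic protein
folds or chemistry (residues are Cα-only points, molecules need not be
synthesizable), homology *between* distinct pool proteins (target
clustering across families is exercised in dedicated unit tests
instead), pocket compositions conserved around true binding motifs
(pockets are random sequence subsets, which makes synthetic PV values
run much larger than the sub-1 values typical of real pocket sets),
correlated descriptor blocks as produced by real chemistry engines, and
any database-specific identifier semantics. Green tests certify the
*machinery* — geometry, clustering, statistics, bookkeeping — not the
biological effect sizes of any particular corpus.

## Numerical choices and degenerate inputs

* Distance boundaries are inclusive with a 1e-9 Å epsilon.
* Bray-Curtis on two all-zero vectors is undefined and raised as an
  error rather than silently 0.
* Complete-linkage cutting keeps clusters with merge height ≤ 0.3
  (`cutree(h = cutoff)`); with tied merge heights the partition follows
  `hclust`'s deterministic merge order.
* Identical fingerprints of two empty bit sets score 1 with a warning.
* Fisher p-values are clamped to 1 before BH (the exact test can return
  1 + 2e-16 in floating point).
* Equal-count binning errors when asked for more bins than distinct
  values; ties merge edges with a warning rather than emitting empty
  bins.
* All tables are written as plain TSV with fixed column order, and every
  random draw flows from a single configuration seed, so reruns are
  byte-identical.

## Problem sizes

The default generator emits 500 compounds; the shipped end-to-end check
runs that size with the event-rate intercept raised to β₀ = 0.61,
producing roughly 2,000 deposited binding events across ~250 structure
files, and completes in a few minutes on one CPU. Unit-level oracle
comparisons use 100–1,000 random instances per property. These sizes
were chosen to exercise every code path at meaningful statistical
resolution while keeping a full run interactive.

## Known limitations

* The identity-based target clustering approximates score-based
  Blastclust; cluster membership can differ near the 30% boundary.
* The path fingerprint is not bit-compatible with CDK/ECFP schemes;
  matching thresholds tuned for those fingerprints should be revalidated
  if a user swaps schemes.
* Ligand-instance weights omit unmodeled hydrogens; the 30 Da lower
  admission bound therefore acts on heavy-atom weight for structures
  (library matching uses full weights).
* The propensity standard errors ignore sampling noise in the
  selective denominator; coverage of `P ± 2se` is slightly below
  nominal, which the calibration tests quantify.
* EC annotations are taken from a per-chain table supplied by the user
  (or generator); no attempt is made to parse enzyme annotations out of
  structure files.
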