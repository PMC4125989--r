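---
title: "Screening low-coverage ancient DNA with adnakit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening low-coverage ancient DNA with adnakit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adnakit)
```

adnakit implements the screening analyses routinely applied to shallow
shotgun sequencing of historical or ancient skeletal samples: is the DNA
authentically old (terminal deamination), what was the individual's genetic
sex (X/Y read counts), where do the few thousand recoverable SNPs place the
individual among modern reference populations (pseudo-haploid calls,
Procrustes-anchored PCA, admixture proportions), and which mitochondrial
lineage is suggested by the covered diagnostic positions. This vignette
documents the models behind each stage, the defaults and why they were
chosen, and what the bundled synthetic-data generator does and does not
emulate.

## The synthetic-data generator

Every stage of the package is testable offline because the generator
produces inputs with known ground truth.

**Population structure.** Reference panels follow the Balding–Nichols
model: each SNP draws an ancestral frequency $p_j$ uniformly from
(0.05, 0.95); population $k$ with divergence $F_k$ draws its frequency from
$\mathrm{Beta}\!\left(p_j\tfrac{1-F_k}{F_k},\,(1-p_j)\tfrac{1-F_k}{F_k}\right)$,
so that $\mathrm{Var}(f_{kj}) = F_k\,p_j(1-p_j)$; $F_k = 0$ degenerates to
$f_{kj}=p_j$. Reference genotypes are binomial draws of two alleles;
an "ancient" individual with admixture vector $q$ draws its genotype from
$\mathrm{Bin}(2, \sum_k q_k f_{kj})$. Sites are unlinked by construction
(1 kb apart, one SNP per fragment), which is what makes the LD-pruning null
test meaningful.

**Fragments.** Read counts per SNP are Poisson with the configured mean
depth (default 1, the single-read regime the pseudo-haploid caller is built
for). Each fragment is assigned to the endogenous genotype with probability
$1 - c$ (contamination $c$, default 0) and otherwise to a single diploid
contaminant individual drawn from a designated panel population. Fragment
lengths are shifted-geometric (minimum 30, mean 60 bases — the typical
ancient-DNA scale). Terminal cytosine deamination converts C→T reading from
the 5′ end and G→A from the 3′ end with probability
$D(z) = b + d_{\max}(1-\lambda)^{z-1}$ at offset $z$
(defaults $d_{\max}=0.3$, $\lambda=0.3$, $b=0.01$, qualitatively matching
published single-strand-library damage curves); only endogenous molecules
are damaged — contaminating modern DNA is not. An independent uniform base
error (default 0.002) applies everywhere, and base qualities are set
consistently with it. Because the two terminal curves are identical, damage
can be applied in genomic orientation for either strand; fragments are
stored in genomic orientation and re-oriented by the profiling code.

The aligned-reference string of a simulated fragment masks the SNP position
itself as `N`. Damage profiling conventionally excludes known polymorphic
sites, so a carried alternate allele must not be countable as a mismatch;
`N` reference bases are ignored by the profiler, the PMD score and the
caller's reference-consistency check.

**Sex reads.** An XY individual yields Y-chromosome reads with expectation
`xy_ry` of the sex-chromosome total; an XX individual yields Y reads only
via the mismapping rate (default 0.002). The default `xy_ry = 0.11` sits
inside the published male band (above 0.075) and was chosen analytically so
that a strict confidence-interval assignment is reliable from roughly 2,000
sex-chromosome reads: an XY call requires
$R_y - 1.96\,\mathrm{SE} > 0.075$, i.e. $R_y \gtrsim 0.0875$ at $n=2000$,
and $0.11 - 2.33\sqrt{0.11\cdot 0.89/2000} \approx 0.094 > 0.0875$. A
baseline of 0.09 — closer to the band edge — would leave roughly a third
of genuine XY replicates unassignable at that depth, which would defeat the
generator's purpose of exercising the thresholds.

**What the generator does not emulate.** Unlinked sites only (no
recombination or real LD), no indels, no paired-end reads, no
platform-specific error profiles, no UDG treatment, and a single
contaminant individual rather than a contaminant population mixture.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every artefact of real
libraries.

## Damage profiling and PMD filtering

`mismatch_profile()` counts, in read orientation, C→T mismatches by 5′
offset and G→A by 3′ offset (reverse-strand fragments are
complement-oriented first), with zero-opportunity offsets reported as 0.
The summary `deaminated_fraction` is defined as the share of fragments with
at least one terminal (offset ≤ 5) C→T/G→A mismatch; the literature phrase
"fraction of reads containing cytosine deamination" has no standard
operational definition, so this one is fixed and documented.
`fit_damage_model()` recovers $(d_{\max}, \lambda, b)$ by weighted least
squares on the pooled 5′/3′ curves.

The per-fragment PMD score is a log-likelihood ratio between a damage model
and a pure-error null, accumulated over positions whose strand-oriented
reference base is C within the first 25 bases (or G within the last 25;
beyond that $D(z)\approx b$, so a bounded window loses essentially
nothing). With per-base error $\varepsilon = \max(10^{-q/10}/3,\,10^{-4})$
(the floor avoids infinite ratios at extreme base qualities):
an observed T over reference C at offset $z$ contributes
$\ln\frac{D(z) + (1-D(z))\varepsilon}{\varepsilon}$, an observed matching C
contributes $\ln(1 - D(z))$, and anything else contributes 0. Filtering at
score ≥ 3 retains reads with clear damage evidence; −2 approximates
"unfiltered". Because only endogenous molecules are damaged, filtering a
50/50 ancient/modern mixture at 3 strongly enriches endogenous molecules;
the price is fewer reads and a reference-allele bias in downstream calls
(damaged C alleles become uncallable), which is why the pipeline reports
the PMD-restricted sex estimate and projection as a *replicate* for
concordance checking rather than as the primary result.

`summarize_alignment()` is the endogenous-DNA estimate used in screening
tables: $100\,m/t$ rounded to two decimals, displayed with trailing zeros
stripped (`format_percent()`), so 7.60 prints as "7.6".

## Sex estimation

`estimate_sex()` computes $R_y = n_Y/(n_X+n_Y)$ with the normal
approximation $\mathrm{SE} = \sqrt{R_y(1-R_y)/n}$ and a 95% interval
(an exact binomial interval is available). Assignment is conservative:
XX only when the whole interval lies below 0.016, XY only when it lies
entirely above 0.075, `insufficient` below 100 sex-chromosome reads,
otherwise `indeterminate`. Published descriptions of these bands sometimes
print the direction sentence swapped; the implementation follows the
method's actual orientation (few Y reads ⇒ female). Pseudoautosomal
regions are assumed excluded by the aligner; `count_sex_reads()` accepts an
interval mask as a hook.

## Pseudo-haploid calling and panel preparation

At each panel SNP the caller piles up bases passing base quality ≥ 15 and
mapping quality ≥ 30 (duplicates — same chromosome, position, strand and
length — are collapsed first), picks one base uniformly at random, and
emits 0 (reference), 2 (alternate) or missing. Sampling a single allele is
unbiased for the individual's allele dose at covered sites, which is the
property the projection and admixture stages rely on. Reference panels are
randomly homozygized (`homozygize_panel()`) so that reference and ancient
individuals carry the same 0/2 representation, avoiding an artificial
diploid/haploid contrast on the leading PCs.

Transition SNPs ({C,T} and {G,A} allele pairs) are excluded outright —
post-mortem deamination fabricates exactly those genotypes. Masking applies
at the SNP level regardless of strand, the conservative choice. LD pruning
slides a 50-SNP window in steps of 5 and, while any pair inside the window
exceeds $r^2 = 0.2$, drops the later SNP of the worst pair; the window and
step are conventional values (only the threshold is dictated by the
workflow being reproduced). Allele harmonization during merging resolves
exact matches, ref/alt swaps (dosage flipped), strand complements and
complemented swaps, in that precedence order; strand-ambiguous SNPs (A/T,
C/G) are flagged in the QC report rather than silently resolved, since for
them the direct and complemented interpretations cannot be distinguished.

## Reference PCA and Procrustes projection

`reference_pca()` standardizes each SNP column by the posterior-mean
frequency $\hat p = (1+\sum g)/(2+2n)$ — centering by $2\hat p$, scaling by
$\sqrt{\hat p(1-\hat p)}$, mean-imputing missing entries, dropping
monomorphic columns — and takes coordinates from the SVD. This is the
standard genotype-PCA normalization; the pseudocount keeps scales finite at
frequency extremes at the cost of columns being centered only approximately.

A sparse ancient sample cannot be dropped into the reference PCA directly:
its covered-site subset changes the geometry. `project_ancient()` restricts
the panel to the sample's non-missing sites, rebuilds the PC space on that
subset (reusing the reference standardization), *projects* the ancient 0/2
row onto those axes, and maps the result into the reference frame with a
Procrustes transform fitted on the reference individuals only. Projecting,
rather than including the ancient row in the SVD, is deliberate: a
pseudo-haploid row has inflated variance and would tilt the axes toward its
own noise, and inclusion would also perturb the column standardization —
with the consequence that even a full-coverage exact copy of a panel
individual would not land on its twin. Under projection semantics the
exact-copy identity holds to machine precision, which the tests assert.
The shrinkage-corrected least-squares projection of smartpca (lsqproject)
is intentionally not implemented.

`procrustes_fit()` solves the similarity-transform least-squares problem in
closed form via the SVD of the centered cross-covariance, with reflections
permitted (an arbitrary sign flip of a PC axis is meaningless, so the fit
must absorb it — a property-based test drives random transforms, half of
them reflections, through the solver). The similarity statistic is
$\rho = \sqrt{1 - \mathrm{residual}/\mathrm{total\ target\ variance}}$.
Anchors are always reference individuals; ancient points never influence
the fit.

## Admixture EM, cross-validation, run alignment

`admixture_em()` maximizes the binomial likelihood
$L = \sum_{ij} g_{ij}\ln p_{ij} + (2-g_{ij})\ln(1-p_{ij})$,
$p_{ij} = \sum_k q_{ik} f_{kj}$, with the classical EM updates (the same
model as the ADMIXTURE program, which uses quasi-Newton block relaxation
instead; EM is slower but provably monotone, and the monotonicity is
asserted at every iteration in the tests). Initialization is seeded:
Q rows Dirichlet(1,…,1), F uniform on (0.05, 0.95). Iteration stops when
the log-likelihood gain falls below 1e-4 or at 2,000 iterations. Two
numerical details matter: cluster frequencies are clipped to
[1e-6, 1−1e-6] after each M-step so the likelihood stays finite, and Q
rows are renormalized explicitly — the update preserves the simplex only
in exact arithmetic, and rounding departures are otherwise amplified
exponentially across iterations, eventually breaking monotonicity. The
E-step uses the raw mixture probability in the posterior weights and
clamps it only inside the logarithms, for the same reason. The inner loop
is compiled (RcppArmadillo), as is usual for this class of model.

`cv_error()` masks a random fold of observed genotype *cells* (not
individuals), refits on the remainder, and scores masked cells by binomial
deviance between the held-out dosage and $2\hat p$, averaged over 5 folds.
CV fits run with a looser convergence budget (tol 1e-2, 150 iterations)
than estimation fits: model choice needs the deviance *ranking* across k,
which stabilizes long before the parameters converge, and a
fully-converged sweep over k and folds would cost roughly five times more
compute for the same selected k.

`align_runs()` aligns repeated seeded runs CLUMPP-style: exhaustive search
over label permutations (k ≤ 8, the fullSearch strategy) maximizing
$G = 1 - \lVert Q_{\mathrm{ref}} - Q_{\mathrm{perm}}\rVert_F / \sqrt{2n}$,
greedy column matching beyond that; aligned runs are averaged element-wise.
The stored permutation is the one applied to a run's columns to match the
reference labelling.

## Mitochondrial haplogroups

Mitochondrial fragments are length-filtered (≥ 25 bases before trimming)
and trimmed 3 bases at each end — discarding the positions where
deamination is concentrated — with start coordinates adjusted around the
16,569-base circle. `call_mt_variants()` takes the majority base per
covered position (base quality ≥ 15; ties break toward the reference, then
alphabetically) and emits differences from the reference with depth and
agreement. `assign_haplogroup()` scores every tree node by the Kulczynski
measure over its path-defining mutations restricted to covered positions,
$\tfrac12(\mathrm{found}/\mathrm{expected} +
\mathrm{found}/\mathrm{observed})$, which is deliberately coverage-aware:
sparse data should not penalize a node for mutations that were never
observable. Ties break toward the deeper node, then lexicographically;
with no covered positions the root is returned flagged uninformative.

The bundled tree (`mt_toy_tree()`) is a ~25-node fabricated stand-in
covering the African L0–L3 macrohaplogroup topology (including L1b1, L2b1
and L3'4'6); its defining positions and bases are synthetic, as is the
bundled circular reference (`mt_reference()` — same length and topology as
the standard mitochondrial coordinate system, but generated from a fixed
seed, since the real reference sequence is not shipped). User trees load
from a simple TSV (`read_tree()`), and a real reference can be supplied as
FASTA. Insertions, deletions and heteroplasmy are out of model.

## The pipeline and its defaults

`run_pipeline()` chains the stages per sample — damage profile, sex
estimate, pseudo-haploid calls on the transition-masked LD-pruned panel,
Procrustes projection, admixture over aligned replicate runs,
mitochondrial haplogroup — and, when at least 100 reads survive PMD
filtering at score 3, repeats the sex estimate and projection on the
damage-restricted reads as a contamination check. A failing sample is
reported with a note and skipped; the batch never aborts. One master seed
fans out into per-stage seeds through a documented integer hash
(`derive_seed()`), so any stage can be re-run in isolation and the whole
report is bit-reproducible. Defaults: base quality ≥ 15, mapping quality
≥ 30, $r^2$ 0.2, PMD 3 / −2, Ry bands 0.016 / 0.075, k = 3 with 10
aligned replicates (`select_k = TRUE` switches to cross-validated choice
over `k_range`). Genome coverage is reported only when a genome size is
supplied, as mapped reads × mean fragment length / genome size.

## Problem sizes used in the checks

The bundled verification suite runs entirely on generator output, at sizes
chosen to make each property measurable while keeping the whole suite
desk-scale: damage recovery on 100,000 fragments; sex assignment on 100 XX
and 100 XY replicates of 2,000 reads; Procrustes exactness on 1,000 random
configurations; projection behaviour over 100 replicates of a
two-population panel (FST 0.1, 200 reference individuals, ~1,000 covered
transversion SNPs); admixture recovery and cross-validated model choice on
a three-population panel (FST 0.1, 201 individuals × 5,000 SNPs, 10 CV
replicates over k = 1..5); PMD enrichment on a half-contaminated sample of
~7,500 fragments; and haplogroup recovery over 100 replicates at mean
depth 2. Statistical thresholds in those checks (e.g. "≥ 90 of 100
replicates") are properties of the stated simulation conditions, not
tunable knobs.

## Known limitations

* Pseudo-haploid calls from damage-filtered reads carry a reference-allele
  bias (deaminated alternate C alleles become uncallable); the
  PMD-restricted projection is therefore a concordance check, not an
  unbiased estimate.
* The binomial admixture likelihood treats a pseudo-haploid 0/2 call as two
  observed alleles; this halves the nominal information per site without
  biasing the point estimate, so reported Q vectors for ancient samples are
  noisier than the reference rows.
* The CV deviance is computed on masked cells predicted from parameters fit
  on the same individuals; it selects k for the panel at hand and is not an
  out-of-sample ancestry error.
* The toy haplogroup tree supports method verification only; real lineage
  assignment requires a real defining-mutation tree and reference.
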