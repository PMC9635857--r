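---
title: "Identifying linker histones and testing selection at their genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying linker histones and testing selection at their genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkerhist)
```

# Overview

`linkerhist` answers two questions in sequence. First, *which of the
GH1-domain proteins in a proteome are true linker histones (H1)?* The GH1
winged-helix domain (Pfam PF00538) also occurs in GH1-Myb and GH1-HMGA
chromatin proteins, so domain presence alone is not diagnostic; the package
encodes the structural criteria that separate the groups. Second, *is there
evidence of non-neutral evolution at the corresponding genes?* — answered
with per-locus diversity statistics and a maximum-likelihood HKA test.

# The H1 decision rule

A protein is called `H1` only if **all** of the following hold (any failure
gives `other`; Myb or AT-hook architectures keep their own labels):

1. **Architecture** (`typical_H1_candidate`): exactly one GH1 domain, no
   Myb domain, fewer than two AT-hooks. Grouping precedence is Myb →
   AT-hooks (≥ 2) → multiple GH1 → typical. The AT-hook pattern is the
   canonical `R-G-R-P` core with at least two additional K/R within the
   four residues flanking either side (combined), which matches the
   `KRPRGRPKK` consensus of HMGA proteins while rejecting bare `RGRP`
   matches in a neutral context.
2. **Binding sites**: at least `binding_min` (default 8) of the ten basic
   sites conserved in the GH1 domain. The shipped site table
   (`h1_binding_sites()`) uses GH1-domain coordinates 2, 17, 19, 29, 43,
   44, 51, 52, 61, 67 (His2 5′ of helix I; two sites between helices I and
   II; one in helix II; four in helix III; two in the β-hairpin).
   Conservation is *class-based*: a site counts only if the observed
   residue is K, R or H (His must count as basic because His2 is itself a
   site); a gap never counts, and chemically similar but non-basic
   replacements (e.g. Lys → Asn) do not count. Positions are configurable
   because numbering conventions differ (users of the avian GH5 frame can
   supply 25, 40, 42, 47, 52, 69, 73, 85, 94, 97 instead).
3. **CTD lysine content** ≥ `ctd_lys_min_pct` (default 20%).
4. **CTD net charge** ≥ `ctd_net_charge_min` (default +20), counting
   (#K + #R) − (#D + #E).
5. **Charge evenness**: the minimum 20-aa moving window sum of per-residue
   charges along the CTD, starting at the GH1 boundary and sliding outward,
   is ≥ `min_window_sum_min` (default +1) — i.e. every window is positive.

The thresholds are deliberate midpoints: observed true H1s have CTD lysine
≈ 29–31%, CTD charges +20 to +53 and 10/10 sites, while the Myb/HMGA groups
sit at ≤ ~11% lysine and ≤ 6 sites. Defaults of 20% / +20 / +1 / 8 leave
wide margins on both sides and are fully configurable
(`h1_criteria()`). Raising any threshold can only remove H1 verdicts, never
add one (tested as a monotonicity property).

Proteins with two GH1 domains and no hooks are reported `multi_GH1`, not
forced into the HMGA group, even though whole-protein trees may place such
proteins there; tree-based regrouping is left to the user (the package
builds neighbor-joining trees for display, `nj_tree()`).

# Physicochemical panel conventions

- **Molecular weight**: sum of average residue masses plus one water, in
  kDa. `X` residues carry no mass (warning).
- **Theoretical pI**: bisection on pH ∈ [0, 14] of the
  Henderson–Hasselbalch titration charge (D, E, C, Y negative; K, R, H
  positive; both termini), Bjellqvist pKa values, tolerance 10⁻⁴ on the
  charge. The charge is strictly decreasing in pH, so bisection always
  converges. We use a *single* N-terminal pKa (7.5) rather than ExPASy's
  residue-specific variants so that the result is a pure function of
  amino-acid composition — a documented deviation that changes pI by at
  most a few hundredths of a unit.
- **Integer net charge** counts only K/R against D/E. Histidine is excluded
  (mostly neutral at physiological pH) and the termini belong to the
  titration model, not to this integer count. This convention reproduces
  the published integer panel values (e.g. a GH1 domain with equal counts
  of basic and acidic residues scoring exactly 0); whether the original
  tabulation included His or termini is not stated anywhere, so the
  convention is a documented assumption.
- **Rounding**: percentages half-up to 1 decimal, MW/pI to 2 decimals,
  densities to 1 decimal — matching the printed tables. (Base `round()`
  rounds half to even; `round_half_up()` is used instead.)
- **Moving windows**: windows shorter than 20 aa occur only when the whole
  tail is shorter than 20 (one truncated window); there are no partial
  windows at the distal end, because the profile is defined as full
  windows starting from the GH1 boundary.
- **Region accounting**: NTD ends exactly one residue before the first GH1
  domain, the CTD starts one after the last; inter-GH1 linkers of
  multi-domain proteins belong to neither tail but are included in the
  totals, so region lengths always sum to the protein length. This
  linker-excluded convention reproduces published per-region lengths for
  two-domain proteins whose tabulated regions do not sum to the protein
  length.

# Diversity statistics

Gap handling is **complete deletion**: any column containing a gap in any
haplotype is excluded from S, π, and the per-site denominators (the default
behavior of the standard desktop software for these statistics, chosen for
reproducibility of a single documented convention).

- π = Σ pairwise differences / (C(n,2) × sites); for n = 2 it equals
  θ<sub>w</sub> exactly.
- Site classes follow Nei–Gojobori (1986): each coding position contributes
  a fractional synonymous site count f = (synonymous one-base changes)/3,
  with changes to stop codons counted nonsynonymous; per codon the
  fractions sum to 3. Pairwise differences in codons differing at more than
  one position are averaged over all orderings of the changes (equal
  pathway weighting). "Silent" pools noncoding positions with synonymous
  sites. This is an approximation to the (unspecified) counting of the
  original desktop tool, documented as such.
- Tajima's D uses the standard a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂ constants; it
  is reported `NA` (never 0) when S = 0 or the variance term vanishes, and
  prints as `NA` in CLI output.
- A site class with zero sites reports π = 0 with an `empty_class` flag,
  matching tables that print 0.0000 for classes with no sites.

# The ML-HKA model

Counts at L loci are modeled as independent Poissons: S_i with mean
κ_i θ_i a(n_i) (a(n) = Σ 1/i, the Watterson factor) and D_i with mean
θ_i (T + 1), divergence to a single outgroup sequence. T is in units of 2N
generations; any additive constant in the divergence expectation is
absorbed by the free parameter T, so inference about the selection
parameter k does not depend on that convention. The neutral model fixes
k = 1; the selection model frees k at one focal locus. The LRT
2(lnL_sel − lnL_neu), clamped at zero, is referred to χ²(1).

Numerics: optimization is multi-start BFGS in log-parameter space (5
deterministic starts by default), with starts built from the closed-form
profile MLE θ̂_i(T) = (S_i + D_i)/(κ_i a_i + T + 1), and the selection fit
warm-started at the neutral optimum — which guarantees
lnL_sel ≥ lnL_neu (proper nesting) by construction. Convergence tolerance
is 10⁻¹² relative in the objective. A locus with S = D = 0 drives its θ̂ to
the zero boundary and is flagged rather than failing. The large simulation
batteries in the test suite use 2 starts per fit to stay inside the time
budget; spot checks show identical optima.

# What the generators emulate — and what they do not

All generators are pure functions of their parameters and a seed (a private
RNG stream; global RNG state is untouched), and their outputs always
satisfy the consuming modules' invariants.

- `gen_proteome()` plants the *contrasts* the classifier keys on: H1-like
  proteins get NTD 20–70 aa, all ten basic sites, and a CTD (77–170 aa)
  with ~30% lysine laid down at a fixed stride with jitter — which
  *guarantees* every 20-aa window is positive, so classifier tests are
  deterministic; Myb-like proteins get a Myb hit, 6/10 sites and an acidic
  CTD; HMGA-like proteins get 3–6 planted `KRPRGRPKK` hooks; decoys keep
  ≤ 3 sites. Background alphabets contain no arginine, so no spurious
  AT-hook cores can arise. GH1 domains are 67–71 aa (not the observed
  63–71) because all ten site positions — the last at 67 — must exist in
  every domain: the generator aligns domains by right-padding, whereas a
  real 63-aa domain scores 10/10 only through alignment gaps, which the
  generator does not simulate. Consequently a green classifier test
  establishes correct *rule logic and thresholds*, not robustness to real
  alignment noise, compositional drift between clades, or HMMER boundary
  error.
- `gen_coalescent()` is a standard neutral Kingman coalescent with
  infinite-sites mutation mapped into L positions (collisions re-drawn, so
  E[S] stays unbiased for L ≫ S; an error is raised if more mutations than
  positions are requested). No recombination, migration or demography, so
  calibration checks (mean pairwise differences = θ at n = 2; mean
  Tajima's D ≈ 0) validate the estimators under the strict neutral model
  only.
- `gen_hka_counts()` draws from exactly the likelihood `hka_fit()`
  maximizes; recovery and type-I-error checks therefore test the optimizer
  and the χ² calibration, not model misspecification (linked sites,
  non-equilibrium demography).
- `gen_coding_population()` verifies every planted SNP's effect against the
  genetic code and places indels only in the noncoding flanks; the
  haplotype alignment carries the SNPs while indels live in the variant
  table only (alignments stay rectangular).

# Variant nomenclature

Placement of a query into the named H1 variant subclades (H1.0–H1.4) is a
deterministic surrogate for maximum-likelihood tree inference (which the
original workflow delegates to external software, out of scope here): the
query joins the variant whose labeled references have the smallest mean
p-distance (pairwise deletion) to it. The margin between the best and
runner-up group means is reported, and a margin below ε (default 10⁻⁹, i.e.
exact ties) flags the assignment `ambiguous`. Mean linkage was chosen over
single linkage to damp the influence of one unusually close reference.

# Known limitations

- No profile-HMM scanning: domain hits are inputs (TSV or HMMER domtblout,
  envelope coordinates), never computed.
- No ML tree inference, bootstrap supports, or model selection; NJ only.
- The VCF reader is a deliberate minimal subset (CHROM/POS/REF/ALT plus GT
  or AC/AN; missing genotypes are absent haplotypes, never reference); no
  phasing, no structural variants.
- Reverse-strand coding annotations are rejected rather than
  reverse-complemented.
- The binding-site frame ships one numbering; if a different reference
  alignment is used, positions must be supplied to `build_site_map()`.
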