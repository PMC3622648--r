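---
title: "Joint genotyping of tumor-normal-parent quartets: model and methods"
author: "quartetcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint genotyping of tumor-normal-parent quartets: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetcall)
```

## The inference problem

A *quartet* is a set of four related sequencing samples: a patient's
tumor and matched normal tissue, plus DNA from both parents. Genotyping
the four genomes jointly — rather than one sample at a time — lets the
known relationships constrain the calls: parental genotypes make de novo
germline mutations distinguishable from inherited variants, the normal
sample anchors somatic mutation calls in the tumor, and, conversely,
reads from the relatives "triangulate" the normal genome so that its
genotype is resolved more reliably at marginal coverage.

`quartetcall` implements a Bayesian model over six hidden diploid
genotypes at each locus: the parental genotypes $g_F, g_M$, the parental
germlines after de novo mutation $g'_F, g'_M$, the child's normal
genotype $g_N$ (by Mendelian inheritance from $g'_F, g'_M$), and the
tumor genotype $g_T$ (by somatic mutation of $g_N$). Genotypes are
unordered pairs over $\{A,C,G,T\}$ — exactly $G = 10$ states; phase is
never modeled. The observed data at a locus are, per sample, a multiset
of base calls $z_k$ with Phred-scaled error probabilities
$\varepsilon_k = 10^{-q_k/10}$.

## Model components

**Parental genotype priors.** Allele frequencies come from a
Jukes-Cantor divergence $v$ from the reference assembly:
$\pi[\mathrm{ref}] = 1 - v$, $\pi[x] = v/3$ otherwise. Diploid priors
adjust Hardy-Weinberg by a heterozygosity parameter $\gamma \le 1$,
numerically analogous to the inbreeding $F$-statistic:
$$\phi(xx) = \pi[x]^2 + \gamma\,\pi[x](1-\pi[x]), \qquad
  \phi(xy) = 2(1-\gamma)\,\pi[x]\pi[y].$$
The implied haploid frequencies equal $\pi$ at any $\gamma$. Negative
$\gamma$ (heterozygote excess) is accepted for fixed-parameter use
whenever all $\phi \ge 0$; the EM estimator constrains
$\hat\gamma \in [0,1)$ because the flip-machine decomposition used in
the M-step (below) only realizes the prior for non-negative $\gamma$.

**Mutation and inheritance.** Germline and somatic mutations follow
single-parameter Jukes-Cantor kernels acting independently on each
allele ($\nu_F$, $\nu_M$ for the parental germlines, $\nu_T$ for the
tumor lineage). Mendelian transmission $\chi(g'_F, g'_M \to g_N)$ takes
values in $\{0, \tfrac14, \tfrac12, 1\}$. Germline mutation and
inheritance are folded into one precomputed kernel
$\chi'(g_F, g_M \to g_N) = \sum_{g'_F, g'_M}
 \nu^{(F)}(g_F{\to}g'_F)\, \nu^{(M)}(g_M{\to}g'_M)\,
 \chi(g'_F, g'_M \to g_N)$,
so the per-locus likelihood costs $O(G^3)$ instead of $O(G^6)$.
The paternal and maternal rates are tied by default
(`tie_germline = TRUE`); separate estimation is available since the
model writes them separately.

**Sequencing errors and tumor impurity.** Errors are unbiased: a read
reports the sampled allele with probability $1-\varepsilon$ and each
other allele with probability $\varepsilon/3$. Reads from the tumor
sample draw from the tumor genotype with probability $\omega$ (the
purity) and from the contaminating normal genotype with $1-\omega$:
$\rho[y] = (1-\omega)\rho_N[y] + \omega\rho_T[y]$. When $g_N = g_T$ the
purity is immaterial.

**Read likelihoods and the partial-likelihood store.** The read
likelihood $L(\rho) = \prod_k \sum_y p_k(y)\rho[y]$ factorizes over
called alleles: only the called allele's frequency $\beta = \rho[z]$
enters each factor $f(\beta, \varepsilon) = \beta +
\varepsilon(1-4\beta)/3$. Across all pure genotypes and all seven
divergent normal-tumor patterns, only nine $\beta$ values ever occur:
$0, \tfrac12, 1$ and six purity-dependent values
($\tfrac12 \pm \tfrac\omega2$, $1-\omega$, $\omega$, $\tfrac\omega2$,
$1-\tfrac\omega2$). Storing, per called allele, the normalized
subproducts $C', H'$ and the six $T'_\beta$ plus one scale value $E =
\prod_k \varepsilon_k/3$ — $1 + 8m$ numbers for $m$ called alleles —
makes every genotype likelihood a product of stored values, independent
of coverage, and lets EM iterate without re-reading the pileup.

*Numerical choices.* All subproducts, the scale, and every dynamic
programming table are kept in log space ($E$ alone underflows past
roughly 150 reads in double precision); per-locus max-subtraction
stabilizes the $10\times10$ and $10\times100$ tables. Calls are
accumulated in a canonical sort order so that permuting the input never
changes any likelihood, bit for bit. A quality of 0 maps to
$\varepsilon = 1$ (the Phred definition, kept inside the model's
$0 < \varepsilon \le 1$ range); qualities are capped at 93, the Sanger
encoding range. MAP ties break toward the genotype containing the
reference allele, then canonical order — deterministic output is a
contract of the implementation regardless of any internal parallelism,
which is why the CLI accepts and ignores a `--threads` value.

**Recurrent call sets.** Low-coverage pileup columns repeat; sorted
run-length encoding of (allele, quality, count) gives a canonical key
under which identical multisets share one store. The key is used only
while compact — at most 64 calls and a 32-byte encoding. These two
bounds are this package's defaults (chosen to cover the low-coverage
exome regime where repetition actually occurs); no reference values
exist for them.

## Posteriors, mutation probabilities, calls

Per locus the engine produces the total likelihood, marginal genotype
posteriors for all four samples, the joint $(g_N, g_T)$ posterior, and
the MAP joint assignment. The somatic posterior is the off-diagonal
$(g_N, g_T)$ mass. The de novo posterior is defined on the *unmutated*
trio: the posterior mass of assignments with
$\chi(g_F, g_M \to g_N) = 0$, i.e. the child's normal genotype is
Mendelian-impossible given the parents as sequenced. An alternative
definition — posterior mass of germline-kernel changes
$g'_F \ne g_F$ or $g'_M \ne g_M$ — integrates over events invisible in
the trio genotypes; we expose the trio-inconsistency quantity because it
matches how de novo candidates are classified from called genotypes.

VCF output follows v4.1: QUAL is the Phred-scaled posterior of the MAP
joint assignment, GQ the per-sample genotype quality. Genotype calls
introduce ambiguity greedily for specificity: a full call $x/y$ is
emitted only at GQ $\ge$ `min_gq`; otherwise the best half call $x/.$
(posterior of all genotypes containing $x$) is tried; otherwise $./.$
By default a record is emitted when its QUAL passes the threshold and
some emitted genotype is non-reference, or when the somatic or de novo
posterior exceeds 0.5 — an emission rule of this package (no reference
semantics exist); `--emit-all` disables it.

## Parameter estimation

All parameters are fitted by EM. With stores cached, one E-step
aggregates across loci: expected (source, target) genotype-pair
posteriors for the three mutation kernels, and reference-stratified
parental genotype posteriors for the prior.

* **Mutation rates.** $\hat\nu = \sum_j \sum_{g,g'}
  \alpha(g,g')\,p_j(g,g') / (2N)$, where $\alpha(g,g')$ is the expected
  number of allele substitutions between the unordered genotypes. We
  evaluate $\alpha$ exactly under the current kernel (its $\nu \to 0$
  limit is the minimum-pairing count: $\alpha(AA{\to}AC)=1$,
  $\alpha(AA{\to}CC)=2$), which makes the update an exact M-step and
  preserves the EM monotonicity guarantee.
* **Divergence and heterozygosity.** The prior is decomposed through a
  flip machine: a Hardy-Weinberg genotype at divergence $v$ enters, a
  heterozygote is flipped to either homozygote with probability
  $\gamma/2$ each. Treating the machine's input as hidden, the expected
  non-reference allele count yields $\hat v$ and the expected
  heterozygote-to-homozygote flip fraction yields $\hat\gamma$.
* **Tumor purity.** No closed-form M-step exists; $\omega$ is updated by
  golden-section profile-likelihood search on $[0,1]$ (tolerance
  $10^{-3}$), rebuilding the tumor stores per candidate. The update runs
  in an outer loop because it invalidates the stores, and a candidate is
  accepted only when it does not decrease the likelihood — the trace
  stays monotone even where the profile is flat (e.g. no somatic
  divergence anywhere).
* **Quality calibration.** Optionally (`fit_mu = TRUE`; off by default
  because it requires retaining raw calls), the map $\mu: q \mapsto
  \varepsilon$ is re-estimated per quality bin as the mean posterior
  probability that a call differs from its sampled allele, integrating
  the sampled allele over the per-sample posterior allele mixture.
  Bins under 100 calls keep the canonical $10^{-q/10}$; estimates are
  floored at $10^{-6}$. The update is accepted only when the likelihood
  does not decrease.

Rates are floored at $10^{-10}$ so EM cannot lock onto the absorbing
state at exactly 0. The inner loop stops when the relative
log-likelihood change drops below `tol` (default $10^{-6}$) or at
`max_iter`; a decrease beyond $10^{-8}$ absolute raises an error with an
iteration dump.

## The simulator and what passing tests show

`simulate_quartet()` runs the generative model forwards — priors,
germline kernels, Mendelian transmission, tumor kernel, purity mixture,
Phred errors — and returns the hidden truth alongside the pileup, so
every estimator can be tested by parameter recovery. Its defaults are
the conditions the package targets: mean depth 6 per sample (matching
the 4.6-6.6x per-sample exome coverages the method was designed for),
divergence $10^{-3}$, $\gamma = 0.1$, germline rate $10^{-4}$, tumor
rate $10^{-3}$, purity 0.6, and a mixed quality profile
(q = 20/30/40 at weights 0.25/0.5/0.25 — a typical short-read quality
mix). Depth is Poisson per sample per locus; reference alleles are
uniform on one synthetic contig.

The simulator emulates exactly the model's assumptions. Real data
violate several of them: mapping errors and strand bias correlate base
calls within a locus, indels and copy-number changes break the diploid
assumption, mutation rates vary along the genome (e.g. CpG context),
and reported quality scores are miscalibrated in structured ways that
the single map $\mu$ only partially absorbs. Recovery tests therefore
demonstrate internal consistency of model, algorithms and estimators —
not robustness to those violations.

Test and verification scales are chosen to exercise each property at
desk size: factorization oracles run on thousands of random call sets
against direct per-read evaluation; the $O(G^3)$ decomposition is
checked against the naive $10^6$-term summation; EM recovery uses
$10^5$ loci at 30x (where the rare-event counts — a few hundred somatic
loci — make purity and rate estimates meaningful); the triangulation
comparison uses 20,000 loci at 8x normal coverage so that error-count
differences are not decided by one or two binomial flips; the
end-to-end somatic detection check raises the tumor rate to $10^{-2}$
at 10,000 loci to obtain ~200 truth somatic events. The acceptance
script (`scripts/acceptance.R`) re-runs the recovery at 30,000 loci.

## Known limitations

* Autosomal diploid loci only: no sex-chromosome inheritance model, no
  indels, no multi-allelic phased genotypes.
* One substitution parameter per lineage: no transition/transversion
  ratio, composition awareness, or site-specific (database-informed)
  priors — the per-locus allele-prior override hook exists internally
  but ships disabled.
* No read-level effects: mapping quality, strand bias and duplicate
  structure are assumed handled upstream of the pileup projection.
* The tumor is modeled as one clone at purity $\omega$; subclonal
  fractions and copy-number-aware somatic calling are out of scope.
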