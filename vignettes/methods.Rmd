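---
title: "Codon models, site identification and convergence testing in chlorosel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon models, site identification and convergence testing in chlorosel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chlorosel detects positive selection and convergent amino-acid evolution in
multi-gene organellar data sets: per-gene in-frame codon alignments, one
fixed phylogeny, and a gene-to-function table go in; tables of
likelihood-ratio tests, positively selected sites, and convergent
substitutions come out. This vignette documents the models, the estimation
machinery, the numerical choices, and what the synthetic-data generator can
and cannot tell you about real data.

## The substitution models

All codon models share a Goldman–Yang rate matrix over the 61 sense codons
of the standard code. A single-nucleotide change from codon $i$ to codon $j$
has rate

$$q_{ij} = \pi_j \cdot \kappa^{[\mathrm{ts}]} \cdot \omega^{[\mathrm{nonsyn}]},$$

where $\pi_j$ is the F3×4 stationary frequency of the target codon (built
from position-specific nucleotide frequencies, renormalized over sense
codons), $\kappa$ is the transition/transversion rate ratio, and $\omega =
d_N/d_S$ multiplies nonsynonymous changes only. Multi-nucleotide changes are
forbidden. The matrix is reversible, so likelihoods are invariant to root
placement and transition probabilities come from one symmetric
eigendecomposition per $\omega$ value.

The model families are mixtures over site classes, each class a pair of
(background $\omega$, foreground $\omega$):

* **M0** — one class, one $\omega$ everywhere. Used for the per-branch
  $d_N$/$d_S$ decomposition and the dS-based gene filter.
* **branch** — one class, separate $\omega$ for tagged foreground branches.
* **M8 / M8a** — a proportion $p_0$ of sites with $\omega$ from a
  discretized Beta($p$, $q$) (10 equal-probability categories at their
  medians), plus a class at $\omega_s \ge 1$; M8a fixes $\omega_s = 1$.
* **branch-site Model A** — four classes: purifying
  ($0 \le \omega_0 \le 1$) and neutral ($\omega_1 = 1$) everywhere, plus
  two classes that switch to $\omega_2 \ge 1$ on the foreground branch. The
  null fixes $\omega_2 = 1$. Class proportions follow the Model A
  construction $p_{2a} = (1 - p_0 - p_1)\,p_0/(p_0 + p_1)$,
  $p_{2b} = (1 - p_0 - p_1)\,p_1/(p_0 + p_1)$.

### One time scale for all classes

A point that matters for power: all classes share a single time scale.
Because the unnormalized mean rate of the matrix at $\omega$ is
$s(\omega) = B + \omega A$ (with $A$ and $B$ the nonsynonymous and
synonymous rate flows), a site under positive selection evolves *faster*,
not merely with a different synonymous/nonsynonymous composition. Branch
lengths are reported as expected substitutions per codon averaged over the
background classes. Normalizing each class matrix separately — an easy
implementation mistake — makes the branch-site alternative nearly
indistinguishable from its null, because the foreground acceleration is
silently rescaled away; we verified this empirically during development and
adopted the shared-scale convention throughout (fitting, simulation,
likelihood evaluation). The overall normalization is a gauge freedom
absorbed by the branch lengths; internally the optimizer uses a neutral
($\omega = 1$) gauge for multi-class models, which makes the per-class
likelihood contributions independent of the class proportions and therefore
cacheable, and converts to the mixture scale on output.

## Likelihood computation and optimization

Likelihoods are computed by Felsenstein pruning over unique site patterns
with per-node logarithmic scaling (deterministic, not
rescale-on-underflow). The inner loop is a small compiled kernel; outward
"messages" — the likelihood of everything outside a branch's subtree —
remain in R and drive three further computations with the same
machinery: per-branch likelihood curves, marginal ancestral posteriors, and
empirical-Bayes site posteriors.

Each fit alternates two steps until the cycle improvement falls below
`cycle_tol`:

1. bounded quasi-Newton (`nlminb`, numerical gradients) on the substitution
   and mixture parameters with branch lengths fixed;
2. exact sequential coordinate ascent on branch lengths: for branch $e$
   with outward message $B_e$ and inward partial $L_e$, the per-site
   likelihood is $B_e^\top P(t) L_e = \sum_k a_k e^{\lambda_k t}$ after
   projecting on the eigenbasis, so each branch update is a cheap
   one-dimensional Brent search, applied in a root-to-tip traversal that
   keeps all messages current.

Defaults and bounds: $\kappa \in [0.02, 99]$ (start 2), $\omega \in
[10^{-6}, 999]$ with $\omega_s, \omega_2 \ge 1$ exactly, branch lengths in
$[10^{-6}, 50]$, relative likelihood tolerance $10^{-8}$, multi-start over
$\omega \in \{0.5, 1, 2\}$ with ties broken by the lowest start. Boundary
hits (notably $\omega_2 = 999$) are flagged, since they are scientifically
meaningful. Nested pairs are guarded twice: if the alternative search ends
below its null, the null solution (a valid alternative point) is adopted;
and when a branch-site statistic is non-trivial the null is re-polished
from the alternative's parameters, which prevents an under-converged null
from inflating the statistic.

Two deliberate deviations from a plain joint-Newton design: branch lengths
are optimized by the message-based coordinate scheme rather than inside the
quasi-Newton step (same optimum, far fewer likelihood evaluations), and the
cross-polish step above replaces a blanket increase in iteration budgets.

## Inference

Likelihood-ratio statistics $2\Delta\ell$ are referred to $\chi^2$ with
df = 1 for all three comparisons (branch vs one-ratio, M8 vs M8a,
branch-site alternative vs null). The plain $\chi^2$ reference — not the
50:50 boundary mixture — is used; for the branch-site test this is
conservative, which the type-I calibration in the test suite reflects:
under strongly purifying backgrounds with a single short foreground
branch, the null distribution of the branch-site statistic has almost no
mass beyond 1, and the realized false-positive rate can be zero rather
than merely below the nominal 5%. FDR control is Benjamini–Hochberg
within a family, where a family is all genes tested for one comparison type
and one foreground lineage (concatenated data sets form their own family);
this is the narrowest defensible reading and is configurable.

Positively selected sites come from the Bayes empirical Bayes (BEB)
posterior of the foreground classes (2a + 2b), averaging class posteriors
over a parameter grid with uniform priors: $10 \times 10$ points for
$(p_0, p_1)$ through the uniform-triangle map $p_0 = 1-\sqrt{u}$,
$p_1 = v\sqrt{u}$, and 10 values of $\omega_2$ on $(1, 11]$; $\kappa$,
$\omega_0$ and branch lengths stay at their MLEs. The $\omega_2$ grid stops
at 11 rather than the fitting bound 999 because a uniform prior to 999
would put almost all prior mass on implausibly extreme values; the limit is
an argument. Sites are called at posterior probability ≥ 0.95. The naive
empirical-Bayes estimator (posteriors at the MLEs only) is provided as a
cross-check.

## Convergence analysis

For each gene, the cleaned alignment is translated, branch lengths are
re-estimated under an empirical amino-acid model (exchangeabilities ×
gene-specific frequencies with a 0.1 pseudocount), and marginal ancestral
posteriors are computed at every internal node; MAP ties break toward the
alphabetically first residue. For a species pair (by default the two
halotolerant lineages), a site with identical extant residues $x$ in both
species qualifies when both parent-node MAP states differ from $x$;
it is *parallel* when the two parent states agree and *convergent* when
they differ. The parent-node reading of the "changed relative to the most
recent common ancestor" criterion is used because the MRCA alone cannot
separate the two categories; a path-based variant would additionally count
changes on internal branches and is deliberately out of scope.

Expected counts condition on the parent MAP states $a_A, a_B$ and the
terminal branch lengths: a site contributes
$\sum_{x \ne a} P_{t_A}(a, x) P_{t_B}(a, x)$ (parallel, $a_A = a_B = a$) or
$\sum_{x \ne a_A, a_B} P_{t_A}(a_A, x) P_{t_B}(a_B, x)$ (convergent). The
observed count is referred to a Poisson distribution with the expected
count as mean — upper tail when observed exceeds expected, lower tail
otherwise — and BH-FDR is applied across genes within a pair. By default
parallel and convergent counts are pooled into one test per gene (the
reported tables separate the types); a per-type mode exists because the
pooling convention is ambiguous in practice. Genes significant for
convergence *and* carrying BEB-supported positively selected sites form the
conservative adaptive set.

The default exchangeability matrix is cpREV, the chloroplast-protein
empirical model shipped with phangorn; any PAML-layout `.dat` matrix (for
example gcpREV) drops in via `read_paml_dat()`.

## The synthetic-data generator

`simulate_codon_alignment()` draws a class per site once (the branch-site
assumption: classes are site properties, fixed across the tree), samples
the root from the stationary distribution, and walks the tree using the
same shared-time-scale transition matrices as the likelihood — so generator
and fitter agree by construction, and parameter-recovery tests are
meaningful. `simulate_aa_alignment()` does the same over 20 states and
records true internal states; planted events overwrite two designated tips
with a shared derived residue. Presets encode the study designs: `bs_null`
($\omega_2 = 1$, 300 codons) for size, `bs_power` (15% foreground sites at
$\omega_2 = 4$, 600 codons) for power, `paper_like` (one class at
$\omega = 0.03$, the average purifying regime of chloroplast genes, with
gene-specific values spanning roughly 0.001–0.06), and `convergence_null`
(cpREV, 300 residues). The default tree has 13 taxa with branch lengths
0.02–0.3 substitutions per codon, the regime in which per-branch dS stays
below the filtering threshold of 1.

What the generator does *not* emulate: indels and alignment error (inputs
are assumed aligned; cleaning is complete deletion of gap/ambiguous codon
columns), selection on synonymous codon usage beyond F3×4, rate variation
from lineage effects other than the tagged foreground, and recombination.
Passing tests therefore demonstrate correctness of the estimators under
the model's own assumptions, not robustness to alignment artefacts — which
is why the pipeline keeps the dS filter, the exclusion list for visually
ambiguous genes, and complete deletion as explicit, configurable steps.

## Numerical notes and limitations

* Site patterns are collapsed before any likelihood work; all reported
  site indices are 1-based alignment positions.
* Zero F3×4 frequencies (possible in degenerate alignments) are floored at
  $10^{-8}$ inside the eigendecomposition only; unreachable states do not
  affect the likelihood of observed data.
* Problem sizes in the test suite (4–13 taxa, 100–600 codons, 20–200
  replicates per calibration study) were chosen as the smallest designs
  that make the statistical checks informative; the same generator scales
  to larger studies.
* With a single foreground tip the branch-site test uses information from
  one branch only; its power at realistic chloroplast divergences is
  modest, and boundary estimates $\omega_2 = 999$ with few supporting
  sites should be read alongside their BEB posteriors, not alone.
* The LRT reference (plain $\chi^2_1$) is conservative for boundary
  hypotheses; a mixture reference can be obtained by halving the p-values
  if desired.
* The dS filter reproduces the rule (discard genes whose maximum
  per-branch dS reaches 1), not any particular published gene list; which
  genes are discarded depends on the data supplied.
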