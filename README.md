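# chlorosel

Detecting positive selection and convergent amino-acid evolution in
chloroplast protein-coding genes — and in any comparable multi-gene
organellar data set — from per-gene codon alignments and a fixed phylogeny.

Extremophile green algae (Antarctic sea-ice, polar and hypersaline
lineages) are a model case for this kind of analysis: purifying selection
dominates chloroplast genes (gene-wide dN/dS around 0.03), so adaptive
signal, where it exists, is confined to a few sites on a few branches, and
separate lineages under the same stress may fix the same residues
independently. chlorosel implements the full inferential chain that this
question requires:

* **Codon models** (Goldman–Yang, F3×4 frequencies): the one-ratio model
  M0 with per-branch dN/dS decomposition and the dS < 1 gene filter; the
  two-ratio branch model; the M8/M8a site-model pair; and branch-site
  Model A with its ω₂ = 1 null — each fitted by maximum likelihood with
  multi-start optimization and re-estimated branch lengths.
* **Inference**: likelihood-ratio tests against χ²(df = 1),
  Benjamini–Hochberg FDR per test family, and Bayes empirical Bayes (BEB)
  identification of positively selected sites at posterior probability
  ≥ 0.95 (naive empirical Bayes as cross-check).
* **Convergence**: marginal ancestral reconstruction under an empirical
  chloroplast amino-acid model (cpREV × gene frequencies; any PAML-layout
  matrix such as gcpREV drops in), classification of parallel
  (same ancestral state) and convergent (different ancestral states)
  substitutions for a species pair, Poisson tests of observed versus
  model-expected counts, and the conservative intersection of positively
  selected and convergent genes.
* **Synthetic data**: a generator for codon and amino-acid alignments
  under the same model families (site classes fixed across the tree,
  foreground ω switching, planted convergent events) with presets for
  null, power and study-like designs.
* **Pipeline**: `run_pipeline()` orchestrates reading/cleaning,
  filtering, all model fits, FDR, BEB, convergence and reporting over a
  gene directory, fail-soft per gene; a thin command-line wrapper with
  `run`, `fit`, `converge`, `simulate` and `report` subcommands is
  installed at `exec/chlorosel`.

The core statistic throughout is ω = dN/dS: ω < 1 purifying selection,
ω = 1 neutrality, ω > 1 positive selection, with the branch-site LRT
statistic 2δ(lnL) = 2(lnL₁ − lnL₀) as the primary test.

## Worked example

Simulate a 13-taxon data set with 15% of sites under foreground positive
selection on the Antarctic lineage, fit the branch-site pair, test, and
identify sites:

```r
library(chlorosel)
ctl <- list(max_cycles = 2, sweeps_per_cycle = 1, rel_tol = 1e-7,
            eval_max = 60, iter_max = 14)
sc   <- scenario_presets("bs_power", seed = 42)
aln  <- simulate_codon_alignment(sc)
fits <- fit_branch_site(aln, sc$tree, "Chlamydomonas_ICEL", control = ctl)
r    <- lrt(fits$null$loglik, fits$alt$loglik, df = 1)
bb   <- beb_sites(fits$alt, aln, sc$tree, "Chlamydomonas_ICEL")
```

Output:

```
fit_result [BS_null] on 'bs_power': lnL = -9477.982146
  params: kappa=2.0292, x=0.6173, y=0.6859, omega0=0.0440, ...
fit_result [BS_alt] on 'bs_power': lnL = -9471.768482
  params: kappa=2.04302, ..., omega0=0.04428, omega2=3.80235, ...
2dlnL = 12.427, p = 0.0004231
BEB sites (PP >= 0.95): 28-0.971, 187-0.987, 201-0.990, 270-0.992,
                        305-0.992, 326-0.991, 478-0.994
```

Reading this: the alternative model places an estimated 19% of sites
(p2a + p2b) in classes allowed ω₂ = 3.8 on the foreground branch; twice
the log-likelihood difference, 12.43, is far in the χ²₁ tail (p ≈ 4×10⁻⁴),
and seven sites reach BEB posterior probability ≥ 0.95 — the data were
simulated with ω₂ = 4 on 15% of sites, so both the effect size and the
flagged sites track the truth. The `site-pp` format (e.g. `28-0.971`)
matches the conventional reporting of positively selected sites.

The same analysis runs from the shell:

```sh
chlorosel simulate --preset bs_power --seed 42 --out data/
chlorosel fit --model BS --aln data/bs_power.fasta --tree data/bs_power.nwk \
          --foreground Chlamydomonas_ICEL
```

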