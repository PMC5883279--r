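# Shared fixtures and settings for the test suite. Problem sizes are kept
# small: 4-6 taxa and a few hundred codons exercise every code path.

# optimizer settings used throughout the tests
light_ctl <- list(max_cycles = 2, sweeps_per_cycle = 1, rel_tol = 1e-7,
                  eval_max = 60, iter_max = 14)

tree4 <- function() {
  ape::read.tree(text = "((A:0.12,B:0.18):0.05,(C:0.22,D:0.09):0.07);")
}

tree6 <- function() {
  ape::read.tree(text = paste0("(((A:0.1,B:0.15):0.05,C:0.2):0.04,",
                               "(D:0.12,(E:0.08,F:0.18):0.06):0.05);"))
}

# small codon alignment from explicit sequences
toy_codon_aln <- function(seqs, gene = "toy") {
  codon_alignment(seqs, gene_name = gene)
}

# deterministic small simulated alignment
sim_codon <- function(tree, n_sites, omega = 0.2, kappa = 2, seed = 1,
                      name = "sim") {
  mix <- site_class_mixture(kappa, uniform_codon_frequencies(), 1, omega)
  simulate_codon_alignment(simulation_scenario(tree, mix, n_sites,
                                               seed = seed, name = name))
}

# memoized expensive fixtures (computed once per test run)
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# a branch-site fit on data with genuine foreground signal (shared by the
# BEB/NEB and reporting tests)
bs_power_fit <- function() {
  fixture("bs_power_fit", function() {
    sc <- scenario_presets("bs_power", n_sites = 400L, seed = 5)
    aln <- simulate_codon_alignment(sc)
    fits <- fit_branch_site(aln, sc$tree, "Chlamydomonas_ICEL", starts = 2,
                            control = light_ctl)
    list(aln = aln, tree = sc$tree, fits = fits,
         foreground = "Chlamydomonas_ICEL")
  })
}

# amino-acid model shared across convergence tests
cpreV_model <- function() {
  fixture("cprev_model", function() {
    ex <- aa_exchangeabilities("cpREV")
    aa_rate_matrix(ex$S, ex$freq)
  })
}

# write a small pipeline input set (returns the directory); `genes` is a
# named list of codon_alignment objects
write_pipeline_inputs <- function(genes, tree, classes, dir = tempfile("pipe")) {
  dir.create(file.path(dir, "genes"), recursive = TRUE)
  for (g in names(genes)) {
    write_gene_alignment(genes[[g]], file.path(dir, "genes", paste0(g, ".fasta")))
  }
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  writeLines(paste(names(classes), classes, sep = "\t"),
             file.path(dir, "classes.tsv"))
  dir
}

# plant convergent codon substitutions: both tips set to `codon` at `sites`
plant_convergent_codons <- function(aln, sites, tips, codon = "TCT") {
  codon_idx <- which(chlorosel:::SENSE_CODONS == codon)
  aln$codons[tips, sites] <- codon_idx
  aln
}
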