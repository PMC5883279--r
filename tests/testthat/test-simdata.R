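# The synthetic-data generator: determinism, degenerate cases, marginal
# distributions and planted events.

test_that("a fixed seed gives bit-identical alignments", {
  sc <- scenario_presets("paper_like", n_sites = 80L, seed = 99)
  a1 <- simulate_codon_alignment(sc)
  a2 <- simulate_codon_alignment(sc)
  expect_identical(a1$codons, a2$codons)
  expect_identical(attr(a1, "true_class"), attr(a2, "true_class"))
  a3 <- simulate_codon_alignment(scenario_presets("paper_like",
                                                  n_sites = 80L, seed = 100))
  expect_false(identical(a1$codons, a3$codons))
})

test_that("zero branch lengths copy the root state to every tip", {
  tr <- algae_tree()
  tr$edge.length[] <- 0
  mix <- site_class_mixture(2, uniform_codon_frequencies(), 1, 0.3)
  aln <- simulate_codon_alignment(simulation_scenario(tr, mix, 50, seed = 5,
                                                      name = "frozen"))
  expect_true(all(apply(aln$codons, 2, function(col) length(unique(col)) == 1)))
})

test_that("a single long branch reaches the stationary distribution", {
  tr <- ape::read.tree(text = "(A:0.0001,B:20);")
  fr <- uniform_codon_frequencies()
  mix <- site_class_mixture(2, fr, 1, 0.5)
  n <- 4000L
  aln <- simulate_codon_alignment(simulation_scenario(tr, mix, n, seed = 8,
                                                      name = "long"))
  counts <- tabulate(aln$codons["B", ], nbins = 61)
  p0 <- 1 / 61
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(counts / n - p0) < 4 * se))
})

test_that("single-branch transition counts match P(t) rows", {
  # two taxa, one effectively zero branch: tip A reads the root state, and
  # B | A = s is a draw from row s of P(t)
  tr <- ape::read.tree(text = "(A:0.000001,B:0.3);")
  fr <- uniform_codon_frequencies()
  mix <- site_class_mixture(2, fr, 1, 0.5)
  aln <- simulate_codon_alignment(simulation_scenario(tr, mix, 5000, seed = 12,
                                                      name = "gof"))
  m <- codon_rate_matrix(2, 0.5, fr)
  P <- transition_matrix(m, 0.3)
  a <- aln$codons["A", ]; b <- aln$codons["B", ]
  # pool over the most frequent parent states; chi-square goodness of fit
  for (s in as.integer(names(sort(table(a), decreasing = TRUE)[1:3]))) {
    obs <- tabulate(b[a == s], nbins = 61)
    expect_gt(suppressWarnings(
      stats::chisq.test(obs, p = P[s, ])$p.value), 0.01)
  }
})

test_that("presets encode their study designs", {
  bsn <- scenario_presets("bs_null", seed = 1)
  expect_true(all(bsn$model$classes$omega_fg <= 1))
  expect_equal(bsn$n_sites, 300L)
  bsp <- scenario_presets("bs_power", seed = 1)
  expect_true(any(bsp$model$classes$omega_fg > 1))
  expect_equal(sum(bsp$model$classes$prop[bsp$model$classes$omega_fg > 1]),
               0.15, tolerance = 1e-12)
  pl <- scenario_presets("paper_like", seed = 1)
  expect_equal(pl$model$classes$omega_bg, 0.03)
  expect_equal(length(algae_tree()$tip.label), 13L)
  expect_error(scenario_presets("nope"), "arg")
})

test_that("planted amino-acid events flow through to pair detection", {
  m <- cpreV_model()
  sc <- scenario_presets("convergence_null", n_sites = 120L, seed = 17)
  sc$planted_events <- data.frame(site = 7L,
                                  tipA = "Chlamydomonas_ICEL",
                                  tipB = "Dunaliella_salina",
                                  residue = "W")
  aln <- simulate_aa_alignment(sc)
  trp <- match("W", chlorosel:::AA_LETTERS)
  expect_equal(unname(aln$aa["Chlamydomonas_ICEL", 7]), trp)
  expect_equal(unname(aln$aa["Dunaliella_salina", 7]), trp)
  asr <- reconstruct_ancestors(aln, sc$tree, m, control = light_ctl)
  found <- find_pair_substitution_sites(asr, c("Chlamydomonas_ICEL",
                                               "Dunaliella_salina"))
  expect_true(7L %in% c(found$parallel$site, found$convergent$site))
  # planting on an unknown taxon is an error
  sc$planted_events$tipA <- "not_a_tip"
  expect_error(simulate_aa_alignment(sc), "non-terminal")
})

test_that("true internal states are recorded for accuracy measurement", {
  sc <- scenario_presets("convergence_null", n_sites = 200L, seed = 23)
  aln <- simulate_aa_alignment(sc)
  ts <- attr(aln, "true_states")
  expect_equal(dim(ts), c(25L, 200L))
  m <- cpreV_model()
  asr <- reconstruct_ancestors(aln, sc$tree, m, control = light_ctl)
  # MAP accuracy on moderate branch lengths is high; node numbering of the
  # reconstruction matches the simulation (same postorder indexing)
  acc <- mean(asr$map == ts[13 + (1:12), ])
  expect_gt(acc, 0.9)
})

test_that("scenario files round-trip through the standard formats", {
  dir <- tempfile("scen")
  sc <- scenario_presets("paper_like", n_sites = 30L, seed = 3)
  paths <- write_scenario(sc, dir)
  aln <- read_gene_alignment(file.path(dir, "paper_like.fasta"))
  expect_equal(aln$n_sites, 30L)
  tr <- ape::read.tree(file.path(dir, "paper_like.nwk"))
  expect_setequal(tr$tip.label, aln$taxa)
  truth <- utils::read.table(file.path(dir, "paper_like_truth.tsv"),
                             header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 30L)
})
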