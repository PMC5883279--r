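# Ancestral reconstruction and the convergent/parallel substitution test.

test_that("invariant columns reconstruct with near-certain posteriors", {
  m <- cpreV_model()
  leu <- which(chlorosel:::AA_LETTERS == "L")
  aa <- structure(list(gene_name = "inv", taxa = tree4()$tip.label,
                       aa = matrix(leu, 4, 10,
                                   dimnames = list(tree4()$tip.label, NULL)),
                       n_sites = 10L), class = "aa_alignment")
  asr <- reconstruct_ancestors(aa, tree4(), m, control = light_ctl)
  expect_true(all(asr$map == leu))
  expect_true(all(asr$post_max > 0.99))
})

test_that("a 3-taxon star matches the direct Bayes computation", {
  m <- cpreV_model()
  tr <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.15);")
  states <- c(A = "L", B = "L", C = "F")
  idx <- match(states, chlorosel:::AA_LETTERS)
  aa <- structure(list(gene_name = "star", taxa = names(states),
                       aa = matrix(idx, 3, 1, dimnames = list(names(states), NULL)),
                       n_sites = 1L), class = "aa_alignment")
  asr <- reconstruct_ancestors(aa, tr, m, control = list(max_cycles = 0))
  # direct: post(a) proportional to pi_a * prod_i P_{t_i}(a -> x_i), with the
  # branch lengths the reconstruction settled on
  t_used <- asr$tree$edge.length[match(1:3, asr$tree$edge[, 2])]
  Pm <- lapply(t_used, function(t) transition_matrix(m, t))
  w <- m$pi
  for (i in 1:3) w <- w * Pm[[i]][, idx[i]]
  w <- w / sum(w)
  root_row <- as.vector(asr$posterior[4, , 1])
  expect_equal(root_row, unname(w), tolerance = 1e-8)
  expect_equal(sum(root_row), 1, tolerance = 1e-10)
})

test_that("posteriors sum to one at every node and site", {
  m <- cpreV_model()
  sc <- scenario_presets("convergence_null", n_sites = 60L, seed = 13)
  aln <- simulate_aa_alignment(sc)
  asr <- reconstruct_ancestors(aln, sc$tree, m, control = light_ctl)
  sums <- apply(asr$posterior[13 + (1:12), , ], c(1, 3), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-8)
})

test_that("planted parallel and convergent substitutions are classified", {
  m <- cpreV_model()
  # force tips A and B to share a derived residue; each sits nested inside
  # a clade fixed for the ancestral residue, so the parent reconstructions
  # are pinned (one change on the long terminal branch beats two changes on
  # the short surrounding branches)
  tr <- ape::read.tree(text = paste0(
    "(((A:0.3,C2:0.02):0.02,C1:0.02):0.05,",
    "((B:0.3,D2:0.02):0.02,D1:0.02):0.05);"))
  ala <- match("A", chlorosel:::AA_LETTERS)
  ser <- match("S", chlorosel:::AA_LETTERS)
  met <- match("M", chlorosel:::AA_LETTERS)
  thr <- match("T", chlorosel:::AA_LETTERS)
  n <- 40L
  base <- matrix(ala, 6, n,
                 dimnames = list(c("A", "C2", "C1", "B", "D2", "D1"), NULL))
  # site 3: parallel Ala -> Ser on both terminal branches
  base[c("A", "B"), 3] <- ser
  # site 7: convergent Met/Thr -> Ser (ancestors pinned by the clades)
  base[c("C1", "C2"), 7] <- met
  base[c("D1", "D2"), 7] <- thr
  base[c("A", "B"), 7] <- ser
  aa <- structure(list(gene_name = "planted", taxa = rownames(base),
                       aa = base, n_sites = n), class = "aa_alignment")
  asr <- reconstruct_ancestors(aa, tr, m, control = light_ctl)
  found <- find_pair_substitution_sites(asr, c("A", "B"))
  expect_equal(found$parallel$site, 3L)
  expect_equal(found$parallel$label, "Ala-Ser")
  expect_equal(found$convergent$site, 7L)
  expect_equal(found$convergent$derived, "Ser")
  # counts are symmetric in pair order
  swapped <- find_pair_substitution_sites(asr, c("B", "A"))
  expect_equal(nrow(swapped$parallel), nrow(found$parallel))
  expect_equal(nrow(swapped$convergent), nrow(found$convergent))
  # identical rows with identical ancestors produce empty lists
  aa0 <- aa; aa0$aa[] <- ala
  asr0 <- reconstruct_ancestors(aa0, tr, m, control = light_ctl)
  f0 <- find_pair_substitution_sites(asr0, c("A", "B"))
  expect_equal(nrow(f0$parallel) + nrow(f0$convergent), 0L)
  expect_error(find_pair_substitution_sites(asr, c("A", "nope")), "leaves")
})

test_that("expected convergence counts follow the pair-product formula", {
  m <- cpreV_model()
  # synthetic reconstruction object with fixed MAP ancestors; the pair
  # members sit in different cherries so their parent nodes are distinct
  tr <- ape::reorder.phylo(tree4(), "postorder")
  tipA <- match("A", tr$tip.label)
  tipC <- match("C", tr$tip.label)
  tr$edge.length[match(c(tipA, tipC), tr$edge[, 2])] <- c(0.3, 0.2)
  parA <- tr$edge[match(tipA, tr$edge[, 2]), 1]
  parB <- tr$edge[match(tipC, tr$edge[, 2]), 1]
  nodes <- sort(unique(tr$edge[, 1]))
  map <- matrix(1L, length(nodes), 3, dimnames = list(nodes, NULL))
  map[as.character(parA), ] <- c(5L, 5L, 7L)
  map[as.character(parB), ] <- c(5L, 5L, 9L)
  asr <- structure(list(tree = tr, map = map, model = m,
                        tip_states = matrix(1L, 4, 3,
                                            dimnames = list(tr$tip.label, NULL)),
                        gene_name = "synthetic"),
                   class = "ancestral_states")
  ex <- expected_pair_convergence(asr, c("A", "C"))
  PA <- transition_matrix(m, 0.3)
  PB <- transition_matrix(m, 0.2)
  exp_par_oracle <- 2 * sum(PA[5, -5] * PB[5, -5])
  exp_con_oracle <- sum(PA[7, -c(7, 9)] * PB[9, -c(7, 9)])
  expect_equal(ex$expected_parallel, exp_par_oracle, tolerance = 1e-12)
  expect_equal(ex$expected_convergent, exp_con_oracle, tolerance = 1e-12)
  # zero terminal branches give zero expectation
  tr0 <- tr
  tr0$edge.length[match(c(tipA, tipC), tr0$edge[, 2])] <- 0
  asr0 <- asr; asr0$tree <- tr0
  ex0 <- expected_pair_convergence(asr0, c("A", "C"))
  expect_equal(ex0$expected_parallel, 0)
  expect_equal(ex0$expected_convergent, 0)
  # expectations grow with terminal branch length
  tr2 <- tr
  tr2$edge.length[match(c(tipA, tipC), tr2$edge[, 2])] <- c(0.6, 0.4)
  asr2 <- asr; asr2$tree <- tr2
  ex2 <- expected_pair_convergence(asr2, c("A", "C"))
  expect_gt(ex2$expected_parallel, ex$expected_parallel)
})

test_that("Poisson tails match pmf summation and the tie convention", {
  expect_equal(poisson_convergence_test(0, 0)$p_value, 1)
  r <- poisson_convergence_test(4, 0.5)
  expect_equal(r$tail, "upper")
  expect_equal(r$p_value, pois_upper_pmf(4, 0.5), tolerance = 1e-10)
  r2 <- poisson_convergence_test(1, 5)
  expect_equal(r2$tail, "lower")
  expect_equal(r2$p_value, pois_lower_pmf(1, 5), tolerance = 1e-10)
  r3 <- poisson_convergence_test(3, 3)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$tail, "none")
  expect_error(poisson_convergence_test(-1, 2), "nonnegative")
  expect_error(poisson_convergence_test(1.5, 2), "integer")
})

test_that("the conservative intersection reproduces the published logic", {
  psg <- c("atpB", "psaB", "rbcL")
  conv <- c("atpB", "atpI", "petA", "psaB", "rbcL", "tufA", "psbF", "psbZ")
  both <- conservative_adaptive_genes(psg, conv)
  expect_equal(as.character(both), c("atpB", "psaB", "rbcL"))
  expect_equal(as.character(conservative_adaptive_genes(c("a"), c("b"))),
               character(0))
  expect_equal(as.character(conservative_adaptive_genes(psg, psg)), sort(psg))
})
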