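# Synthetic codon and amino-acid alignments with the statistical structure
# the analyses assume: site classes drawn once per site and held fixed across
# the tree, foreground/background omega switching on tagged branches, and
# optional planted convergent substitutions for calibration studies.

#' Default 13-taxon green-algal phylogeny
#'
#' A fixed topology over six Chlorophyceae (including the two halotolerant
#' lineages used as the default convergence pair) and seven Trebouxiophyceae,
#' with branch lengths in the 0.02-0.3 substitutions-per-codon range typical
#' of chloroplast genes that pass the dS < 1 filter.
#'
#' @return an ape `phylo` with 13 tips.
#' @export
algae_tree <- function() {
  ape::read.tree(text = paste0(
    "(((Dunaliella_salina:0.22,(Chlamydomonas_applanata:0.16,",
    "(Microglena_monadina:0.12,Chlamydomonas_ICEL:0.14):0.05):0.04):0.06,",
    "(Chlamydomonas_reinhardtii:0.15,Volvox_carteri:0.17):0.08):0.10,",
    "((Paradoxia_multiseta:0.20,Choricystis_parasitica:0.18):0.05,",
    "(Coccomyxa_subellipsoidea:0.19,(Dicloster_acuatus:0.16,",
    "(Parachlorella_kessleri:0.12,(Chlorella_ArM0029B:0.10,",
    "Chlorella_vulgaris:0.11):0.04):0.05):0.04):0.03):0.10);"))
}

#' Simulation scenario
#'
#' @param tree ape `phylo` with branch lengths.
#' @param model a `site_class_mixture` (codon simulation) or a `rate_matrix`
#'   (amino-acid simulation).
#' @param n_sites number of codon or residue sites.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param foreground foreground tip labels for branch/branch-site mixtures.
#' @param planted_events optional data frame (`site`, `tipA`, `tipB`,
#'   `residue`) of forced identical derived residues on two terminal
#'   branches (amino-acid simulation only); `residue` is a single-letter
#'   code.
#' @param name scenario label.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(tree, model, n_sites, seed = 1L,
                                foreground = NULL, planted_events = NULL,
                                name = "scenario") {
  if (is.null(tree$edge.length)) stop("argument error: scenario tree needs branch lengths")
  if (n_sites < 1) stop("argument error: n_sites must be positive")
  structure(list(tree = tree, model = model, n_sites = as.integer(n_sites),
                 seed = as.integer(seed), foreground = foreground,
                 planted_events = planted_events, name = name),
            class = "simulation_scenario")
}

# Evolve integer states down the tree; returns states for all nodes.
.evolve_states <- function(ti, Plists, class_of_site, pi_root, n_states) {
  n_sites <- length(class_of_site)
  nn <- ti$ntip + ti$nnode
  states <- matrix(NA_integer_, nn, n_sites)
  states[ti$root, ] <- sample.int(n_states, n_sites, replace = TRUE, prob = pi_root)
  for (nd in rev(ti$parents_order)) {
    for (e in ti$children_edges[[nd]]) {
      ch <- ti$edge[e, 2]
      par_state <- states[nd, ]
      out <- integer(n_sites)
      for (k in unique(class_of_site)) {
        sel <- class_of_site == k
        P <- Plists[[k]][[e]]
        for (s in unique(par_state[sel])) {
          idx <- which(sel & par_state == s)
          out[idx] <- sample.int(n_states, length(idx), replace = TRUE,
                                 prob = P[s, ])
        }
      }
      states[ch, ] <- out
    }
  }
  states
}

#' Simulate a codon alignment under a site-class mixture
#'
#' Each site draws a class once (held fixed across the tree); the root codon
#' comes from the stationary distribution and states evolve branch by branch
#' through the class transition matrices, with foreground branches using the
#' class's foreground omega.
#'
#' @param scenario a `simulation_scenario` whose model is a
#'   `site_class_mixture`.
#' @return a cleaned `codon_alignment` with attributes `true_class` (per-site
#'   class index) and `scenario`.
#' @export
simulate_codon_alignment <- function(scenario) {
  mix <- scenario$model
  if (!inherits(mix, "site_class_mixture")) {
    stop("argument error: codon simulation needs a site_class_mixture")
  }
  set.seed(scenario$seed)
  ti <- .tree_index(scenario$tree, scenario$tree$tip.label)
  fg <- .foreground_edges(ti, scenario$foreground)
  tvec <- ti$tree$edge.length
  K <- nrow(mix$classes)
  eigs <- lapply(seq_len(K), function(k) list(
    bg = eigen_rate_matrix(codon_rate_matrix(mix$kappa, mix$classes$omega_bg[k], mix$freqs)),
    fg = eigen_rate_matrix(codon_rate_matrix(mix$kappa, mix$classes$omega_fg[k], mix$freqs))))
  # shared time scale across classes: omega rescales the substitution rate,
  # and a branch length is expected substitutions per codon averaged over
  # the background classes (same convention as tree_loglik)
  fl <- .syn_nonsyn_flow(mix$kappa, mix$freqs)
  s_of <- function(w) fl[["B"]] + w * fl[["A"]]
  C_mix <- sum(mix$classes$prop * s_of(mix$classes$omega_bg))
  Plists <- lapply(seq_len(K), function(k) {
    r_bg <- s_of(mix$classes$omega_bg[k]) / C_mix
    r_fg <- s_of(mix$classes$omega_fg[k]) / C_mix
    Pl <- .class_P(eigs[[k]]$bg, eigs[[k]]$fg, tvec * r_bg, fg)
    if (r_fg != r_bg && length(fg)) {
      for (e in fg) Pl[[e]] <- .P_from_eigen(eigs[[k]]$fg, tvec[e] * r_fg)
    }
    Pl
  })
  cls <- sample.int(K, scenario$n_sites, replace = TRUE, prob = mix$classes$prop)
  states <- .evolve_states(ti, Plists, cls, mix$freqs$pi, N_CODON)
  codons <- states[seq_len(ti$ntip), , drop = FALSE]
  rownames(codons) <- ti$tree$tip.label
  aln <- structure(list(gene_name = scenario$name, taxa = ti$tree$tip.label,
                        codons = codons, n_sites = scenario$n_sites),
                   class = "codon_alignment")
  attr(aln, "true_class") <- cls
  attr(aln, "scenario") <- scenario
  aln
}

#' Simulate an amino-acid alignment
#'
#' As the codon simulator but over 20 states under a fixed `rate_matrix`;
#' true internal-node states are recorded so reconstruction accuracy is
#' measurable, and planted events overwrite the drawn state of two
#' designated terminal taxa with a shared derived residue.
#'
#' @param scenario a `simulation_scenario` whose model is a 20-state
#'   `rate_matrix`.
#' @return an `aa_alignment` with attributes `true_states` (nodes x sites
#'   matrix over all tree nodes) and `scenario`.
#' @export
simulate_aa_alignment <- function(scenario) {
  m <- scenario$model
  if (!inherits(m, "rate_matrix") || m$states != 20L) {
    stop("argument error: amino-acid simulation needs a 20-state rate_matrix")
  }
  set.seed(scenario$seed)
  ti <- .tree_index(scenario$tree, scenario$tree$tip.label)
  eig <- eigen_rate_matrix(m)
  Plists <- list(.class_P(eig, eig, ti$tree$edge.length, integer(0)))
  states <- .evolve_states(ti, Plists, rep(1L, scenario$n_sites), m$pi, 20L)
  if (!is.null(scenario$planted_events)) {
    pe <- scenario$planted_events
    for (r in seq_len(nrow(pe))) {
      tips <- match(c(pe$tipA[r], pe$tipB[r]), ti$tree$tip.label)
      if (anyNA(tips)) {
        stop("argument error: planted event on a non-terminal taxon: ",
             pe$tipA[r], "/", pe$tipB[r])
      }
      states[tips, pe$site[r]] <- match(pe$residue[r], AA_LETTERS)
    }
  }
  aa <- states[seq_len(ti$ntip), , drop = FALSE]
  rownames(aa) <- ti$tree$tip.label
  out <- structure(list(gene_name = scenario$name, taxa = ti$tree$tip.label,
                        aa = aa, n_sites = scenario$n_sites),
                   class = "aa_alignment")
  attr(out, "true_states") <- states
  attr(out, "tree_index") <- NULL
  attr(out, "scenario") <- scenario
  out
}

#' Named simulation presets
#'
#' Fully specified scenarios for the routine study designs:
#' \describe{
#'   \item{bs_null}{branch-site data with omega2 = 1 (type-I error studies).}
#'   \item{bs_power}{15\% of foreground sites at omega2 = 4.}
#'   \item{m8_null}{purifying-only beta-distributed sites (no omega > 1 class).}
#'   \item{convergence_null}{amino-acid evolution under cpREV with uniform-ish
#'     gene frequencies and no planted convergence.}
#'   \item{paper_like}{strongly purifying codon data, omega = 0.03, the
#'     average regime of chloroplast genes.}
#' }
#'
#' @param name preset name.
#' @param n_sites number of sites (defaults per preset).
#' @param seed integer seed.
#' @param foreground foreground tip (defaults to the ICE-L lineage).
#' @return a `simulation_scenario`.
#' @export
scenario_presets <- function(name = c("bs_null", "bs_power", "m8_null",
                                      "convergence_null", "paper_like"),
                             n_sites = NULL, seed = 1L,
                             foreground = "Chlamydomonas_ICEL") {
  name <- match.arg(name)
  tree <- algae_tree()
  freqs <- uniform_codon_frequencies()
  if (name == "bs_null") {
    mix <- site_class_mixture(2, freqs, c(0.75, 0.25), c(0.05, 1), c(0.05, 1),
                              label = "bs_null")
    simulation_scenario(tree, mix, n_sites %||% 300L, seed,
                        foreground = foreground, name = name)
  } else if (name == "bs_power") {
    mix <- site_class_mixture(2, freqs,
                              proportions = c(0.60, 0.25, 0.10, 0.05),
                              omega_bg = c(0.05, 1, 0.05, 1),
                              omega_fg = c(0.05, 1, 4, 4),
                              label = "bs_power")
    simulation_scenario(tree, mix, n_sites %||% 600L, seed,
                        foreground = foreground, name = name)
  } else if (name == "m8_null") {
    w <- stats::qbeta((1:10 - 0.5) / 10, 0.5, 2.5)
    mix <- site_class_mixture(2, freqs, rep(0.1, 10), w, label = "m8_null")
    simulation_scenario(tree, mix, n_sites %||% 300L, seed, name = name)
  } else if (name == "convergence_null") {
    ex <- aa_exchangeabilities("cpREV")
    m <- aa_rate_matrix(ex$S, ex$freq)
    simulation_scenario(tree, m, n_sites %||% 300L, seed, name = name)
  } else {
    mix <- site_class_mixture(2, freqs, 1, 0.03, label = "paper_like")
    simulation_scenario(tree, mix, n_sites %||% 400L, seed, name = name)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario's data set to disk
#'
#' FASTA alignment, newick tree and a truth table (TSV of per-site class or
#' internal-node states) so the full pipeline can run on synthetic input.
#'
#' @param scenario a `simulation_scenario`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (inherits(scenario$model, "site_class_mixture")) {
    aln <- simulate_codon_alignment(scenario)
    fa <- file.path(dir, paste0(scenario$name, ".fasta"))
    write_gene_alignment(aln, fa)
    truth <- file.path(dir, paste0(scenario$name, "_truth.tsv"))
    utils::write.table(data.frame(site = seq_len(aln$n_sites),
                                  class = attr(aln, "true_class")),
                       truth, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    aln <- simulate_aa_alignment(scenario)
    fa <- file.path(dir, paste0(scenario$name, "_aa.fasta"))
    seqs <- apply(matrix(AA_LETTERS[aln$aa], nrow(aln$aa)), 1, paste0, collapse = "")
    writeLines(as.vector(rbind(paste0(">", aln$taxa), seqs)), fa)
    truth <- file.path(dir, paste0(scenario$name, "_truth.tsv"))
    ts <- attr(aln, "true_states")
    utils::write.table(
      data.frame(node = rep(seq_len(nrow(ts)), each = ncol(ts)),
                 site = rep(seq_len(ncol(ts)), nrow(ts)),
                 residue = AA_LETTERS[t(ts)[seq_len(length(ts))]]),
      truth, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tr <- file.path(dir, paste0(scenario$name, ".nwk"))
  ape::write.tree(scenario$tree, tr)
  invisible(c(fa, tr, truth))
}
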