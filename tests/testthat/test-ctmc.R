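# Frequencies, rate matrices and transition probabilities.

test_that("uniform nucleotide usage gives 1/61 per sense codon", {
  # 4 single-codon sequences covering each nucleotide once per position
  seqs <- c(a = "ACG", b = "CGT", c = "GTA", d = "TAC")
  aln <- clean_alignment(codon_alignment(seqs, strip_terminal_stop = FALSE))
  fr <- f3x4_frequencies(aln)
  expect_equal(unname(fr$pos_freqs), matrix(0.25, 3, 4), tolerance = 1e-12)
  expect_equal(unname(fr$pi), rep(1 / 61, 61), tolerance = 1e-12)
})

test_that("a single sequence yields point-mass position frequencies", {
  aln <- clean_alignment(codon_alignment(c(s = "ATGATG"),
                                         strip_terminal_stop = FALSE))
  fr <- f3x4_frequencies(aln)
  expect_equal(fr$pos_freqs["pos1", "A"], 1)
  expect_equal(fr$pos_freqs["pos2", "T"], 1)
  expect_equal(fr$pos_freqs["pos3", "G"], 1)
  expect_equal(unname(fr$pi["ATG"]), 1)
})

test_that("F3x4 matches a hand tally on a 2x2 alignment", {
  # codons: s1 = ATG, CCA; s2 = ATA, GCA
  aln <- clean_alignment(codon_alignment(c(s1 = "ATGCCA", s2 = "ATAGCA")))
  fr <- f3x4_frequencies(aln)
  # position 1 sees A,C,A,G; position 2 T,C,T,C; position 3 G,A,A,A
  expect_equal(unname(fr$pos_freqs["pos1", c("A", "C", "G")]),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(fr$pos_freqs["pos2", c("C", "T")]), c(0.5, 0.5))
  expect_equal(unname(fr$pos_freqs["pos3", c("A", "G")]), c(0.75, 0.25))
  # hand-computed product for ATG; position 1 never shows T, so all three
  # stop codons carry zero mass and the sense renormalizer is 1
  raw_atg <- 0.5 * 0.5 * 0.25
  expect_equal(unname(fr$pi["ATG"]), raw_atg, tolerance = 1e-12)
})

test_that("GY94 codon rates obey kappa/omega structure and reversibility", {
  fr <- uniform_codon_frequencies()
  m <- codon_rate_matrix(kappa = 3, omega = 0.2, fr)
  # synonymous transition vs nonsynonymous transversion with uniform pi
  i <- which(chlorosel:::SENSE_CODONS == "TTT")
  j_syn_ts <- which(chlorosel:::SENSE_CODONS == "TTC") # Phe -> Phe, T<->C
  j_non_tv <- which(chlorosel:::SENSE_CODONS == "TTA") # Phe -> Leu, T<->A
  expect_equal(m$Q[i, j_syn_ts] / m$Q[i, j_non_tv], 3 / 0.2, tolerance = 1e-10)
  # no multi-nucleotide changes
  expect_equal(m$Q[i, which(chlorosel:::SENSE_CODONS == "CCT")], 0)
  # rows sum to zero, detailed balance, unit mean rate
  expect_lt(max(abs(rowSums(m$Q))), 1e-10)
  flow <- m$pi * m$Q
  expect_lt(max(abs(flow - t(flow))), 1e-12)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  # omega = kappa = 1 with uniform pi: all permitted rates equal
  m1 <- codon_rate_matrix(1, 1, fr)
  off <- m1$Q[m1$Q > 0]
  expect_lt(diff(range(off)), 1e-12)
  expect_error(codon_rate_matrix(-1, 0.5, fr), "kappa")
  expect_error(codon_rate_matrix(2, -0.1, fr), "omega")
})

test_that("general reversible builder matches a 3-state hand computation", {
  S <- matrix(c(0, 1, 2,
                1, 0, 3,
                2, 3, 0), 3, 3)
  f <- c(0.5, 0.3, 0.2)
  m <- reversible_rate_matrix(S, f)
  # hand: Q_raw[1,2] = 1*0.3, Q_raw[1,3] = 2*0.2, Q_raw[2,3] = 3*0.2
  raw <- matrix(c(0, .3, .4, .5, 0, .6, 1.0, .9, 0), 3, 3, byrow = TRUE)
  diag(raw) <- -rowSums(raw)
  scale <- -sum(f * diag(raw))
  expect_equal(unname(m$Q), raw / scale, tolerance = 1e-12)
  flow <- f * m$Q
  expect_lt(max(abs(flow - t(flow))), 1e-12)
  expect_error(reversible_rate_matrix(matrix(1:9, 3), f), "symmetric")
})

test_that("amino-acid matrices are reversible with gene frequencies", {
  ex <- aa_exchangeabilities("cpREV")
  expect_true(isSymmetric(unname(ex$S)))
  expect_equal(sum(ex$freq), 1, tolerance = 1e-6)
  aln <- sim_codon(tree4(), 60, seed = 9)
  f <- aa_frequencies(translate_alignment(aln))
  expect_true(all(f > 0)) # pseudocount guarantees positivity
  m <- aa_rate_matrix(ex$S, f)
  flow <- m$pi * m$Q
  expect_lt(max(abs(flow - t(flow))), 1e-12)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
})

test_that("PAML .dat layout reads row-wise lower triangle plus frequencies", {
  path <- tempfile(fileext = ".dat")
  # 3 known values placed at (2,1), (3,1), (3,2) positions of PAML order A,R,N
  tri <- numeric(190)
  tri[1:3] <- c(10, 20, 30)
  freqs <- rep(0.05, 20)
  writeLines(c(paste(tri[1]), paste(tri[2], tri[3]),
               paste(tri[4:190], collapse = " "),
               paste(freqs, collapse = " ")), path)
  got <- read_paml_dat(path)
  expect_equal(got$S["A", "R"], 10)
  expect_equal(got$S["A", "N"], 20)
  expect_equal(got$S["R", "N"], 30)
  expect_equal(unname(got$freq), rep(0.05, 20))
})

test_that("transition matrices are exact against a series-expansion oracle", {
  fr <- uniform_codon_frequencies()
  m <- codon_rate_matrix(2.5, 0.4, fr)
  expect_equal(transition_matrix(m, 0), diag(61), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- transition_matrix(m, 0.3)
  expect_equal(unname(P), unname(expm_series(m$Q, 0.3)), tolerance = 1e-9)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  # ergodic limit: every row converges to pi
  P50 <- transition_matrix(m, 50)
  expect_lt(max(abs(sweep(P50, 2, m$pi))), 1e-5)
  expect_lt(max(abs(sweep(transition_matrix(m, 100), 2, m$pi))), 1e-9)
  # semigroup property
  P1 <- transition_matrix(m, 0.1); P2 <- transition_matrix(m, 0.25)
  expect_equal(P1 %*% P2, transition_matrix(m, 0.35), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(transition_matrix(m, -0.1), "argument error")
})
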