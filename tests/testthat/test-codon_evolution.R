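test_that("NG86 site counts match neighbor enumeration and sum to 3", {
  expect_equal(codon_site_counts("TTT"), c(s_sites = 1/3, n_sites = 8/3))
  expect_equal(codon_site_counts("GGG"), c(s_sites = 1, n_sites = 2))
  expect_equal(codon_site_counts("ATG"), c(s_sites = 0, n_sites = 3))
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (cod in sense) {
    got <- codon_site_counts(cod)
    want <- oracle_sites(cod)
    expect_equal(unname(got[1]), unname(want[1]), tolerance = 1e-12)
    expect_equal(sum(got), 3)
  }
  expect_error(codon_site_counts("TAA"), "sense")
})

test_that("pathway-averaged difference counts follow the NG86 rules", {
  expect_equal(count_pair_differences("GTT", "GTA"), c(sd = 1, nd = 0))
  expect_equal(count_pair_differences("TTT", "TTA"), c(sd = 0, nd = 1))
  # two pathways: via GTT (1N+1S), via TTA (2N) -> average (0.5, 1.5)
  expect_equal(count_pair_differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_equal(count_pair_differences("AAA", "AAA"), c(sd = 0, nd = 0))
  set.seed(41)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (i in 1:50) {
    a <- sample(sense, 1)
    b <- sample(sense, 1)
    expect_equal(unname(count_pair_differences(a, b)),
                 unname(oracle_pair_diff(a, b)), tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction matches its closed form and saturates", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.05), -0.75 * log(1 - 0.2 / 3))
  expect_true(is.na(jukes_cantor(0.75)))
  expect_error(jukes_cantor(-0.1), "non-negative")
  # monotone on [0, 3/4)
  p <- seq(0, 0.74, by = 0.01)
  expect_true(all(diff(jukes_cantor(p)) > 0))
})

test_that("codon alignments drop gap, N and stop columns with a tally", {
  aln <- codon_alignment(c("ATGAAA", "ATGAAA"))
  expect_equal(aln$n_columns_used, 2L)
  expect_equal(aln$n_columns_dropped, 0L)

  aln <- codon_alignment(c("ATG---AAA", "ATGCCCAAA"))
  expect_equal(aln$n_columns_used, 2L)
  expect_equal(aln$n_columns_dropped, 1L)
  # origins skip the gap on the gapped sequence only
  expect_equal(aln$column_origin[1, ], c(0L, 1L))
  expect_equal(aln$column_origin[2, ], c(0L, 2L))

  aln <- codon_alignment(c("ATGAAATAAGGG", "ATGAAACCCGGG"))  # TAA stop at col 3
  expect_equal(aln$n_columns_used, 3L)
  expect_equal(aln$n_columns_dropped, 1L)

  aln <- codon_alignment(c("ATGANA", "ATGAAA"))
  expect_equal(aln$n_columns_used, 1L)
})

test_that("protein-guided back-translation reproduces source codons", {
  # MK-F vs MKEF: gap column in the first protein row
  aln <- build_codon_alignment(c("ATGAAATTT", "ATGAAAGAGTTC"),
                               c("MK-F", "MKEF"))
  expect_equal(aln$n_columns_used, 3L)
  expect_equal(aln$n_columns_dropped, 1L)
  expect_equal(unname(aln$codons[, 3]), c("TTT", "TTC"))
  expect_error(build_codon_alignment(c("ATGCCCTTT", "ATGAAATTT"), c("MKF", "MKF")),
               "codon 2")
  expect_error(build_codon_alignment(c("ATGAAA", "ATGAAATTT"), c("MKF", "MKF")),
               "longer than its CDS")
})

test_that("pairwise divergence matches the brute-force oracle and is symmetric", {
  aln <- codon_alignment(c("ATGAAA", "ATGAAA"))
  est <- pairwise_divergence(aln)
  expect_equal(est$ds, 0)
  expect_equal(est$dn, 0)
  expect_true(is.na(est$omega))

  # 100 copies of a (GTT, GTA) column: one synonymous change per codon
  a <- strrep("GTT", 100)
  b <- strrep("GTA", 100)
  est <- pairwise_divergence(codon_alignment(c(a, b)))
  expect_equal(est$sd, 100)
  expect_equal(est$nd, 0)
  expect_equal(est$dn, 0)

  set.seed(7)
  for (i in 1:20) {
    sa <- random_sense_cds(40)
    sb <- random_sense_cds(40)
    est <- pairwise_divergence(codon_alignment(c(sa, sb)))
    want <- oracle_ng86(sa, sb)
    expect_equal(est$sd, want$sd, tolerance = 1e-12)
    expect_equal(est$nd, want$nd, tolerance = 1e-12)
    expect_equal(est$s_sites, want$S, tolerance = 1e-12)
    if (!est$saturated) expect_equal(est$ds, want$ds, tolerance = 1e-12)
    swapped <- pairwise_divergence(codon_alignment(c(sb, sa)))
    expect_equal(est$ds, swapped$ds)
    expect_equal(est$dn, swapped$dn)
  }
})

test_that("4DTv counts fourfold sites and transversions as defined", {
  expect_equal(fourdtv(codon_alignment(c("GGA", "GGT")))$rate, 1)   # A<->T tv
  expect_equal(fourdtv(codon_alignment(c("GGA", "GGG")))$rate, 0)   # A<->G ts
  r <- fourdtv(codon_alignment(c("TTT", "TTC")))                    # twofold
  expect_equal(r$n_fourfold_sites, 0L)
  expect_true(is.na(r$rate))
  # swap invariance
  set.seed(11)
  sa <- random_sense_cds(200)
  sb <- random_sense_cds(200)
  expect_equal(fourdtv(codon_alignment(c(sa, sb)))$rate,
               fourdtv(codon_alignment(c(sb, sa)))$rate)
})

test_that("sliding windows tile the alignment as floor((L-w)/s)+1", {
  a <- random_sense_cds(100)
  prof <- sliding_window_dnds(codon_alignment(c(a, a)))
  expect_equal(nrow(prof), floor((300 - 150) / 30) + 1)
  expect_equal(prof$window_start_bp, seq(0, 150, 30))
  expect_equal(prof$window_end_bp, seq(150, 300, 30))
  expect_true(all(prof$ds == 0))
  expect_true(all(is.na(prof$omega)))
  short <- sliding_window_dnds(codon_alignment(c("ATGAAATTT", "ATGAAATTT")))
  expect_equal(nrow(short), 1L)
  expect_true(short$truncated)
  expect_error(sliding_window_dnds(codon_alignment(c(a, a)), window_bp = 100),
               "multiples of 3")
})

test_that("branch assignment follows the outgroup parsimony rule", {
  aln <- codon_alignment(c("TTC", "TTT", "TTT"), labels = c("p1", "p2", "og"))
  bd <- branch_divergence(aln, "og")
  expect_equal(bd$sd[bd$branch == "p1"], 1)
  expect_equal(bd$nd[bd$branch == "p1"], 0)
  expect_equal(bd$sd[bd$branch == "p2"], 0)

  aln <- codon_alignment(c("TTT", "TTT", "TTC"), labels = c("p1", "p2", "og"))
  bd <- branch_divergence(aln, "og")
  expect_equal(sum(bd$sd + bd$nd), 0)

  aln <- codon_alignment(c("TTA", "TTC", "TTG"), labels = c("p1", "p2", "og"))
  bd <- branch_divergence(aln, "og")
  expect_equal(unique(bd$n_ambiguous), 1L)
  expect_equal(sum(bd$sd + bd$nd), 0)

  expect_error(branch_divergence(aln, "nope"), "outgroup label")
})

test_that("summed branch differences never exceed the pairwise total", {
  set.seed(23)
  for (i in 1:10) {
    anc <- sim_ancestral_cds(80)
    tri <- sim_triple(anc, branch_omegas = list(outgroup = 0.3, p1 = 0.3, p2 = 0.3),
                      target_ds_per_branch = c(outgroup = 0.4, p1 = 0.15, p2 = 0.15))
    aln3 <- codon_alignment(c(tri$p1, tri$p2, tri$outgroup),
                            labels = c("p1", "p2", "og"))
    bd <- branch_divergence(aln3, "og")
    pw <- pairwise_divergence(codon_alignment(c(tri$p1, tri$p2)))
    expect_lte(sum(bd$sd), pw$sd + 1e-9)
    expect_lte(sum(bd$nd), pw$nd + 1e-9)
  }
})

test_that("the neutrality screen is the stated two-sided exact binomial", {
  # counts exactly at the neutral expectation: p ~ 1
  est <- structure(list(sd = 25, nd = 75, s_sites = 100, n_sites = 300),
                   class = "divergence_estimate")
  expect_gt(neutrality_screen(est), 0.9)
  # boundary case nd = 20, sd = 0 at p0 = 0.75: small-p summation
  est <- structure(list(sd = 0, nd = 20, s_sites = 5, n_sites = 15),
                   class = "divergence_estimate")
  expect_equal(neutrality_screen(est), oracle_binom_two_sided(20, 20, 0.75),
               tolerance = 1e-12)
  est <- structure(list(sd = 0.2, nd = 0.2, s_sites = 5, n_sites = 15),
                   class = "divergence_estimate")
  expect_true(is.na(neutrality_screen(est)))
  # random cases against the density-summation oracle
  set.seed(5)
  for (i in 1:25) {
    sd <- rpois(1, 20)
    nd <- rpois(1, 40)
    if (sd + nd == 0) next
    est <- structure(list(sd = sd, nd = nd, s_sites = 120, n_sites = 360),
                     class = "divergence_estimate")
    expect_equal(neutrality_screen(est),
                 oracle_binom_two_sided(nd, sd + nd, 0.75), tolerance = 1e-10)
  }
})
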