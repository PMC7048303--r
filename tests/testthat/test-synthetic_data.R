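test_that("ancestral CDS start with ATG, avoid stops and are seed-determined", {
  expect_equal(sim_ancestral_cds(1, seed = 1), "ATG")
  a <- sim_ancestral_cds(500, seed = 7)
  expect_identical(sim_ancestral_cds(500, seed = 7), a)
  codons <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"))
})

test_that("evolve_pair honours target dS = 0, determinism and saturation", {
  anc <- sim_ancestral_cds(50, seed = 2)
  ev0 <- evolve_pair(anc, 0)
  expect_identical(ev0$cds_a, anc)
  expect_identical(ev0$cds_b, anc)
  ev1 <- evolve_pair(anc, 0.3, seed = 9)
  ev2 <- evolve_pair(anc, 0.3, seed = 9)
  expect_identical(ev1, ev2)
  expect_error(evolve_pair(anc, 50), "saturation")
  expect_error(evolve_pair(anc, -1), "non-negative")
})

test_that("omega = 0 yields essentially no nonsynonymous divergence", {
  anc <- sim_ancestral_cds(10000, seed = 3)
  ev <- evolve_pair(anc, 0.3, omega = 0, kappa = 2, seed = 4)
  est <- pairwise_divergence(codon_alignment(c(ev$cds_a, ev$cds_b)))
  expect_lte(est$dn, 0.005)
  expect_lt(abs(est$ds - 0.3), 0.03)
})

test_that("neutral calibration recovers omega near 1 when NG86 assumptions hold", {
  # without transition/transversion bias the NG86 estimator is unbiased;
  # under kappa > 1 it carries a known mild downward bias
  anc <- sim_ancestral_cds(10000, seed = 5)
  ev <- evolve_pair(anc, 0.3, omega = 1, kappa = 1, seed = 6)
  est <- pairwise_divergence(codon_alignment(c(ev$cds_a, ev$cds_b)))
  expect_lt(abs(est$omega - 1), 0.05)
})

test_that("omega windows confine elevated divergence to their codons", {
  anc <- sim_ancestral_cds(4000, seed = 11)
  ow <- data.frame(start_codon = 1001, end_codon = 2000, omega = 2)
  ev <- evolve_pair(anc, 0.4, omega = 0.05, kappa = 2, seed = 12,
                    omega_windows = ow)
  aln <- codon_alignment(c(ev$cds_a, ev$cds_b))
  inside <- codon_alignment(c(substr(ev$cds_a, 3001, 6000),
                              substr(ev$cds_b, 3001, 6000)))
  outside <- codon_alignment(c(substr(ev$cds_a, 1, 3000),
                               substr(ev$cds_b, 1, 3000)))
  expect_gt(pairwise_divergence(inside)$omega,
            5 * pairwise_divergence(outside)$omega)
})

test_that("pair sets round-trip through the catalog and carry truth", {
  ps <- sim_pair_set(30, 40, n_codons = 60, seed = 13)
  expect_equal(nrow(ps$truth), 70L)
  filt <- filter_genes(cbind(ps$genes, is_te = FALSE), ps$hits)
  expect_equal(nrow(filt$exclusions), 0L)
  pairs <- make_pairs(filt$retained, ps$hits)
  expect_equal(pairs$gene_a, sort(ps$truth$gene_a))
  expect_equal(nrow(pairs), 70L)
  # n_ssd = 0: all truth in one class
  ps0 <- sim_pair_set(15, 0, n_codons = 40, seed = 14)
  expect_true(all(ps0$truth$class == "wgd"))
})

test_that("triples honour zero branch lengths and branch symmetry", {
  anc <- sim_ancestral_cds(2000, seed = 15)
  tri0 <- sim_triple(anc, list(outgroup = 0.2, p1 = 0.2, p2 = 0.2),
                     c(outgroup = 0, p1 = 0, p2 = 0))
  expect_identical(tri0$p1, anc)
  expect_identical(tri0$outgroup, anc)

  tri <- sim_triple(anc, list(outgroup = 0.2, p1 = 0.2, p2 = 0.2),
                    c(outgroup = 0.5, p1 = 0.2, p2 = 0.2), seed = 16)
  aln3 <- codon_alignment(c(tri$p1, tri$p2, tri$outgroup),
                          labels = c("p1", "p2", "og"))
  bd <- branch_divergence(aln3, "og")
  s1 <- bd$sd[bd$branch == "p1"] + bd$nd[bd$branch == "p1"]
  s2 <- bd$sd[bd$branch == "p2"] + bd$nd[bd$branch == "p2"]
  expect_lt(abs(s1 - s2) / max(s1, s2), 0.25)   # equal within sampling error
})

test_that("expression generator is deterministic and bounds false positives", {
  s1 <- sim_expression(40, 0.5, seed = 17)
  s2 <- sim_expression(40, 0.5, seed = 17)
  expect_identical(s1$expr$values, s2$expr$values)

  cons <- sim_expression(600, 0, seed = 18)
  res <- pair_expression_analysis(cons$pairs, cons$expr, cons$stage_phase)
  expect_lte(mean(res$divergent, na.rm = TRUE), 0.02)
})

test_that("planted sex bias at adequate depth is detected by the Fisher screen", {
  sim <- sim_expression(150, 0, seed = 19, n_bias_pairs = 100, bias_odds = 10)
  res <- pair_expression_analysis(sim$pairs, sim$expr, sim$stage_phase)
  biased <- sim$truth$bias_odds > 0
  expect_gte(mean(res$fisher_p_developing[biased] < 0.01), 0.95)
})

test_that("sex contig simulation matches its planted layout and seed", {
  layout <- data.frame(start = c(0, 5000), end = c(5000, 10000),
                       class = c("male-specific", "PAR-like"))
  sc <- sim_sex_contig(10000, layout, seed = 20)
  expect_identical(sim_sex_contig(10000, layout, seed = 20)$track, sc$track)
  msy <- sc$track$female_depth[1:5000]
  expect_lte(mean(msy), 0.01)
  expect_equal(mean(sc$track$male_depth[1:5000]), 20, tolerance = 0.5)
  expect_error(sim_sex_contig(100, data.frame(start = 0, end = 200,
                                              class = "background")),
               "within")
})

test_that("truth sidecars serialize as JSON next to the data", {
  f <- withr::local_tempfile(fileext = ".json")
  truth <- data.frame(gene_a = "x_a", gene_b = "x_b", true_ds = 0.5)
  write_sim_truth(truth, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$true_ds, 0.5)
})
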