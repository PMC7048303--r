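flat_track <- function(male, female, len = 2000) {
  depth_track("c", rep(male, len), rep(female, len))
}

test_that("windowed ratios summarize depth as specified", {
  w <- windowed_ratio(flat_track(20, 20, 1000), window_bp = 500)
  expect_equal(nrow(w), 2L)
  expect_equal(w$female_read_fraction, c(0.5, 0.5))
  expect_false(any(w$repetitive))

  w <- windowed_ratio(flat_track(20, 0, 500), window_bp = 500)
  expect_equal(w$female_read_fraction, 0)

  w <- windowed_ratio(flat_track(90, 90, 500), window_bp = 500,
                      expected_depth = 20)
  expect_true(w$repetitive)   # (90+90)/2 > 2*20

  w <- windowed_ratio(flat_track(0, 0, 500), window_bp = 500)
  expect_true(is.na(w$female_read_fraction))

  expect_error(windowed_ratio(flat_track(1, 1, 200), window_bp = 50), "at least 100")
})

test_that("region classes follow the depth rules and the PAR length rule", {
  classify <- function(male, female, len) {
    classify_regions(windowed_ratio(flat_track(male, female, len)))
  }
  expect_equal(classify(20, 14, 5000)$call, "PAR-like")       # frac 0.41, 5 kb
  expect_equal(classify(20, 14, 2000)$call, "undetermined")   # <= 3 kb
  expect_equal(classify(20, 14, 3000)$call, "undetermined")   # boundary: strictly > 3 kb
  expect_equal(classify(20, 14, 3500)$call, "PAR-like")
  expect_equal(classify(20, 0, 5000)$call, "male-specific")
  expect_equal(classify(90, 90, 5000)$call, "repetitive")
  expect_equal(classify(5, 0, 5000)$call, "undetermined")     # male depth < half expected
})

test_that("region calls merge idempotently and deterministically", {
  layout <- data.frame(start = c(0, 8000, 12000, 32000),
                       end = c(8000, 12000, 32000, 40000),
                       class = c("PAR-like", "repetitive", "male-specific",
                                 "PAR-like"))
  sc <- sim_sex_contig(40000, layout, seed = 5, noise = FALSE)
  w <- windowed_ratio(sc$track)
  calls <- classify_regions(w)
  expect_equal(calls$call, layout$class)
  expect_equal(calls$start, layout$start)
  expect_equal(calls$end, layout$end)
  expect_identical(merge_region_calls(calls), calls)
  expect_identical(classify_regions(w), calls)
})

test_that("the female fraction is scale-invariant; the repetitive flag is not", {
  layout <- data.frame(start = c(0, 10000), end = c(10000, 20000),
                       class = c("male-specific", "PAR-like"))
  sc <- sim_sex_contig(20000, layout, seed = 9, noise = FALSE)
  tr3 <- depth_track("c", sc$track$male_depth * 3, sc$track$female_depth * 3)
  w1 <- windowed_ratio(sc$track)
  w3 <- windowed_ratio(tr3)
  expect_equal(w1$female_read_fraction, w3$female_read_fraction)
  expect_true(any(w3$repetitive) && !any(w1$repetitive))
})

test_that("X-Y divergence tables anchor distances and baselines", {
  set.seed(14)
  anc <- sim_ancestral_cds(150)
  same <- codon_alignment(c(anc, anc))
  ev <- evolve_pair(anc, 0.3, seed = 15)
  div <- codon_alignment(c(ev$cds_a, ev$cds_b))
  pos <- data.frame(gene_id = c("g0", "g1"), start = c(900, 5000),
                    end = c(1100, 5400))
  tab <- xy_divergence_table(
    list(g0 = same, g1 = div), pos, anchor_position = 1000,
    baseline_alignments = list(
      g1 = list(spA = codon_alignment(c(evolve_pair(anc, 0.05, seed = 16)$cds_a,
                                        anc)))))
  expect_equal(tab$ds_xy[tab$gene_id == "g0"], 0)
  expect_equal(tab$distance_to_anchor[tab$gene_id == "g0"], 0)
  expect_equal(tab$distance_to_anchor[tab$gene_id == "g1"], 4200)
  expect_true(tab$exceeds_interspecific[tab$gene_id == "g1"])
  expect_warning(
    xy_divergence_table(list(gX = same), pos, 1000),
    "no coordinates")
})

test_that("divergence decay reports Spearman rho with tie and size guards", {
  tab <- data.frame(gene_id = letters[1:5],
                    distance_to_anchor = c(1, 2, 3, 4, 5) * 1e4,
                    ds_xy = c(0.5, 0.4, 0.3, 0.2, 0.1),
                    exceeds_interspecific = TRUE)
  out <- divergence_decay(tab)
  expect_equal(out$rho, -1)
  expect_equal(out$n_exceeding, 5L)

  flat <- tab
  flat$ds_xy <- 0.3
  out <- divergence_decay(flat)
  expect_true(out$constant)
  expect_true(is.na(out$rho))

  out <- divergence_decay(tab[1:3, ])
  expect_true(out$insufficient)
})

test_that("a planted monotone dS gradient yields negative rho", {
  set.seed(18)
  neg <- 0L
  for (rep in 1:10) {
    anc <- sim_ancestral_cds(120)
    genes <- paste0("g", 1:6)
    ds_true <- seq(0.45, 0.1, length.out = 6)
    alns <- lapply(ds_true, function(d) {
      ev <- evolve_pair(anc, d)
      codon_alignment(c(ev$cds_a, ev$cds_b))
    })
    names(alns) <- genes
    pos <- data.frame(gene_id = genes, start = (1:6) * 1e4, end = (1:6) * 1e4 + 400)
    tab <- xy_divergence_table(alns, pos, anchor_position = 0)
    if (divergence_decay(tab)$rho < 0) neg <- neg + 1L
  }
  expect_gte(neg, 9L)
})
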