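# Dataset-level generators with serializable ground truth: WGD-burst pair
# sets, paired expression matrices with planted divergence and sex bias,
# and male/female depth tracks with a planted region layout.

#' Simulate a paralog pair set with a WGD burst over an SSD background
#'
#' WGD pairs draw their true dS from a lognormal burst (median
#' `burst_ds_mean`, log-sd `burst_ds_sd`); small-scale-duplication pairs
#' draw theirs from an exponential background (mean `ssd_ds_mean`).  Each
#' pair is an independent [evolve_pair()] run from its own random ancestor;
#' a synthetic hit table consistent with [make_pairs()] input is emitted
#' alongside.
#'
#' @param n_wgd,n_ssd numbers of burst and background pairs
#' @param burst_ds_mean burst centre (median of the lognormal), default
#'   0.69
#' @param burst_ds_sd lognormal sigma of the burst, default 0.08
#' @param ssd_ds_mean mean of the exponential background, default 0.15
#' @param omega nonsynonymous acceptance ratio: a scalar, or a function of
#'   `n` returning per-pair draws
#' @param kappa transition/transversion ratio
#' @param n_codons gene length in codons
#' @param seed RNG seed
#' @return list with `genes` (data.frame `gene_id`, `cds`), `hits`
#'   (outfmt-6-compatible columns), and `truth` (per-pair `gene_a`,
#'   `gene_b`, `class`, `true_ds`, `omega`)
#' @export
sim_pair_set <- function(n_wgd, n_ssd, burst_ds_mean = 0.69,
                         burst_ds_sd = 0.08, ssd_ds_mean = 0.15,
                         omega = 0.2, kappa = 2, n_codons = 300, seed = 1) {
  set.seed(seed)
  n <- n_wgd + n_ssd
  true_ds <- c(stats::rlnorm(n_wgd, log(burst_ds_mean), burst_ds_sd),
               stats::rexp(n_ssd, 1 / ssd_ds_mean))
  omegas <- if (is.function(omega)) omega(n) else rep_len(omega, n)
  cls <- rep(c("wgd", "ssd"), c(n_wgd, n_ssd))
  ids_a <- sprintf("g%05d_a", seq_len(n))
  ids_b <- sprintf("g%05d_b", seq_len(n))
  cds_a <- cds_b <- character(n)
  for (i in seq_len(n)) {
    anc <- sim_ancestral_cds(n_codons)
    ev <- evolve_pair(anc, target_ds = true_ds[i], omega = omegas[i],
                      kappa = kappa)
    cds_a[i] <- ev$cds_a
    cds_b[i] <- ev$cds_b
  }
  genes <- data.frame(gene_id = c(rbind(ids_a, ids_b)),
                      cds = c(rbind(cds_a, cds_b)), stringsAsFactors = FALSE)
  hits <- data.frame(query_id = pmin(ids_a, ids_b),
                     subject_id = pmax(ids_a, ids_b),
                     evalue = rep(1e-180, n), bitscore = rep(500, n),
                     stringsAsFactors = FALSE)
  truth <- data.frame(gene_a = pmin(ids_a, ids_b), gene_b = pmax(ids_a, ids_b),
                      class = cls, true_ds = true_ds, omega = omegas,
                      stringsAsFactors = FALSE)
  list(genes = genes, hits = hits, truth = truth)
}

#' Simulate paired expression profiles with planted divergence and sex bias
#'
#' Sixteen samples (`n_stages` stages x 2 sexes).  Conserved pairs share a
#' latent log-expression profile across the series plus small independent
#' noise; divergent pairs draw independent profiles.  Counts are negative
#' binomial around the profile means.  The first `n_bias_pairs` conserved
#' pairs carry a male/female odds shift of `bias_odds` in one paralog only.
#' The number of divergent pairs is planted exactly
#' (`round(frac_divergent * n_pairs)`).
#'
#' @param n_pairs number of paralog pairs
#' @param frac_divergent planted fraction of expression-divergent pairs
#' @param n_stages number of developmental stages (default 8; the first
#'   half are labelled phase `developing`, the rest `mature`)
#' @param seed RNG seed
#' @param n_bias_pairs number of pairs with a planted sex bias
#' @param bias_odds multiplicative male/female shift applied to paralog A
#'   of the biased pairs
#' @param base_log_mean log mean expression level (default `log(300)`)
#' @param profile_sd sd of the shared latent log-profile (default 1.3)
#' @param noise_sd sd of the independent per-sample log-noise on conserved
#'   pairs (default 0.15; realizes a conserved r-squared near 0.8 together
#'   with the counting noise)
#' @param dispersion negative-binomial dispersion (default 0.1)
#' @return list with `expr` (an [expression_matrix()] of counts), `pairs`
#'   (`gene_a`, `gene_b`), `stage_phase` (named map stage -> phase), and
#'   `truth` (per-pair `divergent`, `bias_odds`)
#' @export
sim_expression <- function(n_pairs, frac_divergent, n_stages = 8, seed = 1,
                           n_bias_pairs = 0, bias_odds = 10,
                           base_log_mean = log(300), profile_sd = 1.3,
                           noise_sd = 0.15, dispersion = 0.1) {
  set.seed(seed)
  n_samples <- 2L * n_stages
  stage <- rep(paste0("S", seq_len(n_stages)), each = 2L)
  sex <- rep(c("M", "F"), n_stages)
  sample_ids <- paste(stage, sex, sep = "_")
  n_div <- round(frac_divergent * n_pairs)
  divergent <- rep(c(FALSE, TRUE), c(n_pairs - n_div, n_div))
  divergent <- divergent[sample.int(n_pairs)]   # interleave classes
  bias <- rep(0, n_pairs)
  if (n_bias_pairs > 0) {
    cons <- which(!divergent)
    bias[cons[seq_len(min(n_bias_pairs, length(cons)))]] <- bias_odds
  }
  size <- 1 / dispersion
  ids_a <- sprintf("p%05d_a", seq_len(n_pairs))
  ids_b <- sprintf("p%05d_b", seq_len(n_pairs))
  values <- matrix(0, 2L * n_pairs, n_samples,
                   dimnames = list(c(rbind(ids_a, ids_b)), sample_ids))
  for (i in seq_len(n_pairs)) {
    base_a <- stats::rnorm(1, base_log_mean, 0.5)
    base_b <- stats::rnorm(1, base_log_mean, 0.5)
    z <- stats::rnorm(n_samples, 0, profile_sd)
    za <- if (divergent[i]) stats::rnorm(n_samples, 0, profile_sd) else
      z + stats::rnorm(n_samples, 0, noise_sd)
    zb <- if (divergent[i]) stats::rnorm(n_samples, 0, profile_sd) else
      z + stats::rnorm(n_samples, 0, noise_sd)
    mu_a <- exp(base_a + za)
    mu_b <- exp(base_b + zb)
    if (bias[i] > 0) mu_a[sex == "M"] <- mu_a[sex == "M"] * bias[i]
    values[2L * i - 1L, ] <- stats::rnbinom(n_samples, size = size, mu = mu_a)
    values[2L * i, ] <- stats::rnbinom(n_samples, size = size, mu = mu_b)
  }
  phase <- stats::setNames(
    rep(c("developing", "mature"), c(ceiling(n_stages / 2), floor(n_stages / 2))),
    paste0("S", seq_len(n_stages)))
  list(expr = expression_matrix(values, sex = sex, stage = stage, unit = "counts"),
       pairs = data.frame(gene_a = ids_a, gene_b = ids_b, stringsAsFactors = FALSE),
       stage_phase = phase,
       truth = data.frame(gene_a = ids_a, gene_b = ids_b,
                          divergent = divergent, bias_odds = bias,
                          stringsAsFactors = FALSE))
}

#' Simulate male/female depth tracks over a contig with a planted layout
#'
#' Per-position Poisson depths (or exact expected depths when
#' `noise = FALSE`) according to the planted segment classes:
#' `male-specific` (male at the expected single-copy depth, female 0),
#' `PAR-like` (male at expected depth, female such that the female read
#' fraction equals `par_female_frac`), `repetitive` (both at four times the
#' expected depth) and `background` (both at the expected depth).
#'
#' @param length_bp contig length
#' @param layout data.frame `start`, `end` (0-based half-open, covering the
#'   contig), `class` in `male-specific`, `PAR-like`, `repetitive`,
#'   `background`
#' @param expected_depth expected single-copy depth (default 20)
#' @param seed RNG seed
#' @param noise Poisson noise (default) or exact expected depths
#' @param par_female_frac planted female read fraction in PAR-like
#'   segments (default 0.5)
#' @param contig contig name
#' @return list with `track` (a [depth_track()]) and `truth` (the layout)
#' @export
sim_sex_contig <- function(length_bp, layout, expected_depth = 20, seed = 1,
                           noise = TRUE, par_female_frac = 0.5,
                           contig = "Ycontig") {
  if (!all(layout$class %in% c("male-specific", "PAR-like", "repetitive",
                               "background"))) {
    stop("unknown layout class", call. = FALSE)
  }
  if (any(layout$start < 0 | layout$end > length_bp | layout$end <= layout$start)) {
    stop("layout segments must be within [0, length_bp) with end > start",
         call. = FALSE)
  }
  set.seed(seed)
  lam_m <- rep(expected_depth, length_bp)
  lam_f <- rep(expected_depth, length_bp)
  f_par <- expected_depth * par_female_frac / (1 - par_female_frac)
  for (i in seq_len(nrow(layout))) {
    span <- (layout$start[i] + 1L):layout$end[i]
    switch(layout$class[i],
      "male-specific" = { lam_f[span] <- 0 },
      "PAR-like" = { lam_f[span] <- f_par },
      "repetitive" = { lam_m[span] <- 4 * expected_depth
                       lam_f[span] <- 4 * expected_depth },
      "background" = {})
  }
  if (noise) {
    male <- stats::rpois(length_bp, lam_m)
    female <- stats::rpois(length_bp, lam_f)
  } else {
    male <- lam_m
    female <- lam_f
  }
  list(track = depth_track(contig, male, female), truth = layout)
}

#' Score region calls against a planted layout
#'
#' Base-level confusion between the planted classes and the calls
#' (positions not covered by any call count as `undetermined`).  Planted
#' `background` bases score as correct when called `PAR-like` or
#' `undetermined`, since single-copy two-sex coverage is exactly the
#' pseudoautosomal depth signature.
#'
#' @param calls region calls from [classify_regions()]
#' @param layout planted layout (`start`, `end`, `class`)
#' @param length_bp contig length
#' @return list with `accuracy` and the base-level `confusion` table
#' @export
score_region_calls <- function(calls, layout, length_bp) {
  paint <- function(df, class_col) {
    v <- rep("undetermined", length_bp)
    for (i in seq_len(nrow(df))) {
      v[(df$start[i] + 1L):min(df$end[i], length_bp)] <- df[[class_col]][i]
    }
    v
  }
  truth <- paint(layout, "class")
  called <- paint(calls, "call")
  correct <- called == truth |
    (truth == "background" & called %in% c("PAR-like", "undetermined"))
  list(accuracy = mean(correct), confusion = table(truth = truth, called = called))
}

#' Write simulation ground truth as JSON
#'
#' Serializes a generator's truth object next to its data files so any
#' downstream call can be scored against it.
#'
#' @param truth a truth object (list or data.frame) from a generator
#' @param path output JSON file
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
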