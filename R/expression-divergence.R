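# Paralog expression-divergence classification across the annual
# flower-development series (Pearson r^2), male/female bias testing
# (2x2 Fisher exact on pooled read counts), and fold-bias flags.

#' Pearson expression correlation of a paralog pair
#'
#' Pearson correlation across the ordered sample series (typically 16
#' datapoints: 8 stages x 2 sexes); a pair is called expression-divergent
#' when `r^2 < r2_cutoff` (default 0.3).  Zero-variance profiles give an
#' undefined result, excluded from reported denominators downstream.
#'
#' @param x,y expression profiles of the two paralogs over the same samples
#' @param r2_cutoff divergence threshold on `r^2`
#' @return list with `r`, `r_squared`, `divergent` (all `NA` when either
#'   profile has zero variance or fewer than 3 samples)
#' @export
expression_correlation <- function(x, y, r2_cutoff = 0.3) {
  if (length(x) != length(y)) stop("profiles must have equal length", call. = FALSE)
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, r_squared = NA_real_, divergent = NA))
  }
  r <- stats::cor(x, y, method = "pearson")
  list(r = r, r_squared = r^2, divergent = r^2 < r2_cutoff)
}

#' Two-sided Fisher exact p for 2x2 tables
#'
#' Minimum-likelihood (small-p) summation over the hypergeometric table
#' distribution, the same two-sided convention as `stats::fisher.test`
#' (including its relative tolerance on "as extreme" probabilities).
#' Vectorized over tables so that large enumerations stay cheap.
#'
#' @param a,b,c,d cell counts, row-wise (`a`,`b` top row); vectors recycle
#' @return vector of two-sided p-values; a table with any zero margin
#'   yields `p = 1`
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + b[i]          # row 1 total
    nn <- c[i] + d[i]         # row 2 total
    k <- a[i] + c[i]          # column 1 total
    if (m == 0 || nn == 0 || k == 0 || b[i] + d[i] == 0) {
      p[i] <- 1
      next
    }
    x <- max(0, k - nn):min(k, m)
    dens <- stats::dhyper(x, m, nn, k)
    obs <- stats::dhyper(a[i], m, nn, k)
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  p
}

#' Male/female expression-bias test for a paralog pair
#'
#' Two-sided Fisher exact test on the 2x2 table of pooled read counts, rows
#' = paralogs, columns = sexes, restricted to the samples of one stage
#' phase.  Two-sided by summation of all table probabilities at or below
#' the observed one.  Any zero margin gives `p = 1`, flagged degenerate.
#'
#' @param counts_a,counts_b integer read counts of the two paralogs over
#'   the same samples
#' @param sex per-sample sex (`"M"`/`"F"`)
#' @param use optional logical/index vector selecting the samples of the
#'   stage phase under test
#' @return list with `p`, `table` (2x2 pooled counts), `degenerate`
#' @export
sex_bias_test <- function(counts_a, counts_b, sex, use = NULL) {
  if (!is.null(use)) {
    counts_a <- counts_a[use]
    counts_b <- counts_b[use]
    sex <- sex[use]
  }
  am <- sum(counts_a[sex == "M"])
  af <- sum(counts_a[sex == "F"])
  bm <- sum(counts_b[sex == "M"])
  bf <- sum(counts_b[sex == "F"])
  tab <- matrix(round(c(am, bm, af, bf)), 2,
                dimnames = list(paralog = c("a", "b"), sex = c("M", "F")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else fisher_exact_2x2(tab[1, 1], tab[1, 2],
                                               tab[2, 1], tab[2, 2])
  list(p = p, table = tab, degenerate = degenerate)
}

#' Male/female fold-bias ratios of a paralog pair
#'
#' Per paralog, `log10((male + pseudocount) / (female + pseudocount))` of
#' the pooled expression at the selected samples; the pair is flagged when
#' the two log-ratios differ by more than `log10(fold_cutoff)` (default
#' 5-fold).
#'
#' @param values_a,values_b expression values of the two paralogs
#' @param sex per-sample sex (`"M"`/`"F"`)
#' @param use optional sample selection (stage phase)
#' @param pseudocount added to both pools before the ratio (default 1)
#' @param fold_cutoff fold difference that raises the flag (default 5)
#' @return list with `log10_ratio_a`, `log10_ratio_b`, `fold_flag`
#' @export
fold_bias <- function(values_a, values_b, sex, use = NULL, pseudocount = 1,
                      fold_cutoff = 5) {
  if (!is.null(use)) {
    values_a <- values_a[use]
    values_b <- values_b[use]
    sex <- sex[use]
  }
  ra <- log10((sum(values_a[sex == "M"]) + pseudocount) /
                (sum(values_a[sex == "F"]) + pseudocount))
  rb <- log10((sum(values_b[sex == "M"]) + pseudocount) /
                (sum(values_b[sex == "F"]) + pseudocount))
  list(log10_ratio_a = ra, log10_ratio_b = rb,
       fold_flag = abs(ra - rb) > log10(fold_cutoff))
}

#' Full expression-divergence analysis of a pair catalog
#'
#' Runs [expression_correlation()] over the whole sample series and
#' [sex_bias_test()] plus [fold_bias()] within the developing and mature
#' stage phases for every pair present in the matrix.
#'
#' @param pairs pair catalog (`gene_a`, `gene_b`)
#' @param expr an [expression_matrix()] (counts for the Fisher stage)
#' @param stage_phase named character vector mapping each stage label to
#'   `"developing"` or `"mature"`
#' @param r2_cutoff divergence threshold on `r^2` (default 0.3)
#' @param alpha significance level for the Fisher flags (default 0.01)
#' @param pseudocount,fold_cutoff forwarded to [fold_bias()]
#' @return data.frame with one row per pair: correlation, divergence flag,
#'   per-phase Fisher p and significance flags, log10 male/female ratios
#'   and the >`fold_cutoff`-fold flag
#' @export
pair_expression_analysis <- function(pairs, expr, stage_phase,
                                     r2_cutoff = 0.3, alpha = 0.01,
                                     pseudocount = 1, fold_cutoff = 5) {
  stopifnot(inherits(expr, "expression_matrix"))
  phase <- unname(stage_phase[expr$stage])
  if (anyNA(phase)) {
    stop("stage_phase must map every stage label to 'developing' or 'mature'",
         call. = FALSE)
  }
  dev <- phase == "developing"
  mat <- phase == "mature"
  vals <- expr$values
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]
    gb <- pairs$gene_b[i]
    if (!(ga %in% rownames(vals)) || !(gb %in% rownames(vals))) return(NULL)
    xa <- vals[ga, ]
    xb <- vals[gb, ]
    corr <- expression_correlation(xa, xb, r2_cutoff = r2_cutoff)
    fd <- sex_bias_test(xa, xb, expr$sex, use = dev)
    fm <- sex_bias_test(xa, xb, expr$sex, use = mat)
    bias_d <- fold_bias(xa, xb, expr$sex, use = dev,
                        pseudocount = pseudocount, fold_cutoff = fold_cutoff)
    data.frame(gene_a = ga, gene_b = gb,
               pearson_r = corr$r, r_squared = corr$r_squared,
               divergent = corr$divergent,
               fisher_p_developing = fd$p,
               fisher_p_mature = fm$p,
               significant_developing = !fd$degenerate & fd$p < alpha,
               significant_mature = !fm$degenerate & fm$p < alpha,
               log10_ratio_a = bias_d$log10_ratio_a,
               log10_ratio_b = bias_d$log10_ratio_b,
               fold_flag = bias_d$fold_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  attr(out, "test") <- "counts-based Fisher exact (not a codon-model LRT)"
  out
}

#' Summary fractions of an expression-divergence table
#'
#' @param result output of [pair_expression_analysis()]
#' @return list with the analysed pair count (defined correlations), the
#'   divergent count and percentage, per-phase significant-bias counts and
#'   the fold-flag percentage
#' @export
summarize_expression_divergence <- function(result) {
  defined <- !is.na(result$divergent)
  n <- sum(defined)
  list(n_pairs = n,
       n_divergent = sum(result$divergent[defined]),
       pct_divergent = 100 * sum(result$divergent[defined]) / n,
       n_significant_developing = sum(result$significant_developing, na.rm = TRUE),
       n_significant_mature = sum(result$significant_mature, na.rm = TRUE),
       pct_fold = 100 * mean(result$fold_flag, na.rm = TRUE))
}
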