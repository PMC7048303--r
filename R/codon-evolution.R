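# Codon-level divergence estimation between paralogous coding sequences:
# NG86 site and pathway counting, Jukes-Cantor multiple-hit correction,
# dN/dS, 4DTv, sliding-window profiles, and outgroup-anchored branch
# assignment.

#' Construct a codon alignment from aligned in-frame sequences
#'
#' Takes two or three aligned, in-frame nucleotide sequences (equal length,
#' a multiple of 3; gaps as `-`) and builds the gap-free codon-column
#' alignment on which all divergence estimators operate.  Columns in which
#' any sequence carries a gap, an `N` (or other ambiguity), or a stop codon
#' are excluded at construction and counted in a dropped-column tally.
#'
#' @param sequences character vector of 2 or 3 aligned nucleotide sequences
#'   (same length, multiple of 3).  Lowercase accepted; `U` is mapped to `T`.
#' @param labels sequence labels; defaults to `names(sequences)` or
#'   `seq1`, `seq2`, ...
#' @return An object of class `codon_alignment`: a list with `labels`,
#'   `codons` (matrix, sequences x retained columns, codon strings),
#'   `column_origin` (matrix of 0-based codon indices in each ungapped
#'   source CDS), `n_columns_used` and `n_columns_dropped`.
#' @export
codon_alignment <- function(sequences, labels = NULL) {
  if (!length(sequences) %in% 2:3) {
    stop("a codon alignment needs 2 or 3 sequences", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- names(sequences)
    if (is.null(labels)) labels <- paste0("seq", seq_along(sequences))
  }
  sequences <- toupper(sequences)
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("aligned sequences must have equal length", call. = FALSE)
  if (len %% 3L != 0L) stop("alignment length must be a multiple of 3", call. = FALSE)

  cod <- t(matrix(vapply(sequences, .split_codons, character(len %/% 3L)),
                  ncol = length(sequences)))
  # 0-based codon index of each column in its ungapped source sequence
  origin <- matrix(NA_integer_, nrow(cod), ncol(cod))
  for (i in seq_len(nrow(cod))) {
    ungapped <- !grepl("-", cod[i, ], fixed = TRUE)
    origin[i, ungapped] <- cumsum(ungapped)[ungapped] - 1L
  }
  idx <- matrix(.codon_index(cod), nrow(cod), ncol(cod))
  keep <- colSums(is.na(idx)) == 0L   # drops gaps, Ns, ambiguities, stops
  structure(list(
    labels = labels,
    codons = cod[, keep, drop = FALSE],
    column_origin = origin[, keep, drop = FALSE],
    n_columns_used = sum(keep),
    n_columns_dropped = sum(!keep)
  ), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequences (%s), %d columns used, %d dropped\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              x$n_columns_used, x$n_columns_dropped))
  invisible(x)
}

#' Build a codon alignment from CDS sequences and a protein alignment
#'
#' Back-translates a protein-guided alignment to the codon level: each
#' aligned amino-acid column is replaced by the source codon of the
#' corresponding CDS, checked codon-by-codon against the translation.
#' Terminal stop codons on the CDS are tolerated (dropped as stop columns).
#'
#' @param cds_list list or character vector of 2 or 3 ungapped CDS
#' @param protein_alignment character vector of aligned amino-acid sequences
#'   (same order as `cds_list`, gaps as `-`)
#' @param labels sequence labels
#' @return a [codon_alignment()]
#' @export
build_codon_alignment <- function(cds_list, protein_alignment, labels = NULL) {
  cds_list <- as.character(unlist(cds_list))
  if (length(cds_list) != length(protein_alignment)) {
    stop("need one protein alignment row per CDS", call. = FALSE)
  }
  tb <- codon_tables()
  aligned_nt <- character(length(cds_list))
  for (i in seq_along(cds_list)) {
    cds <- gsub("U", "T", toupper(cds_list[i]), fixed = TRUE)
    codons <- .split_codons(cds)
    aa_row <- .codon_split(toupper(protein_alignment[i]))
    src <- codons[seq_len(sum(aa_row != "-"))]
    if (sum(aa_row != "-") > length(codons)) {
      stop(sprintf("protein row %d is longer than its CDS", i), call. = FALSE)
    }
    # translation check, codon by codon (N-containing codons exempt)
    aa_cds <- tb$gc[src]
    pos <- which(aa_row != "-")
    mism <- which(!is.na(aa_cds) & aa_cds != aa_row[pos] &
                    !(aa_cds == "*" & seq_along(aa_cds) == length(aa_cds)))
    if (length(mism)) {
      stop(sprintf(
        "CDS %d does not translate to its protein alignment row at codon %d (%s -> %s, alignment has %s)",
        i, mism[1], src[mism[1]], aa_cds[mism[1]], aa_row[pos[mism[1]]]),
        call. = FALSE)
    }
    out <- rep("---", length(aa_row))
    out[pos] <- src
    aligned_nt[i] <- paste(out, collapse = "")
  }
  codon_alignment(aligned_nt, labels = labels)
}

#' NG86 synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three codon positions, the fraction of the three
#' single-nucleotide neighbours that encode the same amino acid; neighbours
#' creating stop codons are excluded from the denominator.  The two counts
#' always sum to 3.
#'
#' @param codon a single sense codon over A/C/G/T
#' @return named numeric vector `c(s_sites, n_sites)`
#' @export
codon_site_counts <- function(codon) {
  tb <- codon_tables()
  i <- .codon_index(toupper(codon))
  if (is.na(i)) stop("not a sense codon: ", codon, call. = FALSE)
  c(s_sites = tb$site_s[i], n_sites = tb$site_n[i])
}

#' Pathway-averaged substitution counts between two codons
#'
#' Classifies the nucleotide differences between two sense codons as
#' synonymous or nonsynonymous, averaging over all orderings of the
#' substitutions when they differ at more than one position (NG86).
#' Pathways passing through a stop codon are excluded; in the degenerate
#' case where every pathway does, all pathways are averaged.
#'
#' @param codon_a,codon_b sense codons over A/C/G/T
#' @return named numeric vector `c(sd, nd)`
#' @export
count_pair_differences <- function(codon_a, codon_b) {
  tb <- codon_tables()
  i <- .codon_index(toupper(codon_a))
  j <- .codon_index(toupper(codon_b))
  if (is.na(i) || is.na(j)) stop("both codons must be sense codons", call. = FALSE)
  c(sd = tb$sd[i, j], nd = tb$nd[i, j])
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) log(1 - (4/3) p)` for an observed difference proportion
#' `p < 3/4`; `NA` (saturated) otherwise.
#'
#' @param p observed proportion(s) of differences per site, `p >= 0`
#' @return corrected distance(s); `NA` where saturated
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("p must be non-negative", call. = FALSE)
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

# Core NG86 computation on index matrices (rows = 2 sequences).
.ng86_estimate <- function(ia, ib, n_dropped = 0L, saturation = 0.74) {
  tb <- codon_tables()
  n_used <- length(ia)
  if (n_used == 0L) stop("no retained codon columns", call. = FALSE)
  s_sites <- (sum(tb$site_s[ia]) + sum(tb$site_s[ib])) / 2
  n_sites <- (sum(tb$site_n[ia]) + sum(tb$site_n[ib])) / 2
  sd <- sum(tb$sd[cbind(ia, ib)])
  nd <- sum(tb$nd[cbind(ia, ib)])
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  saturated <- (ps >= saturation) || (pn >= saturation)
  ds <- jukes_cantor(ps)
  dn <- jukes_cantor(pn)
  omega <- if (!saturated && !is.na(ds) && !is.na(dn) && ds > 0) dn / ds else NA_real_
  structure(list(
    s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
    ps = ps, pn = pn, ds = ds, dn = dn, omega = omega,
    saturated = saturated,
    n_columns_used = n_used, n_columns_dropped = n_dropped
  ), class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(
    "divergence_estimate: S=%.2f N=%.2f sd=%.2f nd=%.2f dS=%s dN=%s dN/dS=%s%s (%d columns, %d dropped)\n",
    x$s_sites, x$n_sites, x$sd, x$nd,
    format(x$ds, digits = 4), format(x$dn, digits = 4),
    format(x$omega, digits = 4),
    if (x$saturated) " [saturated]" else "",
    x$n_columns_used, x$n_columns_dropped))
  invisible(x)
}

#' Pairwise NG86 divergence with Jukes-Cantor correction
#'
#' Site counts are averaged over the two sequences; `ps = sd/S` and
#' `pn = nd/N` are Jukes-Cantor corrected into `dS` and `dN`; the selection
#' index `omega = dN/dS` is defined when `dS > 0` and neither proportion is
#' saturated (proportion at or above `saturation`, default 0.74).
#'
#' @param aln a 2-sequence [codon_alignment()]
#' @param saturation difference proportion at or above which the estimate is
#'   flagged saturated
#' @return an object of class `divergence_estimate` with fields `s_sites`,
#'   `n_sites`, `sd`, `nd`, `ps`, `pn`, `ds`, `dn`, `omega`, `saturated`,
#'   `n_columns_used`, `n_columns_dropped`
#' @export
pairwise_divergence <- function(aln, saturation = 0.74) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (nrow(aln$codons) != 2L) {
    stop("pairwise_divergence needs a 2-sequence alignment", call. = FALSE)
  }
  idx <- matrix(.codon_index(aln$codons), 2L)
  .ng86_estimate(idx[1, ], idx[2, ], aln$n_columns_dropped, saturation)
}

#' Fourfold-degenerate transversion rate (4DTv)
#'
#' A column contributes a fourfold-degenerate site when both codons share
#' the same first two bases and that 2-base prefix encodes one amino acid
#' for all four third bases.  The 4DTv rate is the proportion of those sites
#' at which the two third bases differ by a transversion (purine vs
#' pyrimidine).  Reported uncorrected.
#'
#' @param aln a 2-sequence [codon_alignment()]
#' @return list with `n_fourfold_sites`, `n_transversions`, `rate`
#'   (`NA` when no fourfold sites)
#' @export
fourdtv <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (nrow(aln$codons) != 2L) stop("fourdtv needs a 2-sequence alignment", call. = FALSE)
  tb <- codon_tables()
  a <- aln$codons[1, ]
  b <- aln$codons[2, ]
  ia <- .codon_index(a)
  pre_equal <- substr(a, 1, 2) == substr(b, 1, 2)
  four <- pre_equal & tb$fourfold[ia]
  n_sites <- sum(four)
  if (n_sites == 0L) {
    return(list(n_fourfold_sites = 0L, n_transversions = 0, rate = NA_real_))
  }
  t3a <- substr(a[four], 3, 3)
  t3b <- substr(b[four], 3, 3)
  ntv <- sum(tb$tv[cbind(t3a, t3b)])
  list(n_fourfold_sites = n_sites, n_transversions = ntv, rate = ntv / n_sites)
}

#' Sliding-window dN/dS profile along a codon alignment
#'
#' Windows of `window_bp` advanced by `step_bp` (both multiples of 3) over
#' the retained alignment columns, measured in base pairs from the start
#' codon; the last window ends at or before the alignment end.  Alignments
#' shorter than one window yield a single truncated window, flagged.
#'
#' @param aln a 2-sequence [codon_alignment()]
#' @param window_bp window length in bp (default 150)
#' @param step_bp step in bp (default 30)
#' @return data.frame with `window_start_bp`, `window_end_bp`, `truncated`
#'   and the per-window divergence fields
#' @export
sliding_window_dnds <- function(aln, window_bp = 150, step_bp = 30) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (window_bp %% 3 != 0 || step_bp %% 3 != 0) {
    stop("window_bp and step_bp must be multiples of 3", call. = FALSE)
  }
  if (nrow(aln$codons) != 2L) {
    stop("sliding_window_dnds needs a 2-sequence alignment", call. = FALSE)
  }
  idx <- matrix(.codon_index(aln$codons), 2L)
  L <- ncol(idx)
  wc <- window_bp %/% 3L
  sc <- step_bp %/% 3L
  truncated <- L < wc
  starts <- if (truncated) 1L else seq(1L, L - wc + 1L, by = sc)
  rows <- lapply(starts, function(s) {
    e <- min(s + wc - 1L, L)
    est <- .ng86_estimate(idx[1, s:e], idx[2, s:e])
    data.frame(window_start_bp = (s - 1L) * 3L, window_end_bp = e * 3L,
               truncated = truncated,
               s_sites = est$s_sites, n_sites = est$n_sites,
               sd = est$sd, nd = est$nd, ds = est$ds, dn = est$dn,
               omega = est$omega, saturated = est$saturated)
  })
  do.call(rbind, rows)
}

#' Outgroup-anchored branch-specific divergence
#'
#' Assigns substitutions to the two ingroup branches by parsimony against a
#' designated outgroup: a column contributes to the branch of ingroup
#' sequence `i` when the other ingroup codon equals the outgroup codon and
#' sequence `i` differs (pathway-averaged when multi-base).  Columns where
#' all three codons differ, or where the outgroup matches neither ingroup
#' codon while the ingroups disagree, are skipped and tallied as ambiguous.
#' Branch `dS`/`dN` use the branch sequence's own site counts summed over
#' the assignable columns.
#'
#' @param aln a 3-sequence [codon_alignment()]
#' @param outgroup label of the outgroup sequence
#' @param window_bp,step_bp optional sliding window (bp, multiples of 3);
#'   when `window_bp` is `NULL` a single whole-alignment estimate per branch
#'   is returned
#' @return data.frame with one row per branch (and per window when
#'   windowed): `branch`, `window_start_bp`, `window_end_bp`, `sd`, `nd`,
#'   `s_sites`, `n_sites`, `ds`, `dn`, `omega`, `n_ambiguous`
#' @export
branch_divergence <- function(aln, outgroup, window_bp = NULL, step_bp = 30) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (nrow(aln$codons) != 3L) {
    stop("branch_divergence needs a 3-sequence alignment", call. = FALSE)
  }
  og <- match(outgroup, aln$labels)
  if (is.na(og)) stop("outgroup label not found: ", outgroup, call. = FALSE)
  ing <- setdiff(1:3, og)

  idx <- matrix(.codon_index(aln$codons), 3L)
  L <- ncol(idx)
  if (is.null(window_bp)) {
    windows <- data.frame(s = 1L, e = L, start_bp = 0L, end_bp = 3L * L)
  } else {
    if (window_bp %% 3 != 0 || step_bp %% 3 != 0) {
      stop("window_bp and step_bp must be multiples of 3", call. = FALSE)
    }
    wc <- window_bp %/% 3L
    sc <- step_bp %/% 3L
    starts <- if (L < wc) 1L else seq(1L, L - wc + 1L, by = sc)
    ends <- pmin(starts + wc - 1L, L)
    windows <- data.frame(s = starts, e = ends, start_bp = (starts - 1L) * 3L,
                          end_bp = ends * 3L)
  }

  tb <- codon_tables()
  out <- list()
  for (w in seq_len(nrow(windows))) {
    cols <- windows$s[w]:windows$e[w]
    i1 <- idx[ing[1], cols]
    i2 <- idx[ing[2], cols]
    io <- idx[og, cols]
    ambiguous <- (i1 != i2) & (io != i1) & (io != i2)
    to1 <- (i1 != i2) & (io == i2)      # change on ingroup-1's branch
    to2 <- (i1 != i2) & (io == i1)
    usable <- !ambiguous
    for (b in 1:2) {
      self <- if (b == 1) i1 else i2
      other <- if (b == 1) i2 else i1
      on_branch <- if (b == 1) to1 else to2
      sd <- sum(tb$sd[cbind(other[on_branch], self[on_branch])])
      nd <- sum(tb$nd[cbind(other[on_branch], self[on_branch])])
      s_sites <- sum(tb$site_s[self[usable]])
      n_sites <- sum(tb$site_n[self[usable]])
      ds <- if (s_sites > 0) jukes_cantor(sd / s_sites) else NA_real_
      dn <- if (n_sites > 0) jukes_cantor(nd / n_sites) else NA_real_
      omega <- if (!is.na(ds) && !is.na(dn) && ds > 0) dn / ds else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        branch = aln$labels[ing[b]],
        window_start_bp = windows$start_bp[w], window_end_bp = windows$end_bp[w],
        sd = sd, nd = nd, s_sites = s_sites, n_sites = n_sites,
        ds = ds, dn = dn, omega = omega, n_ambiguous = sum(ambiguous))
    }
  }
  do.call(rbind, out)
}

#' Counts-based neutrality screen (dN/dS = 1)
#'
#' Two-sided exact binomial test of the nonsynonymous difference count
#' against the neutral expectation `p0 = N/(N+S)`: under neutral evolution
#' each difference is nonsynonymous with probability equal to the
#' nonsynonymous share of sites.  This is a counts-based screen, not a
#' likelihood-ratio test under a codon model; output tables flag it as such.
#'
#' @param est a `divergence_estimate` (from [pairwise_divergence()])
#' @return two-sided p-value (small-probability summation), or `NA` when
#'   `sd + nd < 1`
#' @export
neutrality_screen <- function(est) {
  stopifnot(inherits(est, "divergence_estimate"))
  total <- round(est$sd + est$nd)
  if (total < 1) return(NA_real_)
  p0 <- est$n_sites / (est$n_sites + est$s_sites)
  x <- min(round(est$nd), total)
  stats::binom.test(x, total, p = p0, alternative = "two.sided")$p.value
}
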