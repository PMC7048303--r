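# Classification of Y-contig regions from male/female pooled read depth
# (male-specific, PAR-like, repetitive, undetermined) and X-Y divergence
# decay with distance from the anchor gene.

#' Per-window male/female depth summary
#'
#' Cuts a depth track into non-overlapping windows (the final window may be
#' shorter) and reports mean male depth, mean female depth, the female read
#' fraction `F / (M + F)` (`NA` where both means are 0), and a repetitive
#' flag raised when the mean of the two depths exceeds twice the expected
#' single-copy depth.
#'
#' @param track a [depth_track()]
#' @param window_bp window size in bp (>= 100; default 500)
#' @param expected_depth expected single-copy depth (default 20)
#' @return data.frame with `contig`, `start`, `end` (0-based half-open),
#'   `mean_male_depth`, `mean_female_depth`, `female_read_fraction`,
#'   `repetitive`
#' @export
windowed_ratio <- function(track, window_bp = 500, expected_depth = 20) {
  stopifnot(inherits(track, "depth_track"))
  if (window_bp < 100) stop("window_bp must be at least 100", call. = FALSE)
  n <- length(track$male_depth)
  if (n == 0L) stop("empty depth track", call. = FALSE)
  starts <- seq(0L, n - 1L, by = window_bp)
  ends <- pmin(starts + window_bp, n)
  grp <- rep(seq_along(starts), times = ends - starts)
  mm <- tapply(track$male_depth, grp, mean)
  mf <- tapply(track$female_depth, grp, mean)
  tot <- mm + mf
  frac <- ifelse(tot > 0, mf / tot, NA_real_)
  data.frame(contig = track$contig, start = starts, end = ends,
             mean_male_depth = as.numeric(mm),
             mean_female_depth = as.numeric(mf),
             female_read_fraction = as.numeric(frac),
             repetitive = as.numeric(tot) / 2 > 2 * expected_depth,
             stringsAsFactors = FALSE)
}

#' Merge adjacent or overlapping region calls of the same class
#'
#' Depth statistics of merged calls are length-weighted means.  The merge
#' is idempotent: applying it to its own output changes nothing.
#'
#' @param calls region-call data.frame (`contig`, `start`, `end`, `call`,
#'   depth statistics)
#' @return merged calls, sorted by contig and start
#' @export
merge_region_calls <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  calls <- calls[order(calls$contig, calls$start), , drop = FALSE]
  out <- calls[0, , drop = FALSE]
  cur <- calls[1, , drop = FALSE]
  stat_cols <- intersect(c("mean_male_depth", "mean_female_depth",
                           "female_read_fraction"), names(calls))
  for (i in seq_len(nrow(calls))[-1]) {
    row <- calls[i, , drop = FALSE]
    if (row$contig == cur$contig && row$call == cur$call &&
        row$start <= cur$end) {
      w1 <- cur$end - cur$start
      w2 <- row$end - row$start
      for (cl in stat_cols) {
        cur[[cl]] <- (cur[[cl]] * w1 + row[[cl]] * w2) / (w1 + w2)
      }
      cur$end <- max(cur$end, row$end)
    } else {
      out <- rbind(out, cur)
      cur <- row
    }
  }
  out <- rbind(out, cur)
  rownames(out) <- NULL
  out
}

#' Classify Y-contig regions from windowed depth summaries
#'
#' Window classes: `repetitive` where the repetitive flag is raised;
#' otherwise `male-specific` where the female read fraction is below
#' `male_specific_max_female_frac` and male depth is at least half the
#' expected single-copy depth; otherwise a PAR-like candidate where the
#' female fraction exceeds `par_min_female_frac`; everything else
#' `undetermined`.  Consecutive same-class windows are merged; PAR
#' candidates become `PAR-like` only when the merged run is longer than
#' `par_min_length_bp` (strictly), otherwise they fall back to
#' `undetermined` and are merged with their neighbours.  The procedure is
#' deterministic and idempotent.
#'
#' @param windows output of [windowed_ratio()]
#' @param expected_depth expected single-copy depth (default 20)
#' @param par_min_length_bp minimum merged PAR run length (default 3000,
#'   strictly greater)
#' @param par_min_female_frac female-fraction threshold for PAR candidates
#'   (default 0.30, strictly greater)
#' @param male_specific_max_female_frac female-fraction ceiling for
#'   male-specific calls (default 0.05, strictly less)
#' @return region-call data.frame: `contig`, `start`, `end`, `call`,
#'   `mean_male_depth`, `mean_female_depth`, `female_read_fraction`
#' @export
classify_regions <- function(windows, expected_depth = 20,
                             par_min_length_bp = 3000,
                             par_min_female_frac = 0.30,
                             male_specific_max_female_frac = 0.05) {
  frac <- windows$female_read_fraction
  call <- rep("undetermined", nrow(windows))
  call[windows$repetitive] <- "repetitive"
  ms <- !windows$repetitive & !is.na(frac) &
    frac < male_specific_max_female_frac &
    windows$mean_male_depth >= 0.5 * expected_depth
  call[ms] <- "male-specific"
  parc <- !windows$repetitive & !ms & !is.na(frac) & frac > par_min_female_frac
  call[parc] <- "PAR-candidate"

  calls <- data.frame(contig = windows$contig, start = windows$start,
                      end = windows$end, call = call,
                      mean_male_depth = windows$mean_male_depth,
                      mean_female_depth = windows$mean_female_depth,
                      female_read_fraction = frac,
                      stringsAsFactors = FALSE)
  calls <- merge_region_calls(calls)
  is_par <- calls$call == "PAR-candidate"
  long <- calls$end - calls$start > par_min_length_bp
  calls$call[is_par & long] <- "PAR-like"
  calls$call[is_par & !long] <- "undetermined"
  calls <- merge_region_calls(calls)   # rejoin undetermined neighbours
  rownames(calls) <- NULL
  calls
}

#' X-Y divergence table anchored to a reference gene
#'
#' Computes the synonymous divergence between the X and Y alleles of each
#' gene from its codon alignment, the distance of the gene midpoint to the
#' anchor coordinate, and per-species interspecific baselines from ortholog
#' alignments computed the same way.
#'
#' @param xy_alignments named list (by gene id) of 2-sequence
#'   [codon_alignment()]s of the X and Y alleles
#' @param gene_positions data.frame `gene_id`, `start`, `end` (0-based
#'   half-open, same contig as the anchor)
#' @param anchor_position bp coordinate of the anchor gene
#' @param baseline_alignments optional named list (by gene id) of named
#'   lists (by species) of X-allele ortholog codon alignments
#' @param absolute report absolute distances (default) or signed
#' @return data.frame with `gene_id`, `distance_to_anchor`, `ds_xy`, one
#'   `ds_<species>` baseline column per species, and
#'   `exceeds_interspecific` (`ds_xy` above every baseline; recombination
#'   arrest predating speciation)
#' @export
xy_divergence_table <- function(xy_alignments, gene_positions, anchor_position,
                                baseline_alignments = NULL, absolute = TRUE) {
  species <- unique(unlist(lapply(baseline_alignments, names)))
  rows <- list()
  for (g in names(xy_alignments)) {
    pos <- gene_positions[gene_positions$gene_id == g, , drop = FALSE]
    if (nrow(pos) == 0L) {
      warning("no coordinates for gene ", g, "; skipped", call. = FALSE)
      next
    }
    aln <- xy_alignments[[g]]
    if (is.null(aln)) {
      warning("missing alignment for gene ", g, "; skipped", call. = FALSE)
      next
    }
    mid <- (pos$start[1] + pos$end[1]) / 2
    dist <- mid - anchor_position
    if (absolute) dist <- abs(dist)
    ds_xy <- pairwise_divergence(aln)$ds
    row <- data.frame(gene_id = g, distance_to_anchor = dist, ds_xy = ds_xy,
                      stringsAsFactors = FALSE)
    for (sp in species) {
      b <- baseline_alignments[[g]][[sp]]
      row[[paste0("ds_", sp)]] <-
        if (is.null(b)) NA_real_ else pairwise_divergence(b)$ds
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  if (length(species)) {
    base <- as.matrix(out[, paste0("ds_", species), drop = FALSE])
    maxb <- apply(base, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    out$exceeds_interspecific <- !is.na(out$ds_xy) & !is.na(maxb) & out$ds_xy > maxb
  } else {
    out$exceeds_interspecific <- NA
  }
  rownames(out) <- NULL
  out
}

#' Divergence decay of X-Y dS with distance to the anchor
#'
#' Spearman rank correlation (average ranks on ties) between the distance
#' to the anchor and the X-Y synonymous divergence.  `rho` is undefined
#' when either variable is constant; reports with fewer than 4 usable
#' genes are marked insufficient.
#'
#' @param xy_table output of [xy_divergence_table()]
#' @return list with `n`, `rho`, `p`, `insufficient`, `constant`,
#'   `n_exceeding` (genes whose X-Y dS exceeds every interspecific
#'   baseline)
#' @export
divergence_decay <- function(xy_table) {
  ok <- !is.na(xy_table$ds_xy) & !is.na(xy_table$distance_to_anchor)
  d <- xy_table[ok, , drop = FALSE]
  n <- nrow(d)
  n_exceeding <- if ("exceeds_interspecific" %in% names(d)) {
    sum(d$exceeds_interspecific, na.rm = TRUE)
  } else NA_integer_
  if (n < 4L) {
    return(list(n = n, rho = NA_real_, p = NA_real_, insufficient = TRUE,
                constant = NA, n_exceeding = n_exceeding))
  }
  constant <- stats::sd(d$ds_xy) == 0 || stats::sd(d$distance_to_anchor) == 0
  if (constant) {
    return(list(n = n, rho = NA_real_, p = NA_real_, insufficient = FALSE,
                constant = TRUE, n_exceeding = n_exceeding))
  }
  ct <- suppressWarnings(stats::cor.test(d$distance_to_anchor, d$ds_xy,
                                         method = "spearman", exact = FALSE))
  list(n = n, rho = unname(ct$estimate), p = ct$p.value, insufficient = FALSE,
       constant = FALSE, n_exceeding = n_exceeding)
}
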