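# Build the filtered paralog-pair catalog: TE / repetitive-gene exclusion,
# similarity thresholding, and gene-family grouping by single-linkage
# connected components of the hit graph.

#' Filter genes by TE annotation and homolog count
#'
#' Removes genes flagged as transposable elements and "repetitive" genes
#' with more than `max_homologs` distinct within-genome homologs at the hit
#' threshold (distinct non-self subjects; the boundary is strictly greater
#' than `max_homologs`).
#'
#' @param genes data.frame with at least `gene_id`; an optional logical
#'   `is_te` column marks transposable-element annotations
#' @param hits thresholded hit table from [read_hits()]
#' @param max_homologs retain genes with at most this many homologs
#'   (default 5)
#' @return list with `retained` (the filtered gene data.frame) and
#'   `exclusions` (data.frame `gene_id`, `reason`, `n_homologs`)
#' @export
filter_genes <- function(genes, hits, max_homologs = 5) {
  is_te <- if ("is_te" %in% names(genes)) {
    !is.na(genes$is_te) & genes$is_te
  } else rep(FALSE, nrow(genes))

  edges <- rbind(
    data.frame(gene = hits$query_id, other = hits$subject_id),
    data.frame(gene = hits$subject_id, other = hits$query_id))
  counts <- tapply(edges$other, edges$gene, function(x) length(unique(x)))
  n_hom <- ifelse(genes$gene_id %in% names(counts),
                  as.integer(counts[genes$gene_id]), 0L)

  repetitive <- n_hom > max_homologs
  drop <- is_te | repetitive
  reason <- ifelse(is_te, "TE", "repetitive")
  exclusions <- data.frame(gene_id = genes$gene_id[drop],
                           reason = reason[drop],
                           n_homologs = n_hom[drop],
                           stringsAsFactors = FALSE)
  list(retained = genes[!drop, , drop = FALSE], exclusions = exclusions)
}

#' Build the paralog-pair catalog with gene-family ids
#'
#' One pair per surviving hit between retained genes, ids ordered
#' lexicographically within each pair.  Family ids are single-linkage
#' connected components of the hit graph, numbered by each family's
#' smallest member id; pairs are sorted lexicographically.  The output is
#' invariant to input row order.
#'
#' @param genes retained gene data.frame (from [filter_genes()])
#' @param hits thresholded hit table
#' @return data.frame `gene_a`, `gene_b`, `family_id`
#' @export
make_pairs <- function(genes, hits) {
  keep <- hits$query_id %in% genes$gene_id & hits$subject_id %in% genes$gene_id
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      family_id = integer()))
  }
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  ord <- order(a, b)
  a <- a[ord]
  b <- b[ord]
  dup <- duplicated(paste(a, b, sep = "\r"))
  a <- a[!dup]
  b <- b[!dup]

  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  anchor <- vapply(member, function(x) min(x), character(1))
  fam_rank <- integer(comp$no)
  fam_rank[order(anchor)] <- seq_len(comp$no)
  family_id <- fam_rank[comp$membership[a]]

  out <- data.frame(gene_a = a, gene_b = b, family_id = family_id,
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Annotate a pair catalog with divergence and 4DTv statistics
#'
#' Computes [pairwise_divergence()] and [fourdtv()] for every pair, either
#' from pre-aligned equal-length CDS (gap-free, e.g. simulator output) or
#' from a caller-supplied list of [codon_alignment()]s keyed by
#' `gene_a|gene_b`.
#'
#' @param pairs pair catalog from [make_pairs()]
#' @param genes gene data.frame with `gene_id`, `cds` (used when
#'   `alignments` is `NULL`; each pair's two CDS must have equal length)
#' @param alignments optional named list of codon alignments
#' @param saturation saturation threshold forwarded to
#'   [pairwise_divergence()]
#' @return `pairs` with appended columns `s_sites`, `n_sites`, `sd`, `nd`,
#'   `ds`, `dn`, `omega`, `saturated`, `n_columns_used`,
#'   `n_columns_dropped`, `fourdtv_sites`, `fourdtv_rate`
#' @export
annotate_divergence <- function(pairs, genes = NULL, alignments = NULL,
                                saturation = 0.74) {
  n <- nrow(pairs)
  cols <- c("s_sites", "n_sites", "sd", "nd", "ds", "dn", "omega")
  for (cl in cols) pairs[[cl]] <- NA_real_
  pairs$saturated <- NA
  pairs$n_columns_used <- NA_integer_
  pairs$n_columns_dropped <- NA_integer_
  pairs$fourdtv_sites <- NA_integer_
  pairs$fourdtv_rate <- NA_real_
  if (n == 0L) return(pairs)
  seq_of <- if (!is.null(genes)) stats::setNames(genes$cds, genes$gene_id)
  for (i in seq_len(n)) {
    key <- paste(pairs$gene_a[i], pairs$gene_b[i], sep = "|")
    aln <- if (!is.null(alignments)) alignments[[key]]
    if (is.null(aln)) {
      sa <- seq_of[[pairs$gene_a[i]]]
      sb <- seq_of[[pairs$gene_b[i]]]
      if (is.null(sa) || is.null(sb) || nchar(sa) != nchar(sb)) {
        warning("skipping pair with missing or unalignable CDS: ", key,
                call. = FALSE)
        next
      }
      aln <- codon_alignment(c(sa, sb), labels = c(pairs$gene_a[i], pairs$gene_b[i]))
    }
    est <- pairwise_divergence(aln, saturation = saturation)
    for (cl in cols) pairs[[cl]][i] <- est[[cl]]
    pairs$saturated[i] <- est$saturated
    pairs$n_columns_used[i] <- est$n_columns_used
    pairs$n_columns_dropped[i] <- est$n_columns_dropped
    f <- fourdtv(aln)
    pairs$fourdtv_sites[i] <- f$n_fourfold_sites
    pairs$fourdtv_rate[i] <- f$rate
  }
  pairs
}
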