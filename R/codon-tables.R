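# Precomputed codon bookkeeping shared by the estimators and the simulator.
#
# Everything here derives from the standard genetic code
# (Biostrings::GENETIC_CODE).  Tables are built once per session, at first
# use, and cached in a package environment:
#   sense      - the 61 sense codons, the canonical state ordering
#   site_s/n   - NG86 synonymous / nonsynonymous site counts per sense codon
#   sd/nd      - 61 x 61 pathway-averaged synonymous / nonsynonymous
#                difference counts (stop-crossing pathways excluded; if every
#                pathway crosses a stop, all pathways are averaged)
#   fourfold   - logical per sense codon: third position fourfold degenerate

.dupfate <- new.env(parent = emptyenv())

.bases <- c("A", "C", "G", "T")
.purines <- c("A", "G")

.is_transition <- function(x, y) {
  (x %in% .purines) == (y %in% .purines)
}

.codon_split <- function(codon) strsplit(codon, "", fixed = TRUE)[[1]]

# NG86 site counts for one codon: at each position, the fraction of the
# three single-nucleotide neighbours that are synonymous; neighbours that
# would create a stop codon are excluded from the denominator.
.ng86_sites_one <- function(codon, gc) {
  ch <- .codon_split(codon)
  s <- 0
  for (pos in 1:3) {
    alt <- vapply(setdiff(.bases, ch[pos]), function(b) {
      x <- ch
      x[pos] <- b
      paste(x, collapse = "")
    }, character(1))
    keep <- gc[alt] != "*"
    if (any(keep)) {
      s <- s + sum(gc[alt[keep]] == gc[codon]) / sum(keep)
    }
  }
  c(s, 3 - s)
}

# Pathway-averaged (sd, nd) between two sense codons.
.ng86_diff_one <- function(a, b, gc) {
  ca <- .codon_split(a)
  cb <- .codon_split(b)
  dp <- which(ca != cb)
  k <- length(dp)
  if (k == 0L) return(c(0, 0))
  orders <- switch(as.character(k),
    "1" = list(dp),
    "2" = list(dp, rev(dp)),
    "3" = {
      out <- list()
      for (i in 1:3) for (j in setdiff(1:3, i)) {
        out[[length(out) + 1L]] <- c(dp[i], dp[j], dp[setdiff(1:3, c(i, j))])
      }
      out
    })
  valid <- list()
  all_paths <- list()
  for (ord in orders) {
    cur <- ca
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      from <- gc[paste(cur, collapse = "")]
      to <- gc[paste(nxt, collapse = "")]
      if (to == "*") ok <- FALSE
      if (to == from) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    all_paths[[length(all_paths) + 1L]] <- c(sd, nd)
    if (ok) valid[[length(valid) + 1L]] <- c(sd, nd)
  }
  use <- if (length(valid)) valid else all_paths
  colMeans(do.call(rbind, use))
}

.build_codon_tables <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  sense <- codons[gc != "*"]
  ns <- length(sense)

  sites <- t(vapply(sense, .ng86_sites_one, numeric(2), gc = gc))
  sd_mat <- matrix(0, ns, ns, dimnames = list(sense, sense))
  nd_mat <- sd_mat
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i >= j) next
      d <- .ng86_diff_one(sense[i], sense[j], gc)
      sd_mat[i, j] <- sd_mat[j, i] <- d[1]
      nd_mat[i, j] <- nd_mat[j, i] <- d[2]
    }
  }

  # fourfold-degenerate third position: the 2-base prefix encodes one amino
  # acid whatever the third base
  prefix <- substr(sense, 1, 2)
  fourfold <- vapply(prefix, function(p) {
    length(unique(gc[paste0(p, .bases)])) == 1L
  }, logical(1))

  # base-level transversion indicator, indexed by base characters
  tv <- matrix(!outer(.bases %in% .purines, .bases %in% .purines, "=="),
               4, 4, dimnames = list(.bases, .bases))

  list(gc = gc, sense = sense, n_sense = ns,
       aa = unname(gc[sense]),
       site_s = unname(sites[, 1]), site_n = unname(sites[, 2]),
       sd = sd_mat, nd = nd_mat,
       fourfold = unname(fourfold),
       tv = tv)
}

codon_tables <- function() {
  if (is.null(.dupfate$tables)) .dupfate$tables <- .build_codon_tables()
  .dupfate$tables
}

# Map a vector of codon strings to indices in the sense-codon ordering.
# Stop codons and codons containing anything outside A/C/G/T map to NA.
.codon_index <- function(codons) {
  tb <- codon_tables()
  match(codons, tb$sense)
}

# Split an in-frame nucleotide string into its codon vector.
.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
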