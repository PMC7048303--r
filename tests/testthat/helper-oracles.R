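# Independent brute-force oracles.  These deliberately share no code with
# the package internals: site fractions and pathway averages are recomputed
# from scratch with character-level enumeration, Fisher probabilities with
# explicit binomial-coefficient products, and the two-sided binomial by
# direct density summation.

.oracle_gc <- Biostrings::GENETIC_CODE
.oracle_bases <- c("A", "C", "G", "T")

oracle_translate <- function(codon) unname(.oracle_gc[codon])

oracle_neighbors <- function(codon, pos) {
  ch <- strsplit(codon, "")[[1]]
  out <- c()
  for (b in setdiff(.oracle_bases, ch[pos])) {
    x <- ch
    x[pos] <- b
    out <- c(out, paste(x, collapse = ""))
  }
  out
}

# NG86 site counts by neighbor enumeration.
oracle_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    nb <- oracle_neighbors(codon, pos)
    nb <- nb[oracle_translate(nb) != "*"]
    if (length(nb)) s <- s + mean(oracle_translate(nb) == oracle_translate(codon))
  }
  c(s = s, n = 3 - s)
}

# All orderings of positions, as a list of integer vectors.
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Pathway-averaged (sd, nd) by explicit pathway enumeration.
oracle_pair_diff <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  dp <- which(ca != cb)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  keep <- list()
  everything <- list()
  for (ord in oracle_perms(dp)) {
    cur <- ca
    sd <- nd <- 0
    through_stop <- FALSE
    for (pos in ord) {
      prev <- paste(cur, collapse = "")
      cur[pos] <- cb[pos]
      now <- paste(cur, collapse = "")
      if (oracle_translate(now) == "*") through_stop <- TRUE
      if (oracle_translate(now) == oracle_translate(prev)) sd <- sd + 1 else nd <- nd + 1
    }
    everything[[length(everything) + 1]] <- c(sd, nd)
    if (!through_stop) keep[[length(keep) + 1]] <- c(sd, nd)
  }
  use <- if (length(keep)) keep else everything
  m <- colMeans(do.call(rbind, use))
  c(sd = m[1], nd = m[2])
}

# Full NG86 + Jukes-Cantor estimate on two equal-length gap-free CDS.
oracle_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a)
  ca <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  usable <- oracle_translate(ca) != "*" & oracle_translate(cb) != "*" &
    !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[usable]
  cb <- cb[usable]
  S <- N <- sd <- nd <- 0
  for (i in seq_along(ca)) {
    sa <- oracle_sites(ca[i])
    sb <- oracle_sites(cb[i])
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    d <- oracle_pair_diff(ca[i], cb[i])
    sd <- sd + d["sd"]
    nd <- nd + d["nd"]
  }
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ps <- unname(sd / S)
  pn <- unname(nd / N)
  list(S = unname(S), N = unname(N), sd = unname(sd), nd = unname(nd),
       ps = ps, pn = pn, ds = jc(ps), dn = jc(pn))
}

# Two-sided Fisher exact by explicit enumeration of all tables with the
# observed margins, probabilities from binomial-coefficient products.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  total <- m + n
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  prob <- vapply(xs, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(total, k))
  }, numeric(1))
  obs <- prob[match(a, xs)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Two-sided exact binomial by density summation.
oracle_binom_two_sided <- function(x, n, p) {
  dens <- dbinom(0:n, n, p)
  min(1, sum(dens[dens <= dens[x + 1] * (1 + 1e-7)]))
}

# Deterministic random sense CDS for tests (uses the current RNG stream).
random_sense_cds <- function(n_codons) {
  sense <- names(.oracle_gc)[.oracle_gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
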