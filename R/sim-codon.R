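# Codon sequence simulator: a mutation-selection process (K80 mutation,
# kappa transition/transversion bias, times omega acceptance for
# nonsynonymous changes, zero rate into stop codons) over the 61 sense
# codons, with divergence time calibrated numerically so the expected
# NG86-estimated dS between the outputs hits a requested target.

# Symmetric instantaneous rate matrix over the sense codons.
.codon_rate_matrix <- function(omega, kappa) {
  tb <- codon_tables()
  ns <- tb$n_sense
  Q <- matrix(0, ns, ns)
  ch <- matrix(unlist(strsplit(tb$sense, "")), nrow = 3)
  for (pos in 1:3) {
    for (i in seq_len(ns)) {
      for (j in seq_len(ns)) {
        if (i == j) next
        diff <- ch[, i] != ch[, j]
        if (sum(diff) != 1L || !diff[pos]) next
        r <- if (tb$tv[ch[pos, i], ch[pos, j]]) 1 else kappa
        if (tb$aa[i] != tb$aa[j]) r <- r * omega
        Q[i, j] <- r
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Eigendecomposition cache keyed by (omega, kappa).
.codon_eigen <- function(omega, kappa) {
  key <- sprintf("eig_%.10g_%.10g", omega, kappa)
  if (is.null(.dupfate[[key]])) {
    .dupfate[[key]] <- eigen(.codon_rate_matrix(omega, kappa), symmetric = TRUE)
  }
  .dupfate[[key]]
}

# Transition probability matrix P(t) = V exp(Lambda t) V'.
.codon_pmat <- function(eig, t) {
  P <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Expected NG86 difference proportions (ps, pn) for sequences separated by
# total path time t.  `groups` is a list of per-omega groups, each with
# `eig` and `pi` (ancestral codon composition over sense codons) and `n`
# (number of codons).  mode "pair": both endpoints evolve t/2 from the
# ancestor; mode "branch": one endpoint is the ancestor itself.
.expected_proportions <- function(t, groups, mode = c("pair", "branch")) {
  mode <- match.arg(mode)
  tb <- codon_tables()
  Esd <- End <- ES <- EN <- 0
  for (g in groups) {
    if (mode == "pair") {
      P <- .codon_pmat(g$eig, t / 2)
      W <- t(P) %*% (g$pi * P)            # W[a,b] = sum_i pi_i P_ia P_ib
      q1 <- q2 <- colSums(g$pi * P)
    } else {
      P <- .codon_pmat(g$eig, t)
      W <- g$pi * P
      q1 <- g$pi
      q2 <- colSums(g$pi * P)
    }
    Esd <- Esd + g$n * sum(W * tb$sd)
    End <- End + g$n * sum(W * tb$nd)
    ES <- ES + g$n * (sum(q1 * tb$site_s) + sum(q2 * tb$site_s)) / 2
    EN <- EN + g$n * (sum(q1 * tb$site_n) + sum(q2 * tb$site_n)) / 2
  }
  c(ps = Esd / ES, pn = End / EN)
}

# Solve for the total path time whose expected NG86 dS equals target_ds
# (bisection in the monotone ps scale; tolerance well inside 1%).
.calibrate_time <- function(target_ds, groups, mode = "pair") {
  if (target_ds == 0) return(0)
  p_target <- 0.75 * (1 - exp(-4 * target_ds / 3))
  if (p_target >= 0.74) {
    # inside the estimator's saturation regime: no meaningful calibration
    stop(sprintf("target_ds = %g is beyond saturation for this model", target_ds),
         call. = FALSE)
  }
  f <- function(t) .expected_proportions(t, groups, mode)[["ps"]] - p_target
  hi <- 1
  while (f(hi) < 0 && hi < 4096) hi <- hi * 2
  if (f(hi) < 0) {
    stop(sprintf("target_ds = %g is beyond saturation for this model", target_ds),
         call. = FALSE)
  }
  stats::uniroot(f, c(0, hi), tol = 1e-7)$root
}

# Draw endpoint codons for every ancestral codon index given P.
.sample_codons <- function(anc_idx, P) {
  cum <- t(apply(P, 1, cumsum))
  cm <- cum[anc_idx, , drop = FALSE]
  u <- stats::runif(length(anc_idx))
  pmin(1L + rowSums(cm < u), ncol(P))
}

# Resolve the per-codon omega assignment into calibration/sampling groups.
.omega_groups <- function(anc_idx, omega, kappa, omega_windows) {
  n <- length(anc_idx)
  per_codon <- rep(omega, n)
  if (!is.null(omega_windows)) {
    for (w in seq_len(nrow(omega_windows))) {
      lo <- omega_windows$start_codon[w]
      hi <- omega_windows$end_codon[w]
      if (lo < 1 || hi > n || lo > hi) {
        stop("omega_windows rows must satisfy 1 <= start_codon <= end_codon <= n_codons",
             call. = FALSE)
      }
      per_codon[lo:hi] <- omega_windows$omega[w]
    }
  }
  tb <- codon_tables()
  groups <- lapply(unique(per_codon), function(om) {
    sel <- which(per_codon == om)
    pi <- tabulate(anc_idx[sel], nbins = tb$n_sense)
    list(omega = om, eig = .codon_eigen(om, kappa), idx = sel,
         pi = pi / sum(pi), n = length(sel))
  })
  list(groups = groups, per_codon = per_codon)
}

#' Simulate a random ancestral CDS
#'
#' Uniform random sense codons (no stops), starting with `ATG`;
#' deterministic given the seed.
#'
#' @param n_codons number of codons (>= 1)
#' @param seed RNG seed (optional; when given, `set.seed` is called)
#' @return a CDS string of `3 * n_codons` bases
#' @export
sim_ancestral_cds <- function(n_codons, seed = NULL) {
  if (n_codons < 1) stop("n_codons must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tb <- codon_tables()
  codons <- c("ATG", sample(tb$sense, n_codons - 1L, replace = TRUE))
  paste(codons[seq_len(n_codons)], collapse = "")
}

#' Evolve a paralog pair to a target synonymous divergence
#'
#' Both lineages evolve independently from the ancestor under the
#' mutation-selection codon process (transition rate proportional to
#' `kappa`, transversion rate 1, nonsynonymous changes additionally scaled
#' by `omega`, zero rate into stops).  The total divergence time is
#' calibrated numerically (bisection on the expected synonymous difference
#' proportion, given the ancestral codon composition) so that the expected
#' NG86+JC estimated dS between the two outputs equals `target_ds`.
#'
#' @param ancestral ancestral CDS (sense codons only)
#' @param target_ds target expected NG86-estimated dS (>= 0)
#' @param omega nonsynonymous/synonymous acceptance ratio (background)
#' @param kappa transition/transversion rate ratio
#' @param seed optional RNG seed
#' @param omega_windows optional data.frame (`start_codon`, `end_codon`,
#'   `omega`) assigning distinct omega values to 1-based codon ranges
#' @return list with `cds_a`, `cds_b` and `truth` (the planted parameters,
#'   including the calibrated time)
#' @export
evolve_pair <- function(ancestral, target_ds, omega = 0.2, kappa = 2,
                        seed = NULL, omega_windows = NULL) {
  if (target_ds < 0) stop("target_ds must be non-negative", call. = FALSE)
  if (omega < 0) stop("omega must be non-negative", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  tb <- codon_tables()
  anc_idx <- .codon_index(.split_codons(toupper(ancestral)))
  if (anyNA(anc_idx)) stop("ancestral CDS must consist of sense codons", call. = FALSE)

  og <- .omega_groups(anc_idx, omega, kappa, omega_windows)
  truth <- list(target_ds = target_ds, omega = omega, kappa = kappa,
                omega_windows = omega_windows, seed = seed,
                n_codons = length(anc_idx))
  if (target_ds == 0) {
    return(list(cds_a = ancestral, cds_b = ancestral,
                truth = c(truth, list(time = 0))))
  }
  t_total <- .calibrate_time(target_ds, og$groups, mode = "pair")
  if (!is.null(seed)) set.seed(seed)
  ia <- ib <- anc_idx
  for (g in og$groups) {
    P <- .codon_pmat(g$eig, t_total / 2)
    ia[g$idx] <- .sample_codons(anc_idx[g$idx], P)
    ib[g$idx] <- .sample_codons(anc_idx[g$idx], P)
  }
  list(cds_a = paste(tb$sense[ia], collapse = ""),
       cds_b = paste(tb$sense[ib], collapse = ""),
       truth = c(truth, list(time = t_total)))
}

#' Simulate an outgroup + paralog-pair triple
#'
#' The outgroup diverges from the root first and the two ingroup paralogs
#' split immediately after (internal branch of length zero), so all three
#' branches radiate from the common ancestral sequence.  Each branch gets
#' its own omega (optionally windowed) and its own expected NG86 dS from
#' the ancestor.
#'
#' @param ancestral ancestral CDS
#' @param branch_omegas named list/vector with entries `outgroup`, `p1`,
#'   `p2` (background omega per branch)
#' @param target_ds_per_branch named numeric with entries `outgroup`,
#'   `p1`, `p2`: expected NG86 dS between the ancestor and each branch tip
#' @param kappa transition/transversion ratio
#' @param seed optional RNG seed
#' @param omega_windows optional named list of per-branch omega-window
#'   data.frames (see [evolve_pair()])
#' @return list with `outgroup`, `p1`, `p2` CDS strings and `truth`
#' @export
sim_triple <- function(ancestral, branch_omegas, target_ds_per_branch,
                       kappa = 2, seed = NULL, omega_windows = NULL) {
  tb <- codon_tables()
  anc_idx <- .codon_index(.split_codons(toupper(ancestral)))
  if (anyNA(anc_idx)) stop("ancestral CDS must consist of sense codons", call. = FALSE)
  branches <- c("outgroup", "p1", "p2")
  if (!all(branches %in% names(branch_omegas)) ||
      !all(branches %in% names(target_ds_per_branch))) {
    stop("branch_omegas and target_ds_per_branch need entries outgroup, p1, p2",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  times <- numeric(0)
  for (b in branches) {
    og <- .omega_groups(anc_idx, branch_omegas[[b]], kappa, omega_windows[[b]])
    target <- target_ds_per_branch[[b]]
    if (target == 0) {
      out[[b]] <- ancestral
      times[b] <- 0
      next
    }
    t_b <- .calibrate_time(target, og$groups, mode = "branch")
    ib <- anc_idx
    for (g in og$groups) {
      P <- .codon_pmat(g$eig, t_b)
      ib[g$idx] <- .sample_codons(anc_idx[g$idx], P)
    }
    out[[b]] <- paste(tb$sense[ib], collapse = "")
    times[b] <- t_b
  }
  out$truth <- list(branch_omegas = branch_omegas,
                    target_ds_per_branch = target_ds_per_branch,
                    kappa = kappa, seed = seed, times = times,
                    omega_windows = omega_windows)
  out
}
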