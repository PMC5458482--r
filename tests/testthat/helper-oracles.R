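# Independent brute-force oracles used across the suite. These re-derive
# each statistic from its definition and never share code with the package.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
# The U distribution is symmetric about na*nb/2 under H0, so the two-sided
# p is 2 * min(P(U <= u), P(U >= u)) capped at 1.
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) # number of pairs x > y
  u_obs <- u_stat(a, b)
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Benjamini-Hochberg step-up q-values from the written-out definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, 0)
    q_sorted[i] <- min(c(cand, 1))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-tailed Fisher exact p for a 2x2 table: sum of hypergeometric
# probabilities of all tables with the same margins that are as or more
# extreme (probability <= observed, with a relative tolerance as in the
# conventional implementation).
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Breslow partial log-likelihood for a single binary covariate, written out
# directly; maximized on a grid refinement by optimize().
cox_brute_coef <- function(time, event, x) {
  loglik <- function(beta) {
    ll <- 0
    for (i in which(as.logical(event))) {
      risk <- which(time >= time[i])
      ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
    ll
  }
  stats::optimize(loglik, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# Ward agglomeration by direct Lance-Williams recursion on squared
# Euclidean distances (the ward.D2 criterion); returns merge heights in
# order. Ties broken by lowest pair index, matching a fixed scan order.
ward_brute_heights <- function(d2) {
  n <- attr(d2, "Size")
  act <- as.list(seq_len(n))
  sizes <- rep(1, n)
  dm <- as.matrix(d2)^2
  heights <- numeric(0)
  while (length(act) > 1) {
    best <- c(NA, NA); best_val <- Inf
    for (i in seq_along(act)) for (j in seq_along(act)) {
      if (i < j && dm[i, j] < best_val - 1e-12) {
        best_val <- dm[i, j]; best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(best_val))
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- vapply(seq_along(act), function(k) {
      if (k == i || k == j) return(NA_real_)
      nk <- sizes[k]
      ((ni + nk) * dm[i, k] + (nj + nk) * dm[j, k] - nk * dm[i, j]) /
        (ni + nj + nk)
    }, 0)
    keep <- setdiff(seq_along(act), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    act <- c(act[keep], list(c(act[[i]], act[[j]])))
  }
  heights
}

# small simulated matrix shared by several tests
small_sim <- function(seed = 7, ...) {
  simulate_beta(sim_config(seed = seed, n_probes = 400,
                           n_nevus = 8, n_primary = 10, n_meta = 9,
                           n_prognostic = 20, ...))
}

# primary-only cohort whose survival arms coincide with the generator's
# planted risk groups: short survivors die at 24 months, long survivors are
# followed past the 48-month cutoff
make_survivor_fixture <- function(n_per_arm = 20, delta = 0.3,
                                  n_probes = 1500, n_planted = 60,
                                  seed = 19) {
  cfg <- sim_config(seed = seed, n_nevus = 1, n_primary = 2 * n_per_arm,
                    n_meta = 1, n_probes = n_probes,
                    frac_dev_hyper = 0, frac_dev_hypo = 0,
                    frac_prog_hyper = 0, frac_prog_hypo = 0,
                    n_prognostic = n_planted, prognostic_delta = delta,
                    frac_missing = 0.01)
  s <- simulate_beta(cfg)
  pri <- s$samples[s$samples$group == "primary", ]
  sheet <- data.frame(
    sample_id = pri$sample_id, group = "primary",
    survival_months = ifelse(pri$risk_group == "high", 24, 60),
    event = pri$risk_group == "high",
    breslow_mm = 1, ulceration = FALSE, stringsAsFactors = FALSE)
  list(sim = s, sheet = sheet)
}

# toy annotation with explicit islands and TSSs for classification tests
toy_annotation <- function() {
  probes <- data.frame(
    probe_id = sprintf("p%02d", 1:8),
    chr = "chrS",
    #        island [1000,2000], TSS at 1500 and 9000
    pos = c(1500L,  # in island, at TSS -> promoter island
            1980L,  # in island, 480 bp from TSS -> promoter island
            2001L,  # 1 bp past edge -> shore
            4500L,  # 2500 bp out -> shelf
            7000L,  # 5000 bp out -> open sea
            8990L,  # open sea but 10 bp from TSS -> not promoter island
            3500L,  # exactly 2000 bp from TSS (strict) -> shore, not promoter
            1010L), # in island, 490 bp from TSS -> promoter island
    strand = "+",
    gene_symbols = c("GeneA", "GeneA", "GeneA", "GeneA", "",
                     "GeneB", "GeneA;GeneB", ""),
    gene_features = c("TSS200", "Body", "Body", "3UTR", "",
                      "TSS1500", "TSS200;Body", ""),
    island_start = 1000L, island_end = 2000L,
    snp_overlap = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    is_genotyping = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  structure(list(
    probes = probes,
    tss = data.frame(gene = c("GeneA", "GeneB"), tss_pos = c(1500L, 9000L),
                     stringsAsFactors = FALSE),
    islands = data.frame(start = 1000L, end = 2000L)
  ), class = "probe_annotation")
}
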