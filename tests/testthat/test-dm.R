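test_that("vectorised ANOVA F matches aov on small numeric cases", {
  set.seed(5)
  groups <- rep(c("a", "b", "c"), each = 4)
  for (i in 1:10) {
    beta <- matrix(runif(3 * 12), 3,
                   dimnames = list(paste0("p", 1:3), paste0("s", 1:12)))
    if (i > 5) beta[cbind(sample(3, 3, TRUE), sample(12, 3))] <- NA
    for (r in 1:3) {
      v <- beta[r, ]
      fit <- stats::aov(v ~ g, data = data.frame(v = v, g = groups))
      p_aov <- summary(fit)[[1]][["Pr(>F)"]][1]
      # recompute through the screen at delta 0 so only the p gate acts
      sel_lo <- anova_screen(beta[r, , drop = FALSE], groups,
                             delta = 0, conf = 1 - p_aov - 1e-8)
      sel_hi <- anova_screen(beta[r, , drop = FALSE], groups,
                             delta = 0, conf = 1 - p_aov + 1e-8)
      expect_equal(length(sel_lo), 1)  # cutoff just above p -> selected
      expect_equal(length(sel_hi), 0)  # cutoff just below p -> not selected
    }
  }
})

test_that("ANOVA screen applies both the p gate and the median-delta gate", {
  groups <- rep(c("a", "b", "c"), each = 5)
  flat <- matrix(0.5, 1, 15, dimnames = list("flat", paste0("s", 1:15)))
  expect_equal(anova_screen(flat, groups), character(0))
  spread <- matrix(rep(c(0.1, 0.5, 0.9), each = 5) +
                     rep(seq(-0.002, 0.002, length.out = 5), 3),
                   1, 15, dimnames = list("spread", paste0("s", 1:15)))
  expect_equal(anova_screen(spread, groups), "spread")
  # delta gate: medians 0.1/0.3/0.5 differ by < 0.33 only pairwise-adjacent
  mid <- matrix(rep(c(0.1, 0.3, 0.5), each = 5) +
                  rep(seq(-0.002, 0.002, length.out = 5), 3),
                1, 15, dimnames = list("mid", paste0("s", 1:15)))
  expect_equal(anova_screen(mid, groups, delta = 0.33), "mid")  # 0.4 >= 0.33
  expect_equal(anova_screen(mid, groups, delta = 0.45), character(0))
  expect_error(anova_screen(flat, groups[1:10]), "one label per sample")
})

test_that("Ward clustering recovers simulated groups and matches the criterion", {
  # two well-separated groups -> perfect labels
  set.seed(2)
  beta <- cbind(matrix(rbeta(50 * 6, 2, 10), 50), # low group
                matrix(rbeta(50 * 6, 10, 2), 50)) # high group
  dimnames(beta) <- list(paste0("p", 1:50), paste0("s", 1:12))
  wc <- ward_cluster(beta, k = 2)
  labels <- wc$labels
  expect_equal(length(unique(labels[1:6])), 1)
  expect_equal(length(unique(labels[7:12])), 1)
  expect_false(labels[1] == labels[7])

  # duplicated sample merges first at height 0
  beta2 <- beta[, c(1, 1, 7, 9)]
  colnames(beta2) <- paste0("t", 1:4)
  wc2 <- ward_cluster(beta2)
  expect_equal(wc2$hclust$height[1], 0)
  expect_equal(sort(wc2$hclust$merge[1, ]), c(-2, -1))

  # merge heights match the brute-force Ward (Lance-Williams) recursion
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(8 * 5), 8, dimnames = list(paste0("p", 1:8),
                                                 paste0("s", 1:5)))
    hc <- ward_cluster(m)$hclust
    expect_equal(hc$height, ward_brute_heights(dist(t(m))), tolerance = 1e-8)
  }

  # three samples with pairwise distances 1,1,2: second merge at sqrt(3)
  line <- matrix(c(0, 1, 2), 1, dimnames = list("p1", paste0("s", 1:3)))
  hc3 <- ward_cluster(line)$hclust
  expect_equal(hc3$height, c(1, sqrt(3)))
  expect_error(ward_cluster(line[, 1, drop = FALSE]), "two samples")
})

test_that("exact Mann-Whitney agrees with full enumeration (n_a+n_b <= 10)", {
  set.seed(31)
  sizes <- subset(expand.grid(na = 3:7, nb = 3:7), na + nb <= 10)
  for (r in seq_len(nrow(sizes))) {
    for (rep in 1:3) {
      a <- sample(seq_len(50), sizes$na[r])
      b <- sample(setdiff(seq_len(50), a), sizes$nb[r])
      expect_equal(mann_whitney(a, b), mw_enum_p(a, b), tolerance = 1e-12,
                   info = sprintf("na=%d nb=%d", sizes$na[r], sizes$nb[r]))
    }
  }
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical multisets (tie-heavy, normal branch): p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 1)
  # below min_group_n: untestable
  expect_true(is.na(mann_whitney(c(1, 2), c(3, 4, 5))))
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:100) {
    p <- runif(sample(1:1000, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("DGMB gate excludes large-p probes before testing", {
  set.seed(23)
  # probe with dgmb just under the gate but a tiny p is never significant
  a <- matrix(c(rep(0.30, 8), rep(0.54, 8),
                rep(0.10, 8), rep(0.60, 8)), 2, byrow = TRUE,
              dimnames = list(c("under_gate", "over_gate"), paste0("s", 1:16)))
  a["under_gate", 1:8] <- seq(0.29, 0.31, length.out = 8)
  a["under_gate", 9:16] <- seq(0.53, 0.55, length.out = 8)
  cmp <- dgmb_compare(a, paste0("s", 1:8), paste0("s", 9:16))
  row <- cmp[cmp$probe_id == "under_gate", ]
  expect_lt(abs(row$dgmb), 0.25)
  expect_false(row$significant)
  expect_true(is.na(row$p_raw))  # gated out before testing
  expect_true(cmp[cmp$probe_id == "over_gate", "significant"])
  # the BH family is the gated probes only
  expect_equal(sum(!is.na(cmp$p_adj)), 1)
  # test-then-gate tests everything but still applies the effect gate
  cmp2 <- dgmb_compare(a, paste0("s", 1:8), paste0("s", 9:16),
                       gate_order = "test_then_gate")
  expect_false(cmp2[cmp2$probe_id == "under_gate", "significant"])
  expect_false(any(is.na(cmp2$p_raw)))
})

test_that("DGMB comparison against its own data yields nothing", {
  s <- small_sim()
  gr <- split(s$samples$sample_id, s$samples$group)
  half_a <- gr$primary[1:5]
  half_b <- gr$primary[6:10]
  cmp <- dgmb_compare(s$beta, half_a, half_b)
  expect_equal(sum(cmp$significant), 0)
  expect_error(dgmb_compare(s$beta, gr$nevus, gr$nevus), "overlap")
})

test_that("DGMB is antisymmetric and thresholds act monotonically", {
  s <- small_sim()
  gr <- split(s$samples$sample_id, s$samples$group)
  ab <- dgmb_compare(s$beta, gr$nevus, gr$primary)
  ba <- dgmb_compare(s$beta, gr$primary, gr$nevus)
  m <- merge(as.data.frame(ab)[, c("probe_id", "dgmb")],
             as.data.frame(ba)[, c("probe_id", "dgmb")], by = "probe_id")
  expect_equal(m$dgmb.x, -m$dgmb.y)
  sig_at <- function(dgmb_min, alpha)
    sum(dgmb_compare(s$beta, gr$nevus, gr$primary,
                     dgmb_min = dgmb_min, alpha = alpha)$significant)
  base <- sig_at(0.25, 0.05)
  expect_lte(sig_at(0.30, 0.05), base)  # raising the gate never adds
  expect_lte(sig_at(0.25, 0.01), base)  # lowering alpha never adds
})

test_that("planted probes are recovered with high sensitivity and low FDR", {
  cfg <- sim_config(seed = 77, n_probes = 2000, n_nevus = 15,
                    n_primary = 15, n_meta = 15,
                    frac_dev_hyper = 0.025, frac_dev_hypo = 0.025,
                    frac_prog_hyper = 0, frac_prog_hypo = 0,
                    effect_delta = 0.4, n_prognostic = 0)
  s <- simulate_beta(cfg)
  gr <- split(s$samples$sample_id, s$samples$group)
  cmp <- dgmb_compare(s$beta, gr$nevus, gr$primary, name = "nevus_vs_primary")
  planted_hyper <- s$truth$probe_id[s$truth$class == "dev_hyper"]
  planted_hypo <- s$truth$probe_id[s$truth$class == "dev_hypo"]
  sig <- cmp[cmp$significant, ]
  sens <- mean(c(planted_hyper %in% sig$probe_id[sig$direction == "hyper"],
                 planted_hypo %in% sig$probe_id[sig$direction == "hypo"]))
  fdr <- mean(!(sig$probe_id %in% c(planted_hyper, planted_hypo)))
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("hit-list crossing is consistent set algebra", {
  # construct three tiny comparisons by hand through dgmb_compare on
  # engineered data: probes A,B significant in both nevi comparisons,
  # C only in one, D with conflicting directions
  mk <- function(dgmbs) {
    # 10 samples per group; probe value = base +/- dgmb/2 with tiny jitter
    n <- 8
    beta <- t(sapply(seq_along(dgmbs), function(i) {
      c(seq(0.5 - 0.001, 0.5 + 0.001, length.out = n),
        seq(0.5 + dgmbs[i] - 0.001, 0.5 + dgmbs[i] + 0.001, length.out = n))
    }))
    dimnames(beta) <- list(names(dgmbs), paste0("s", 1:(2 * n)))
    dgmb_compare(beta, paste0("s", 1:n), paste0("s", (n + 1):(2 * n)))
  }
  np <- mk(c(A = 0.4, B = -0.4, C = 0.4, D = 0.4))
  nm <- mk(c(A = 0.4, B = -0.4, C = 0.0, D = -0.4))
  pm <- mk(c(A = 0.0, B = 0.0, C = 0.0, D = 0.4))
  ann <- structure(list(
    probes = data.frame(probe_id = c("A", "B", "C", "D"), chr = "chrS",
                        pos = 1:4, strand = "+",
                        gene_symbols = c("GA", "GB", "GC", "GD"),
                        gene_features = c("TSS200", "Body", "Body", "Body"),
                        island_start = NA_integer_, island_end = NA_integer_,
                        snp_overlap = 0L, is_genotyping = 0L),
    tss = data.frame(gene = character(0), tss_pos = integer(0)),
    islands = data.frame(start = integer(0), end = integer(0))),
    class = "probe_annotation")
  part <- cross_hit_lists(np, nm, pm, ann)
  expect_equal(part$probes$dev_hyper, "A")
  expect_equal(part$probes$dev_hypo, "B")
  expect_equal(part$conflict_probes, "D")     # hyper in np, hypo in nm
  expect_equal(part$dev_partial_probes, "C")  # significant in np only
  expect_equal(part$probes$prog_hyper, "D")
  expect_equal(part$genes$dev_hyper, "GA")
  expect_equal(part$promoter_genes$dev_hyper, "GA")
  expect_equal(part$promoter_genes$prog_hyper, character(0))
  expect_equal(part$common_genes, character(0))
  # empty progression comparison -> empty common genes
  pm0 <- mk(c(A = 0, B = 0, C = 0, D = 0))
  expect_equal(cross_hit_lists(np, nm, pm0, ann)$common_genes, character(0))
})

test_that("stage assignment on simulation separates dev from prog plants", {
  cfg <- sim_config(seed = 99, n_probes = 2000, n_nevus = 15,
                    n_primary = 15, n_meta = 15,
                    frac_dev_hyper = 0.02, frac_dev_hypo = 0.02,
                    frac_prog_hyper = 0.02, frac_prog_hypo = 0.02,
                    effect_delta = 0.4, n_prognostic = 0)
  s <- simulate_beta(cfg)
  ann <- simulate_manifest(n_probes = 2000, seed = 100)
  gr <- split(s$samples$sample_id, s$samples$group)
  part <- cross_hit_lists(
    dgmb_compare(s$beta, gr$nevus, gr$primary),
    dgmb_compare(s$beta, gr$nevus, gr$metastasis),
    dgmb_compare(s$beta, gr$primary, gr$metastasis), ann)
  acc <- mean(c(
    s$truth$probe_id[s$truth$class == "dev_hyper"] %in% part$probes$dev_hyper,
    s$truth$probe_id[s$truth$class == "dev_hypo"] %in% part$probes$dev_hypo,
    s$truth$probe_id[s$truth$class == "prog_hyper"] %in% part$probes$prog_hyper,
    s$truth$probe_id[s$truth$class == "prog_hypo"] %in% part$probes$prog_hypo))
  expect_gte(acc, 0.9)
})

test_that("compartment profile counts, fractions and Fisher p are coherent", {
  ann <- toy_annotation()
  prof <- methylprog:::profile_probe_sets(
    hyper_ids = c("p01", "p02", "p08"),   # all island
    hypo_ids = c("p04", "p05", "p06"),    # shelf + open sea
    ann)
  expect_equal(unname(prof$context_fractions["hyper", "island"]), 1)
  expect_equal(sum(prof$context_fractions["hyper", ]), 1)
  expect_equal(sum(prof$context_fractions["hypo", ]), 1)
  expect_equal(prof$fisher_p,
               fisher_enum_p(matrix(c(3, 0, 0, 3), 2, byrow = TRUE)),
               tolerance = 1e-12)
  # symmetric table -> p = 1
  prof2 <- methylprog:::profile_probe_sets(
    hyper_ids = c("p01", "p03"), hypo_ids = c("p02", "p05"), ann)
  expect_equal(prof2$fisher_p, 1)
})

test_that("partition reporting recomputes shares from counts", {
  part <- structure(list(
    genes = list(dev_hyper = sprintf("g%03d", 1:457),
                 dev_hypo = sprintf("h%02d", 1:63),
                 prog_hyper = sprintf("q%03d", 1:131),
                 prog_hypo = sprintf("r%03d", 1:383)),
    promoter_genes = list(dev_hyper = sprintf("g%03d", 1:255),
                          dev_hypo = character(0),
                          prog_hyper = sprintf("q%03d", 1:86),
                          prog_hypo = character(0)),
    probes = list(), common_genes = character(0)),
    class = "stage_partition")
  tab <- report_partition_fractions(part)
  hyper <- tab[tab$direction == "hyper", ]
  expect_equal(hyper$dev_share_pct, 77.7)   # 457 of 588
  expect_equal(hyper$prog_share_pct, 22.3)  # 131 of 588
  expect_equal(hyper$dev_promoter_pct, 55.8)  # 255 of 457
  expect_equal(hyper$prog_promoter_pct, 65.6) # 86 of 131 = 65.648...
  # degenerate: empty development set
  part$genes$dev_hyper <- character(0)
  part$promoter_genes$dev_hyper <- character(0)
  tab2 <- report_partition_fractions(part)
  expect_equal(tab2[tab2$direction == "hyper", "prog_share_pct"], 100.0)
  expect_true(is.na(tab2[tab2$direction == "hyper", "dev_promoter_pct"]))
})
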