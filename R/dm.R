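#' ANOVA pre-screen for variable probes
#'
#' First-pass probe selection across the three progression groups: a probe
#' is kept iff (i) a one-way ANOVA across the groups rejects at confidence
#' `conf` (p < 1 - conf) and (ii) at least `min_pairs` pairs of groups
#' differ in group median beta by at least `delta`. The defaults
#' (`delta = 0.33`, `conf = 0.99`) are the conventional screen for
#' three-group 450K designs.
#'
#' The per-probe F statistic is computed vectorised from the one-way
#' sum-of-squares decomposition over non-missing values (verified against
#' `stats::aov` in the test suite); probes with fewer than 2 non-missing
#' values in 2 groups, or no residual degrees of freedom, are skipped.
#'
#' @param beta beta-value matrix.
#' @param groups factor/character vector of group labels, one per column
#'   of `beta`.
#' @param delta minimum group-median difference.
#' @param conf ANOVA confidence level; the p-value cutoff is `1 - conf`.
#' @param min_pairs number of group pairs that must clear `delta`
#'   (1 = "at least one pair", the default reading).
#' @return character vector of selected probe IDs.
#' @export
anova_screen <- function(beta, groups, delta = 0.33, conf = 0.99,
                         min_pairs = 1L) {
  groups <- as.character(groups)
  if (length(groups) != ncol(beta))
    stop("groups must have one label per sample column")
  tab <- table(groups)
  if (any(tab == 0) || length(tab) < 2)
    stop("need at least two non-empty groups")
  lev <- names(tab)
  obs <- !is.na(beta)
  per_group <- function(f) {
    m <- vapply(lev, f, numeric(nrow(beta)))
    matrix(m, nrow = nrow(beta), dimnames = list(rownames(beta), lev))
  }
  # per-group counts, sums, sums of squares (vectorised over probes)
  cnt <- per_group(function(g) rowSums(obs[, groups == g, drop = FALSE]))
  sm <- per_group(function(g)
    rowSums(beta[, groups == g, drop = FALSE], na.rm = TRUE))
  sq <- per_group(function(g)
    rowSums(beta[, groups == g, drop = FALSE]^2, na.rm = TRUE))
  usable <- rowSums(cnt >= 2) >= 2
  k <- rowSums(cnt > 0)
  n <- rowSums(cnt)
  grand <- rowSums(sm)
  ssb <- rowSums(ifelse(cnt > 0, sm^2 / pmax(cnt, 1), 0)) - grand^2 / n
  sst <- rowSums(sq) - grand^2 / n
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # zero within-group variance with real between-group spread: p -> 0
  p[ssw <= 1e-12 & ssb > 1e-12] <- 0
  p[ssw <= 1e-12 & ssb <= 1e-12] <- 1
  p[!usable | df2 < 1] <- NA

  med <- per_group(function(g)
    apply(beta[, groups == g, drop = FALSE], 1, stats::median, na.rm = TRUE))
  pairs <- utils::combn(length(lev), 2)
  passes <- vapply(seq_len(ncol(pairs)), function(j) {
    abs(med[, pairs[1, j]] - med[, pairs[2, j]]) >= delta
  }, logical(nrow(beta)))
  npass <- rowSums(matrix(passes, nrow = nrow(beta)))
  sel <- !is.na(p) & p < (1 - conf) & npass >= min_pairs
  rownames(beta)[sel]
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of samples (columns) with the Ward minimum-
#' variance criterion on Euclidean distances over the selected probes.
#' Missing beta values are mean-imputed per probe before distances are
#' computed, so a shared mask never drops a sample.
#'
#' @param beta beta-value matrix.
#' @param probe_subset optional probe IDs to cluster on (e.g. the
#'   [anova_screen()] set); default all probes.
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust` (the merge tree) and, when `k` is given,
#'   `labels` (named integer cluster labels).
#' @export
ward_cluster <- function(beta, probe_subset = NULL, k = NULL) {
  if (ncol(beta) < 2) stop("need at least two samples to cluster")
  if (!is.null(probe_subset)) {
    missing <- setdiff(probe_subset, rownames(beta))
    if (length(missing) > 0)
      stop("probe(s) not in matrix: ", paste(missing, collapse = ", "))
    beta <- beta[probe_subset, , drop = FALSE]
  }
  if (anyNA(beta)) {
    rm <- rowMeans(beta, na.rm = TRUE)
    rm[is.nan(rm)] <- 0.5  # probe entirely missing: uninformative midpoint
    idx <- which(is.na(beta), arr.ind = TRUE)
    beta[idx] <- rm[idx[, 1]]
  }
  hc <- stats::hclust(stats::dist(t(beta), method = "euclidean"),
                      method = "ward.D2")
  out <- list(hclust = hc)
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value
#'
#' Exact p from the null rank-sum distribution when
#' `length(a) + length(b) <= exact_max` and the data are tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction. Returns `NA` (untestable) when either side has fewer than
#' `min_group_n` non-missing values.
#'
#' @param a,b numeric vectors (missing values dropped).
#' @param mode `"auto"` (size/tie-based dispatch), `"exact"` or `"normal"`.
#' @param exact_max largest combined sample size for the exact branch in
#'   auto mode.
#' @param min_group_n minimum non-missing values per side.
#' @return two-sided p-value in (0, 1], or `NA_real_` if untestable.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal"),
                         exact_max = 12L, min_group_n = 3L) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < min_group_n || length(b) < min_group_n)
    return(NA_real_)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
    auto = !ties && (length(a) + length(b)) <= exact_max,
    exact = TRUE,
    normal = FALSE)
  if (exact && ties)
    stop("exact Mann-Whitney requires tie-free data")
  p <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = "two.sided", exact = exact,
    correct = TRUE, paired = FALSE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR q-values: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]` (`NA` passed through).
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' DGMB differential-methylation comparison between two groups
#'
#' The core selection procedure. Per probe, the difference of group
#' methylation medians DGMB = median(group_b) - median(group_a) is computed
#' over non-missing values, with `group_b` the more advanced stage, so
#' `direction = "hyper"` means methylation gained toward the later stage.
#' With the default `gate_order = "gate_then_test"`, probes must first show
#' a large effect (|DGMB| >= `dgmb_min`); only the gated probes are then
#' tested by the probe-wise Mann-Whitney test, and Benjamini-Hochberg
#' adjustment runs within that gated family. A probe is significant iff it
#' passes the gate and its adjusted p is below `alpha`. The alternative
#' `"test_then_gate"` tests and adjusts all testable probes before gating.
#'
#' Probes with fewer than `min_group_n` non-missing values in either group
#' are untestable and excluded (IDs kept in attribute `"untestable"`).
#'
#' @param beta beta-value matrix.
#' @param group_a,group_b disjoint character vectors of sample IDs;
#'   `group_b` is the more advanced stage.
#' @param dgmb_min minimum absolute DGMB.
#' @param alpha adjusted-p significance level.
#' @param min_group_n minimum non-missing values per group per probe.
#' @param gate_order `"gate_then_test"` (default) or `"test_then_gate"`.
#' @param mode Mann-Whitney dispatch, see [mann_whitney()].
#' @param name label for the comparison (e.g. `"nevus_vs_primary"`).
#' @return A data.frame of class `"dgmb_comparison"` with one row per
#'   testable probe: `probe_id`, `median_a`, `median_b`, `dgmb`, `p_raw`,
#'   `p_adj`, `direction`, `significant`. Attributes: `name`, `params`,
#'   `untestable`.
#' @export
dgmb_compare <- function(beta, group_a, group_b, dgmb_min = 0.25,
                         alpha = 0.05, min_group_n = 3L,
                         gate_order = c("gate_then_test", "test_then_gate"),
                         mode = "auto", name = "a_vs_b") {
  gate_order <- match.arg(gate_order)
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  missing <- setdiff(c(group_a, group_b), colnames(beta))
  if (length(missing) > 0)
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(group_a) < min_group_n || length(group_b) < min_group_n)
    stop("each group needs at least min_group_n samples")

  ma <- beta[, group_a, drop = FALSE]
  mb <- beta[, group_b, drop = FALSE]
  na_ok <- rowSums(!is.na(ma)) >= min_group_n
  nb_ok <- rowSums(!is.na(mb)) >= min_group_n
  testable <- na_ok & nb_ok
  untestable <- rownames(beta)[!testable]

  med_a <- apply(ma[testable, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  med_b <- apply(mb[testable, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  dgmb <- med_b - med_a
  ids <- rownames(beta)[testable]
  gated <- abs(dgmb) >= dgmb_min

  test_idx <- if (gate_order == "gate_then_test") which(gated)
              else seq_along(ids)
  p_raw <- rep(NA_real_, length(ids))
  if (length(test_idx) > 0) {
    sub_a <- ma[testable, , drop = FALSE][test_idx, , drop = FALSE]
    sub_b <- mb[testable, , drop = FALSE][test_idx, , drop = FALSE]
    p_raw[test_idx] <- vapply(seq_len(nrow(sub_a)), function(i) {
      mann_whitney(sub_a[i, ], sub_b[i, ], mode = mode,
                   min_group_n = min_group_n)
    }, 0)
  }
  p_adj <- rep(NA_real_, length(ids))
  p_adj[test_idx] <- bh_adjust(p_raw[test_idx])
  significant <- gated & !is.na(p_adj) & p_adj < alpha

  out <- data.frame(
    probe_id = ids, median_a = med_a, median_b = med_b, dgmb = dgmb,
    p_raw = p_raw, p_adj = p_adj,
    direction = ifelse(dgmb >= 0, "hyper", "hypo"),
    significant = significant,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out,
            class = c("dgmb_comparison", "data.frame"),
            name = name,
            params = list(dgmb_min = dgmb_min, alpha = alpha,
                          min_group_n = min_group_n, gate_order = gate_order),
            untestable = untestable)
}

#' @export
print.dgmb_comparison <- function(x, ...) {
  pr <- attr(x, "params")
  cat(sprintf("DGMB comparison '%s' (|DGMB| >= %.2f, BH alpha %.3g, %s)\n",
              attr(x, "name"), pr$dgmb_min, pr$alpha, pr$gate_order))
  cat(sprintf("  %d testable probes, %d untestable\n",
              nrow(x), length(attr(x, "untestable"))))
  cat(sprintf("  significant: %d hyper, %d hypo\n",
              sum(x$significant & x$direction == "hyper"),
              sum(x$significant & x$direction == "hypo")))
  invisible(x)
}

#' @export
summary.dgmb_comparison <- function(object, ...) {
  sig <- object[object$significant, , drop = FALSE]
  list(name = attr(object, "name"),
       n_testable = nrow(object),
       n_untestable = length(attr(object, "untestable")),
       n_gated = sum(abs(object$dgmb) >= attr(object, "params")$dgmb_min),
       n_significant = nrow(sig),
       n_hyper = sum(sig$direction == "hyper"),
       n_hypo = sum(sig$direction == "hypo"))
}
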