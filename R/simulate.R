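#' Simulate a beta-value matrix with planted differential methylation
#'
#' Draws a probes x samples matrix of methylation beta values for three
#' progression groups (nevus, primary, metastasis) from a Beta noise model
#' parameterised by a probe-specific baseline mean and a shared precision.
#' Baseline means come from a bimodal mixture (low mode around 0.15, high
#' mode around 0.85), mimicking the marginal distribution of 450K arrays, so
#' both hyper- and hypomethylation plants are feasible.
#'
#' Planted classes shift the Beta mean of the affected groups by
#' `effect_delta` (development/progression classes) or `prognostic_delta`
#' (prognostic class, between the two survival-risk halves of the primary
#' tumors); see [sim_config()] for the class definitions. Hypermethylation
#' plants are forced onto low-baseline probes and vice versa, so the shifted
#' mean always stays inside (0, 1); configurations for which no valid
#' baseline exists are rejected.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"sim_beta"` with elements
#'   * `beta` — numeric matrix (probes x samples) in `[0,1]`, `NA` = missing;
#'   * `truth` — data.frame `probe_id`, `class` (one of `null`, `dev_hyper`,
#'     `dev_hypo`, `prog_hyper`, `prog_hypo`, `prognostic`), `direction`
#'     (`hyper`/`hypo`/`none`);
#'   * `samples` — data.frame `sample_id`, `group`, `risk_group`
#'     (`high`/`low` for primary tumors, `NA` otherwise).
#' @export
#' @examples
#' sim <- simulate_beta(sim_config(seed = 7, n_probes = 300))
#' range(sim$beta, na.rm = TRUE)
#' table(sim$truth$class)
simulate_beta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  eps <- 0.02  # margin keeping shifted Beta means strictly inside (0,1)
  if (config$effect_delta + 2 * eps >= 1 ||
      config$prognostic_delta + 2 * eps >= 1)
    stop("effect size too large: shifted group means would leave (0, 1)")
  set.seed(config$seed)

  n <- config$n_probes
  probe_ids <- sprintf("cg%08d", seq_len(n))
  groups <- c(rep("nevus", config$n_nevus),
              rep("primary", config$n_primary),
              rep("metastasis", config$n_meta))
  sample_ids <- c(sprintf("NEV%03d", seq_len(config$n_nevus)),
                  sprintf("PRI%03d", seq_len(config$n_primary)),
                  sprintf("MET%03d", seq_len(config$n_meta)))

  # survival-risk split of the primary tumors (used by the prognostic class)
  risk <- rep(NA_character_, length(groups))
  pri_idx <- which(groups == "primary")
  n_high <- floor(length(pri_idx) / 2)
  high_idx <- sample(pri_idx, n_high)
  risk[pri_idx] <- "low"
  risk[high_idx] <- "high"

  # carve planted classes out of a shuffled probe order
  counts <- c(dev_hyper = round(config$frac_dev_hyper * n),
              dev_hypo = round(config$frac_dev_hypo * n),
              prog_hyper = round(config$frac_prog_hyper * n),
              prog_hypo = round(config$frac_prog_hypo * n),
              prognostic = config$n_prognostic)
  shuffled <- sample.int(n)
  cls <- rep("null", n)
  at <- 0L
  for (k in names(counts)) {
    if (counts[[k]] > 0L) {
      cls[shuffled[at + seq_len(counts[[k]])]] <- k
      at <- at + counts[[k]]
    }
  }

  # baseline means: bimodal mixture; plants are forced onto the feasible mode
  mode_low <- runif(n) < 0.5
  m0 <- ifelse(mode_low, rbeta(n, 3, 17), rbeta(n, 17, 3))
  delta <- config$effect_delta
  pdel <- config$prognostic_delta
  up <- cls %in% c("dev_hyper", "prog_hyper")
  dn <- cls %in% c("dev_hypo", "prog_hypo")
  prog_dir <- rep("none", n)
  is_prog <- cls == "prognostic"
  prog_dir[is_prog] <- rep_len(c("hyper", "hypo"), sum(is_prog))
  m0[up] <- pmin(pmax(m0[up], eps), 1 - delta - eps)
  m0[dn] <- pmax(pmin(m0[dn], 1 - eps), delta + eps)
  m0[is_prog & prog_dir == "hyper"] <-
    pmin(pmax(m0[is_prog & prog_dir == "hyper"], eps), 1 - pdel - eps)
  m0[is_prog & prog_dir == "hypo"] <-
    pmax(pmin(m0[is_prog & prog_dir == "hypo"], 1 - eps), pdel + eps)
  m0 <- pmin(pmax(m0, eps), 1 - eps)

  # per-(probe, sample) target mean
  mu <- matrix(rep(m0, times = length(groups)), nrow = n)
  tumor <- groups %in% c("primary", "metastasis")
  meta <- groups == "metastasis"
  high <- !is.na(risk) & risk == "high"
  mu[cls == "dev_hyper", tumor] <- mu[cls == "dev_hyper", tumor] + delta
  mu[cls == "dev_hypo", tumor] <- mu[cls == "dev_hypo", tumor] - delta
  mu[cls == "prog_hyper", meta] <- mu[cls == "prog_hyper", meta] + delta
  mu[cls == "prog_hypo", meta] <- mu[cls == "prog_hypo", meta] - delta
  mu[is_prog & prog_dir == "hyper", high] <-
    mu[is_prog & prog_dir == "hyper", high] + pdel
  mu[is_prog & prog_dir == "hypo", high] <-
    mu[is_prog & prog_dir == "hypo", high] - pdel
  if (any(mu <= 0 | mu >= 1))
    stop("internal: shifted Beta mean outside (0, 1)")

  phi <- config$beta_precision
  beta <- matrix(rbeta(length(mu), mu * phi, (1 - mu) * phi),
                 nrow = n, dimnames = list(probe_ids, sample_ids))
  if (config$frac_missing > 0)
    beta[runif(length(beta)) < config$frac_missing] <- NA_real_

  direction <- rep("none", n)
  direction[up] <- "hyper"
  direction[dn] <- "hypo"
  direction[is_prog] <- prog_dir[is_prog]

  structure(list(
    beta = beta,
    truth = data.frame(probe_id = probe_ids, class = cls,
                       direction = direction, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_ids, group = groups,
                         risk_group = risk, stringsAsFactors = FALSE)
  ), class = "sim_beta")
}

#' Simulate a toy probe manifest with CpG islands and TSSs
#'
#' Lays probes along a single toy chromosome at a fixed step, places CpG
#' islands of width `island_width` at every `island_spacing` bp (island k
#' occupies offsets `[5000, 5000 + island_width)` of period k), and one gene
#' TSS per `tss_spacing` bp placed just inside each island region so that a
#' computable subset of probes satisfies the promoter-island rule (inside an
#' island and < 2000 bp from a TSS). Gene features are assigned
#' deterministically from the probe's offset relative to its gene's TSS:
#' upstream within 1500/200 bp gives TSS1500/TSS200, downstream offsets map
#' to 5'UTR, 1stExon, Body and 3'UTR in order.
#'
#' @param n_probes number of probes.
#' @param island_spacing period of the island lattice in bp; `0` requests a
#'   genome with no islands (all probes open sea).
#' @param tss_spacing period of the TSS lattice in bp; `0` = no genes.
#' @param seed seed for the SNP/genotyping flag draws.
#' @param island_width island width in bp.
#' @param probe_step distance between consecutive probes in bp; the default
#'   97 is coprime with the default lattices so probe offsets sample every
#'   residue of the island period evenly.
#' @param frac_snp,frac_genotyping fractions of probes flagged as
#'   SNP-overlapping / genotyping controls (removed by QC).
#' @return A `"probe_annotation"` list with `probes` (one row per probe:
#'   `probe_id`, `chr`, `pos`, `strand`, `gene_symbols`, `gene_features`,
#'   `island_start`, `island_end`, `snp_overlap`, `is_genotyping`),
#'   `tss` (`gene`, `tss_pos`) and `islands` (`start`, `end`).
#' @export
simulate_manifest <- function(n_probes, island_spacing = 10000,
                              tss_spacing = 10000, seed = 1L,
                              island_width = 1000, probe_step = 97,
                              frac_snp = 0.02, frac_genotyping = 0.01) {
  if (island_spacing < 0 || tss_spacing < 0)
    stop("spacings must be non-negative")
  if (n_probes < 1) stop("n_probes must be >= 1")
  if (probe_step < 1) stop("probe_step must be positive")
  set.seed(seed)

  pos <- 1L + (seq_len(n_probes) - 1L) * as.integer(probe_step)
  chr_len <- max(pos) + 10000L

  islands <- if (island_spacing > 0) {
    starts <- seq(5001L, chr_len, by = as.integer(island_spacing))
    data.frame(start = starts, end = starts + as.integer(island_width) - 1L)
  } else {
    data.frame(start = integer(0), end = integer(0))
  }

  tss <- if (tss_spacing > 0) {
    tss_pos <- seq(5101L, chr_len, by = as.integer(tss_spacing))
    data.frame(gene = sprintf("GENE%04d", seq_along(tss_pos)),
               tss_pos = tss_pos, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), tss_pos = integer(0))
  }

  # nearest island per probe (coords stored; absent when no islands exist)
  if (nrow(islands) > 0) {
    nearest <- nearest_interval(pos, islands$start, islands$end)
    isl_start <- islands$start[nearest]
    isl_end <- islands$end[nearest]
  } else {
    isl_start <- rep(NA_integer_, n_probes)
    isl_end <- rep(NA_integer_, n_probes)
  }

  gene_symbols <- rep("", n_probes)
  gene_features <- rep("", n_probes)
  if (nrow(tss) > 0) {
    ti <- vapply(pos, function(p) which.min(abs(tss$tss_pos - p)), 1L)
    off <- pos - tss$tss_pos[ti]  # negative = upstream of TSS
    feat <- rep(NA_character_, n_probes)
    feat[off >= -1500 & off < -200] <- "TSS1500"
    feat[off >= -200 & off < 0] <- "TSS200"
    feat[off >= 0 & off < 300] <- "5UTR"
    feat[off >= 300 & off < 600] <- "1stExon"
    feat[off >= 600 & off < 2400] <- "Body"
    feat[off >= 2400 & off <= 3000] <- "3UTR"
    hit <- !is.na(feat)
    gene_symbols[hit] <- tss$gene[ti[hit]]
    gene_features[hit] <- feat[hit]
  }

  probes <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chr = "chrS", pos = pos, strand = "+",
    gene_symbols = gene_symbols, gene_features = gene_features,
    island_start = isl_start, island_end = isl_end,
    snp_overlap = as.integer(runif(n_probes) < frac_snp),
    is_genotyping = as.integer(runif(n_probes) < frac_genotyping),
    stringsAsFactors = FALSE
  )
  structure(list(probes = probes, tss = tss, islands = islands),
            class = "probe_annotation")
}

# index of the interval (starts/ends, parallel) nearest to each position;
# distance is 0 inside an interval
nearest_interval <- function(pos, starts, ends) {
  vapply(pos, function(p) {
    d <- pmax(starts - p, p - ends, 0L)
    which.min(d)
  }, 1L)
}

#' Simulate differential-expression tables with sign-concordant effects
#'
#' Emits one differential-expression table per source label covering the
#' planted differentially methylated genes. A seeded `concordant_frac`
#' subset of genes receives, in one randomly assigned source table, a
#' log2 fold change of sign opposite to its methylation direction with
#' `|logFC| >= 1` and `q < 0.05` (the conventional two-fold / q < 0.05
#' significance gate); every other (gene, table) entry is null
#' (`|logFC| < 1`, `q >= 0.05`).
#'
#' @param gene_truth data.frame with columns `gene` and `direction`
#'   (`hyper`/`hypo`), one row per planted gene.
#' @param concordant_frac fraction of genes given a concordant expression
#'   signal in at least one table.
#' @param seed integer seed.
#' @param sources character vector of table labels.
#' @return A list of data.frames (`gene`, `logFC`, `q`, `source`), one per
#'   source, with attribute `"truth"`: `gene`, `direction`, `concordant`,
#'   `signal_source`.
#' @export
simulate_expression <- function(gene_truth, concordant_frac, seed = 1L,
                                sources = c("expr1", "expr2", "expr3")) {
  stopifnot(is.data.frame(gene_truth),
            all(c("gene", "direction") %in% names(gene_truth)))
  if (concordant_frac < 0 || concordant_frac > 1)
    stop("concordant_frac must lie in [0, 1]")
  set.seed(seed)
  ng <- nrow(gene_truth)
  n_conc <- round(concordant_frac * ng)
  conc_idx <- if (n_conc > 0) sample.int(ng, n_conc) else integer(0)
  concordant <- seq_len(ng) %in% conc_idx
  signal_source <- rep(NA_character_, ng)
  signal_source[concordant] <- sample(sources, sum(concordant), replace = TRUE)

  tables <- lapply(sources, function(src) {
    logFC <- runif(ng, -0.8, 0.8)
    q <- runif(ng, 0.05, 1)
    sig <- concordant & signal_source == src
    sgn <- ifelse(gene_truth$direction == "hyper", -1, 1)
    logFC[sig] <- sgn[sig] * runif(sum(sig), 1.2, 3)
    q[sig] <- runif(sum(sig), 0, 0.049)
    data.frame(gene = gene_truth$gene, logFC = logFC, q = q,
               source = rep(src, ng), stringsAsFactors = FALSE)
  })
  names(tables) <- sources
  attr(tables, "truth") <- data.frame(
    gene = gene_truth$gene, direction = gene_truth$direction,
    concordant = concordant, signal_source = signal_source,
    stringsAsFactors = FALSE
  )
  tables
}

#' Simulate survival records with a marker-dependent hazard
#'
#' Event times are exponential with baseline hazard `log(2)/baseline_median`
#' (months) multiplied by `hazard_ratio` for marker-high samples. Censoring
#' times are uniform on `(0, u)` with `u` tuned by root finding so the
#' expected censored fraction equals `censor_frac`; `censor_frac = 0` yields
#' no censoring. Breslow thickness (log-normal, thicker for marker-high) and
#' ulceration (Bernoulli, likelier for marker-high) are generated as
#' correlated clinical covariates.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param marker_levels logical/0-1 vector, `TRUE`/1 = marker high.
#' @param hazard_ratio multiplicative hazard for marker-high samples.
#' @param censor_frac target fraction of censored records, in `[0, 1)`.
#' @param seed integer seed.
#' @param baseline_median median survival (months) of marker-low samples.
#' @return data.frame `sample_id`, `time` (months), `event` (logical),
#'   `marker_level` (`"high"`/`"low"`), `breslow_mm`, `ulceration`.
#' @export
simulate_survival <- function(sample_ids, marker_levels, hazard_ratio,
                              censor_frac, seed = 1L, baseline_median = 40) {
  n <- length(sample_ids)
  marker <- as.logical(marker_levels)
  if (length(marker) != n || anyNA(marker))
    stop("marker_levels must be binary, one per sample")
  if (censor_frac < 0 || censor_frac >= 1)
    stop("censor_frac must lie in [0, 1)")
  set.seed(seed)
  lambda0 <- log(2) / baseline_median
  rate <- lambda0 * ifelse(marker, hazard_ratio, 1)
  t_event <- rexp(n, rate)
  if (censor_frac > 0) {
    # P(C < T) for C ~ U(0,u), T ~ Exp(rate): (1 - exp(-rate*u)) / (rate*u)
    cens_prob <- function(u) mean((1 - exp(-rate * u)) / (rate * u))
    u <- uniroot(function(u) cens_prob(u) - censor_frac,
                 lower = 1e-6, upper = 1e7, tol = 1e-9)$root
    t_cens <- runif(n, 0, u)
    time <- pmin(t_event, t_cens)
    event <- t_event <= t_cens
  } else {
    time <- t_event
    event <- rep(TRUE, n)
  }
  data.frame(
    sample_id = sample_ids, time = time, event = event,
    marker_level = ifelse(marker, "high", "low"),
    breslow_mm = rlnorm(n, meanlog = log(2) + 0.4 * marker, sdlog = 0.5),
    ulceration = runif(n) < (0.15 + 0.25 * marker),
    stringsAsFactors = FALSE
  )
}
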