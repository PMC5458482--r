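#' Pipeline run configuration
#'
#' Collects every stage threshold (defaulting to the conventional values of
#' the progression-methylome screen: DGMB >= 0.25 at BH alpha 0.05, ANOVA
#' delta 0.33 at confidence 0.99, survivor signature diff >= 0.2 at
#' q < 0.01, two-fold expression change at q < 0.05, 48-month survival
#' cutoff), the simulation settings and the output directory.
#'
#' @param seed master seed; stage generators derive their seeds from it.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param dgmb_min,alpha [dgmb_compare()] thresholds.
#' @param anova_delta,anova_conf [anova_screen()] thresholds.
#' @param diff_min,q_max [survivor_signature()] thresholds.
#' @param fc_min,de_q_max [call_expression()] thresholds.
#' @param cutoff_months survivor-signature survival cutoff.
#' @param min_group_n minimum non-missing values per group per probe.
#' @param gate_order DGMB gate ordering, see [dgmb_compare()].
#' @param concordant_frac planted concordant-expression fraction for the
#'   simulated DE tables.
#' @param dichotomize_rule marker dichotomization rule, see [dichotomize()].
#' @param out_dir output directory (created if absent); `NULL` = no files.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, sim = sim_config(seed = seed),
                       dgmb_min = 0.25, alpha = 0.05,
                       anova_delta = 0.33, anova_conf = 0.99,
                       diff_min = 0.2, q_max = 0.01,
                       fc_min = 1, de_q_max = 0.05,
                       cutoff_months = 48, min_group_n = 3L,
                       gate_order = "gate_then_test",
                       concordant_frac = 0.5,
                       dichotomize_rule = "median",
                       out_dir = NULL) {
  stopifnot(dgmb_min > 0, dgmb_min < 1, alpha > 0, alpha < 1,
            anova_delta > 0, anova_delta < 1, anova_conf > 0, anova_conf < 1,
            diff_min > 0, diff_min < 1, q_max > 0, q_max < 1,
            fc_min > 0, de_q_max > 0, de_q_max < 1, cutoff_months > 0,
            concordant_frac >= 0, concordant_frac <= 1)
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, dgmb_min = dgmb_min,
                 alpha = alpha, anova_delta = anova_delta,
                 anova_conf = anova_conf, diff_min = diff_min, q_max = q_max,
                 fc_min = fc_min, de_q_max = de_q_max,
                 cutoff_months = cutoff_months,
                 min_group_n = as.integer(min_group_n),
                 gate_order = gate_order,
                 concordant_frac = concordant_frac,
                 dichotomize_rule = dichotomize_rule, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys override [run_config()] defaults;
#'   simulation keys live under `sim:`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  sim <- do.call(sim_config, c(list(seed = if (!is.null(y$seed)) y$seed else 1L),
                               sim_args[setdiff(names(sim_args), "seed")]))
  do.call(run_config, c(y, list(sim = sim)))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full progression-methylome pipeline on simulated data
#'
#' Executes every stage in order — simulate, probe QC, ANOVA screen with
#' Ward clustering, the three DGMB comparisons, hit-list crossing and
#' compartment profiling, methylation-expression integration, and the
#' prognosis stage (survivor signature, Kaplan-Meier, log-rank, Cox on the
#' dichotomized risk marker) — and returns one summary. Re-running with the
#' same configuration reproduces the summary exactly. When
#' `config$out_dir` is set, per-stage tables, a `summary.json` and a run
#' log are written there.
#'
#' @param config a [run_config()].
#' @return list of class `"pipeline_result"` with elements `summary`
#'   (plain list, JSON-stable), `sim`, `annotation`, `comparisons`,
#'   `partition`, `profiles`, `integration`, `signature`, `survival`
#'   (records, km per arm, logrank, cox), `cluster`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  sim <- with_stage("simulate", simulate_beta(config$sim))
  ann <- with_stage("simulate", simulate_manifest(
    n_probes = config$sim$n_probes, seed = seed + 1L))
  truth_genes <- with_stage("simulate", planted_gene_truth(sim$truth, ann))
  de_tables <- with_stage("simulate", simulate_expression(
    truth_genes, concordant_frac = config$concordant_frac,
    seed = seed + 2L))

  beta <- with_stage("qc", qc_filter_probes(sim$beta, ann))
  qc_removed <- attr(beta, "qc_removed")

  groups <- sim$samples$group[match(colnames(beta), sim$samples$sample_id)]
  screen <- with_stage("screen", anova_screen(
    beta, groups, delta = config$anova_delta, conf = config$anova_conf))
  cluster <- with_stage("screen", if (length(screen) >= 2)
    ward_cluster(beta, screen, k = 3) else NULL)

  gr <- split(sim$samples$sample_id, sim$samples$group)
  cmp <- function(a, b, nm) dgmb_compare(
    beta, intersect(gr[[a]], colnames(beta)),
    intersect(gr[[b]], colnames(beta)),
    dgmb_min = config$dgmb_min, alpha = config$alpha,
    min_group_n = config$min_group_n, gate_order = config$gate_order,
    name = nm)
  cmp_np <- with_stage("dgmb", cmp("nevus", "primary", "nevus_vs_primary"))
  cmp_nm <- with_stage("dgmb", cmp("nevus", "metastasis", "nevus_vs_metastasis"))
  cmp_pm <- with_stage("dgmb", cmp("primary", "metastasis",
                                   "primary_vs_metastasis"))

  partition <- with_stage("cross", cross_hit_lists(cmp_np, cmp_nm, cmp_pm, ann))
  profiles <- with_stage("compartments", list(
    development = compartment_profile(partition, ann, stage = "development"),
    progression = compartment_profile(partition, ann, stage = "progression")))

  dm_genes <- with_stage("integrate", partition_gene_directions(partition))
  integration <- with_stage("integrate", integrate_expression(
    dm_genes, de_tables, fc_min = config$fc_min, q_max = config$de_q_max))

  pri <- sim$samples[sim$samples$group == "primary", , drop = FALSE]
  surv <- with_stage("prognosis", simulate_survival(
    pri$sample_id, pri$risk_group == "high",
    hazard_ratio = config$sim$hazard_ratio,
    censor_frac = config$sim$censor_frac, seed = seed + 3L))
  sheet <- with_stage("prognosis", data.frame(
    sample_id = sim$samples$sample_id, group = sim$samples$group,
    survival_months = surv$time[match(sim$samples$sample_id, surv$sample_id)],
    event = surv$event[match(sim$samples$sample_id, surv$sample_id)],
    breslow_mm = surv$breslow_mm[match(sim$samples$sample_id, surv$sample_id)],
    ulceration = surv$ulceration[match(sim$samples$sample_id, surv$sample_id)],
    stringsAsFactors = FALSE))
  signature <- with_stage("prognosis", tryCatch(
    survivor_signature(beta, sheet, cutoff_months = config$cutoff_months,
                       diff_min = config$diff_min, q_max = config$q_max,
                       min_group_n = config$min_group_n),
    error = function(e) e))
  km <- with_stage("prognosis", lapply(
    split(surv, surv$marker_level),
    function(d) km_estimate(d$time, d$event)))
  lr <- with_stage("prognosis",
                   logrank_test(surv$time, surv$event, surv$marker_level))
  cox <- with_stage("prognosis", cox_fit(
    data.frame(time = surv$time, event = surv$event,
               marker_level = surv$marker_level,
               breslow_mm = surv$breslow_mm, ulceration = surv$ulceration)))

  sig_ok <- inherits(signature, "survivor_signature")
  summary <- list(
    seed = seed,
    n_probes = config$sim$n_probes,
    n_samples = nrow(sim$samples),
    qc_removed = as.list(qc_removed),
    n_anova_selected = length(screen),
    comparisons = lapply(list(cmp_np, cmp_nm, cmp_pm),
                         summary.dgmb_comparison),
    partition = list(
      dev_hyper_probes = length(partition$probes$dev_hyper),
      dev_hypo_probes = length(partition$probes$dev_hypo),
      prog_hyper_probes = length(partition$probes$prog_hyper),
      prog_hypo_probes = length(partition$probes$prog_hypo),
      common_genes = length(partition$common_genes),
      fractions = report_partition_fractions(partition)),
    compartments = list(
      development_fisher_p = profiles$development$fisher_p,
      development_hyper_island_frac =
        unname(profiles$development$context_fractions["hyper", "island"]),
      progression_fisher_p = profiles$progression$fisher_p),
    integration = integration$summary,
    signature = if (sig_ok) {
      list(n_selected = sum(signature$selected), n_testable = nrow(signature))
    } else {
      list(error = conditionMessage(signature))
    },
    survival = list(logrank_chi_square = lr$chi_square, logrank_p = lr$p,
                    cox = as.data.frame(cox))
  )

  res <- structure(list(summary = summary, sim = sim, annotation = ann,
                        de_tables = de_tables,
                        comparisons = list(nevus_vs_primary = cmp_np,
                                           nevus_vs_metastasis = cmp_nm,
                                           primary_vs_metastasis = cmp_pm),
                        partition = partition, profiles = profiles,
                        integration = integration,
                        signature = if (sig_ok) signature else NULL,
                        survival = list(records = surv, sheet = sheet,
                                        km = km, logrank = lr, cox = cox),
                        cluster = cluster, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Progression-methylome pipeline run (seed %d)\n", s$seed))
  cat(sprintf("  %d probes x %d samples; QC removed %d; ANOVA screen kept %d\n",
              s$n_probes, s$n_samples, s$qc_removed$total, s$n_anova_selected))
  for (cs in s$comparisons)
    cat(sprintf("  %s: %d significant (%d hyper / %d hypo)\n",
                cs$name, cs$n_significant, cs$n_hyper, cs$n_hypo))
  cat(sprintf("  integration: %d/%d concordant; signature: %s probes\n",
              s$integration$n_concordant, s$integration$n_testable,
              if (!is.null(s$signature$n_selected))
                s$signature$n_selected else "n/a"))
  invisible(x)
}

# direction of each planted gene, from probe truth + annotation
planted_gene_truth <- function(truth, ann) {
  feat <- classify_gene_feature(ann)
  feat$gene <- toupper(feat$gene)
  planted <- truth[truth$direction %in% c("hyper", "hypo") &
                     truth$class != "prognostic", , drop = FALSE]
  m <- merge(planted, feat[, c("probe_id", "gene")], by = "probe_id")
  if (nrow(m) == 0)
    return(data.frame(gene = character(0), direction = character(0)))
  agg <- stats::aggregate(direction ~ gene, data = m, FUN = function(d) {
    if (length(unique(d)) == 1) unique(d) else NA_character_
  })
  agg <- agg[!is.na(agg$direction), , drop = FALSE]
  data.frame(gene = agg$gene, direction = agg$direction,
             stringsAsFactors = FALSE)
}

# one direction per significant gene; genes hit in both directions dropped
partition_gene_directions <- function(partition) {
  hyper <- union(partition$genes$dev_hyper, partition$genes$prog_hyper)
  hypo <- union(partition$genes$dev_hypo, partition$genes$prog_hypo)
  both <- intersect(hyper, hypo)
  data.frame(
    gene = c(setdiff(hyper, both), setdiff(hypo, both)),
    direction = c(rep("hyper", length(setdiff(hyper, both))),
                  rep("hypo", length(setdiff(hypo, both)))),
    stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_beta_matrix(res$sim$beta, p("beta.tsv"))
  utils::write.table(res$sim$truth, p("ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(res$annotation, p("manifest.tsv"), p("tss.tsv"))
  write_sample_sheet(res$survival$sheet, p("sample_sheet.csv"))
  write_de_tables(res$de_tables, p("de_tables.tsv"))
  for (nm in names(res$comparisons))
    utils::write.table(as.data.frame(res$comparisons[[nm]]),
                       p(paste0("dgmb_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  part_rows <- do.call(rbind, lapply(names(res$partition$genes), function(k) {
    g <- res$partition$genes[[k]]
    if (length(g) == 0) return(NULL)
    data.frame(gene = g,
               stage = sub("_(hyper|hypo)$", "", k),
               direction = sub("^(dev|prog)_", "", k),
               promoter_flag = g %in% res$partition$promoter_genes[[k]],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(part_rows))
    utils::write.table(part_rows, p("partition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  writeLines(c(
    paste("R", as.character(getRversion())),
    paste("methylprog", as.character(utils::packageVersion("methylprog"))),
    paste("seed", res$config$seed),
    "config:",
    yaml::as.yaml(unclass_run_config(res$config))), p("run.log"))
  invisible(out_dir)
}

unclass_run_config <- function(cfg) {
  out <- unclass(cfg)
  out$sim <- unclass(out$sim)
  out
}
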