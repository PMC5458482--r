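#' Percentage share, one-decimal convention
#'
#' All reported percentages recompute from their own counts as
#' `round(100 * part / whole, 1)`; an empty denominator gives `NA`.
#'
#' @param part,whole numeric counts.
#' @return percentage rounded to one decimal, `NA_real_` when `whole` is 0.
#' @export
#' @examples
#' share_pct(457, 457 + 131)  # 77.7
share_pct <- function(part, whole) {
  ifelse(whole == 0, NA_real_, round(100 * part / whole, 1))
}

#' Cross stage-wise hit lists into development and progression sets
#'
#' Development (early-phase) changes are probes significant with a
#' consistent direction in BOTH the nevus-vs-primary and nevus-vs-metastasis
#' comparisons; probes significant in both but with conflicting directions
#' are excluded and logged, probes significant in only one nevi comparison
#' are reported separately (`dev_partial_probes`), not silently dropped.
#' Progression changes are probes significant in primary-vs-metastasis.
#' Gene-level sets are unique upper-cased symbols of the probes' exploded
#' gene annotations; a gene is a promoter gene of its set if at least one of
#' its significant probes sits in a promoter feature (TSS1500, TSS200,
#' 5'UTR, 1stExon).
#'
#' @param cmp_nevus_primary,cmp_nevus_meta,cmp_primary_meta
#'   [dgmb_compare()] results on the same probe universe, each with the
#'   later stage as `group_b`.
#' @param ann `"probe_annotation"` for gene-level summarisation.
#' @return A list of class `"stage_partition"`: `probes` and `genes` (each
#'   with `dev_hyper`, `dev_hypo`, `prog_hyper`, `prog_hypo`),
#'   `promoter_genes` (same slots), `common_genes` (development x
#'   progression gene intersection), `common_by_direction`,
#'   `dev_partial_probes`, `conflict_probes`.
#' @export
cross_hit_lists <- function(cmp_nevus_primary, cmp_nevus_meta,
                            cmp_primary_meta, ann) {
  for (cmp in list(cmp_nevus_primary, cmp_nevus_meta, cmp_primary_meta))
    stopifnot(inherits(cmp, "dgmb_comparison"))

  sig <- function(cmp, dir) cmp$probe_id[cmp$significant & cmp$direction == dir]
  np_h <- sig(cmp_nevus_primary, "hyper"); np_l <- sig(cmp_nevus_primary, "hypo")
  nm_h <- sig(cmp_nevus_meta, "hyper");    nm_l <- sig(cmp_nevus_meta, "hypo")

  dev_hyper <- intersect(np_h, nm_h)
  dev_hypo <- intersect(np_l, nm_l)
  conflict <- union(intersect(np_h, nm_l), intersect(np_l, nm_h))
  one_sided <- setdiff(union(c(np_h, np_l), c(nm_h, nm_l)),
                       c(dev_hyper, dev_hypo, conflict))
  prog_hyper <- sig(cmp_primary_meta, "hyper")
  prog_hypo <- sig(cmp_primary_meta, "hypo")

  feat <- classify_gene_feature(ann)
  feat$gene <- toupper(feat$gene)
  genes_of <- function(ids) sort(unique(feat$gene[feat$probe_id %in% ids]))
  promoter_genes_of <- function(ids)
    sort(unique(feat$gene[feat$probe_id %in% ids & feat$promoter]))

  probes <- list(dev_hyper = dev_hyper, dev_hypo = dev_hypo,
                 prog_hyper = prog_hyper, prog_hypo = prog_hypo)
  genes <- lapply(probes, genes_of)
  promoter_genes <- lapply(probes, promoter_genes_of)

  dev_genes <- union(genes$dev_hyper, genes$dev_hypo)
  prog_genes <- union(genes$prog_hyper, genes$prog_hypo)
  structure(list(
    probes = probes, genes = genes, promoter_genes = promoter_genes,
    common_genes = sort(intersect(dev_genes, prog_genes)),
    common_by_direction = list(
      hyper = sort(intersect(genes$dev_hyper, genes$prog_hyper)),
      hypo = sort(intersect(genes$dev_hypo, genes$prog_hypo))),
    dev_partial_probes = sort(one_sided),
    conflict_probes = sort(conflict)
  ), class = "stage_partition")
}

#' @export
print.stage_partition <- function(x, ...) {
  cat("Stage partition of differential methylation\n")
  cat(sprintf("  development: %d hyper / %d hypo probes (%d / %d genes)\n",
              length(x$probes$dev_hyper), length(x$probes$dev_hypo),
              length(x$genes$dev_hyper), length(x$genes$dev_hypo)))
  cat(sprintf("  progression: %d hyper / %d hypo probes (%d / %d genes)\n",
              length(x$probes$prog_hyper), length(x$probes$prog_hypo),
              length(x$genes$prog_hyper), length(x$genes$prog_hypo)))
  cat(sprintf("  common genes: %d; partial-evidence probes: %d; conflicts: %d\n",
              length(x$common_genes), length(x$dev_partial_probes),
              length(x$conflict_probes)))
  invisible(x)
}

#' Genomic-compartment profile of significant probes
#'
#' Counts and fractions of hyper- and hypomethylated probes per CpG-density
#' context (island / shore / shelf / open sea) and per gene feature, plus a
#' two-tailed Fisher exact test of the 2x2 table
#' \{hyper, hypo\} x \{island, non-island\} asking whether gains of
#' methylation preferentially target CpG islands.
#'
#' @param x a [dgmb_compare()] result (uses its significant probes) or a
#'   [cross_hit_lists()] partition (selects one stage via `stage`).
#' @param ann `"probe_annotation"`.
#' @param stage for a partition: `"development"` or `"progression"`.
#' @param ... unused.
#' @return list of class `"compartment_profile"`: `context_counts`,
#'   `context_fractions` (rows hyper/hypo, columns island/shore/shelf/
#'   open_sea, fractions summing to 1 per row), `feature_counts`,
#'   `fisher_p`, `fisher_table`.
#' @export
compartment_profile <- function(x, ann, ...) UseMethod("compartment_profile")

#' @rdname compartment_profile
#' @export
compartment_profile.dgmb_comparison <- function(x, ann, ...) {
  profile_probe_sets(x$probe_id[x$significant & x$direction == "hyper"],
                     x$probe_id[x$significant & x$direction == "hypo"], ann)
}

#' @rdname compartment_profile
#' @export
compartment_profile.stage_partition <- function(x, ann,
    stage = c("development", "progression"), ...) {
  stage <- match.arg(stage)
  if (stage == "development")
    profile_probe_sets(x$probes$dev_hyper, x$probes$dev_hypo, ann)
  else
    profile_probe_sets(x$probes$prog_hyper, x$probes$prog_hypo, ann)
}

profile_probe_sets <- function(hyper_ids, hypo_ids, ann) {
  ctx_levels <- c("island", "shore", "shelf", "open_sea")
  feat_levels <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
  count_ctx <- function(ids) {
    ctx <- factor(classify_island_context(ann, ids), levels = ctx_levels)
    table(ctx)
  }
  count_feat <- function(ids) {
    if (length(ids) == 0)
      return(table(factor(character(0), levels = feat_levels)))
    f <- classify_gene_feature(ann, ids)
    # one count per (probe, distinct feature)
    u <- unique(f[, c("probe_id", "feature")])
    table(factor(u$feature, levels = feat_levels))
  }
  cc <- rbind(hyper = count_ctx(hyper_ids), hypo = count_ctx(hypo_ids))
  fr <- cc / pmax(rowSums(cc), 1)
  fc <- rbind(hyper = count_feat(hyper_ids), hypo = count_feat(hypo_ids))
  tab <- cbind(island = cc[, "island"],
               non_island = rowSums(cc[, c("shore", "shelf", "open_sea")]))
  fisher_p <- if (all(rowSums(tab) > 0)) fisher_two_sided(tab) else NA_real_
  structure(list(context_counts = cc, context_fractions = fr,
                 feature_counts = fc, fisher_table = tab,
                 fisher_p = fisher_p),
            class = "compartment_profile")
}

# two-tailed Fisher exact p on a 2x2 table (hypergeometric enumeration)
fisher_two_sided <- function(tab) {
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' @export
print.compartment_profile <- function(x, ...) {
  cat("Compartment profile (fractions per direction)\n")
  print(round(x$context_fractions, 3))
  cat(sprintf("Fisher exact p (island association, two-tailed): %.3g\n",
              x$fisher_p))
  invisible(x)
}

#' Reporting summary of a stage partition
#'
#' Emits, per direction, the development and progression unique-gene counts,
#' each stage's percentage of the pooled (development + progression) gene
#' list, and the promoter-hypermethylation percentage within each stage —
#' the headline summary of a progression methylome screen. Percentages are
#' recomputed from the counts at one-decimal precision; an empty pooled
#' list yields `NA` shares.
#'
#' @param partition a [cross_hit_lists()] result.
#' @return data.frame with one row per direction (`hyper`, `hypo`):
#'   `n_dev`, `n_prog`, `dev_share_pct`, `prog_share_pct`,
#'   `dev_promoter_pct`, `prog_promoter_pct`.
#' @export
report_partition_fractions <- function(partition) {
  stopifnot(inherits(partition, "stage_partition"))
  row_for <- function(dir) {
    nd <- length(partition$genes[[paste0("dev_", dir)]])
    np <- length(partition$genes[[paste0("prog_", dir)]])
    pd <- length(partition$promoter_genes[[paste0("dev_", dir)]])
    pp <- length(partition$promoter_genes[[paste0("prog_", dir)]])
    data.frame(direction = dir, n_dev = nd, n_prog = np,
               dev_share_pct = share_pct(nd, nd + np),
               prog_share_pct = share_pct(np, nd + np),
               dev_promoter_pct = share_pct(pd, nd),
               prog_promoter_pct = share_pct(pp, np),
               stringsAsFactors = FALSE)
  }
  rbind(row_for("hyper"), row_for("hypo"))
}
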