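#' Remove SNP-overlapping and genotyping probes
#'
#' Probe-level QC: drops probes flagged as overlapping a known SNP and the
#' chip's genotyping control probes; both carry genetic rather than
#' epigenetic signal. The operation is idempotent.
#'
#' @param beta beta-value matrix (probes x samples).
#' @param ann `"probe_annotation"` covering every probe of `beta`.
#' @return the filtered matrix; attribute `"qc_removed"` holds the counts of
#'   probes removed per flag.
#' @export
qc_filter_probes <- function(beta, ann) {
  p <- ann$probes
  missing_ann <- setdiff(rownames(beta), p$probe_id)
  if (length(missing_ann) > 0)
    stop("probe(s) absent from annotation: ",
         paste(utils::head(missing_ann, 10), collapse = ", "),
         if (length(missing_ann) > 10) ", ..." else "")
  idx <- match(rownames(beta), p$probe_id)
  snp <- p$snp_overlap[idx] == 1
  geno <- p$is_genotyping[idx] == 1
  keep <- !(snp | geno)
  out <- beta[keep, , drop = FALSE]
  attr(out, "qc_removed") <- c(snp_overlap = sum(snp),
                               genotyping = sum(geno),
                               total = sum(!keep))
  out
}

#' Promoter-CpG-island predicate
#'
#' A probe is in a promoter CpG island iff it lies within a CpG island and
#' less than 2000 bp (strict) from the nearest transcription start site.
#' Probes with no island annotation are never promoter-island.
#'
#' @param probe_ids probe IDs to classify (default: all annotated probes).
#' @param ann `"probe_annotation"` object.
#' @param max_tss_dist strict distance ceiling to the nearest TSS in bp.
#' @return named logical vector.
#' @export
classify_promoter_island <- function(ann, probe_ids = NULL,
                                     max_tss_dist = 2000) {
  p <- sel_probes(ann, probe_ids)
  in_island <- !is.na(p$island_start) &
    p$pos >= p$island_start & p$pos <= p$island_end
  near_tss <- if (nrow(ann$tss) > 0) {
    vapply(p$pos, function(x) min(abs(ann$tss$tss_pos - x)), 0) < max_tss_dist
  } else {
    rep(FALSE, nrow(p))
  }
  stats::setNames(in_island & near_tss, p$probe_id)
}

#' CpG-density context of a probe
#'
#' Classifies each probe by distance to the nearest CpG island: `island`
#' inside an island, `shore` within 2000 bp of an island edge, `shelf`
#' between 2000 and 4000 bp, `open_sea` beyond (the conventional Illumina
#' shore/shelf widths). The four labels are mutually exclusive and
#' exhaustive; a genome with no islands is all open sea.
#'
#' @inheritParams classify_promoter_island
#' @return named character vector with levels
#'   `island`, `shore`, `shelf`, `open_sea`.
#' @export
classify_island_context <- function(ann, probe_ids = NULL) {
  p <- sel_probes(ann, probe_ids)
  if (nrow(ann$islands) == 0)
    return(stats::setNames(rep("open_sea", nrow(p)), p$probe_id))
  d <- vapply(p$pos, function(x) {
    min(pmax(ann$islands$start - x, x - ann$islands$end, 0))
  }, 0)
  ctx <- ifelse(d == 0, "island",
         ifelse(d <= 2000, "shore",
         ifelse(d <= 4000, "shelf", "open_sea")))
  stats::setNames(ctx, p$probe_id)
}

#' Gene-feature assignments of probes
#'
#' Explodes the `;`-separated multi-gene annotation into one
#' (probe, gene, feature) row per assignment and validates the feature
#' vocabulary (`TSS1500`, `TSS200`, `5UTR`, `1stExon`, `Body`, `3UTR`).
#' The promoter predicate is feature membership in
#' \{TSS1500, TSS200, 5UTR, 1stExon\}.
#'
#' @inheritParams classify_promoter_island
#' @return data.frame `probe_id`, `gene`, `feature`, `promoter` (logical);
#'   probes without gene annotation contribute no rows.
#' @export
classify_gene_feature <- function(ann, probe_ids = NULL) {
  p <- sel_probes(ann, probe_ids)
  has <- nzchar(p$gene_symbols)
  genes <- strsplit(p$gene_symbols[has], ";", fixed = TRUE)
  feats <- strsplit(p$gene_features[has], ";", fixed = TRUE)
  ng <- lengths(genes)
  if (any(ng != lengths(feats)))
    stop("gene_symbols and gene_features disagree in length for probe(s): ",
         paste(p$probe_id[has][ng != lengths(feats)], collapse = ", "))
  out <- data.frame(
    probe_id = rep(p$probe_id[has], ng),
    gene = unlist(genes, use.names = FALSE),
    feature = unlist(feats, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  known <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
  bad <- setdiff(unique(out$feature), known)
  if (length(bad) > 0)
    stop("unknown gene-feature token(s): ", paste(bad, collapse = ", "))
  out$promoter <- out$feature %in% c("TSS1500", "TSS200", "5UTR", "1stExon")
  out
}

sel_probes <- function(ann, probe_ids) {
  stopifnot(inherits(ann, "probe_annotation"))
  p <- ann$probes
  if (is.null(probe_ids)) return(p)
  idx <- match(probe_ids, p$probe_id)
  if (anyNA(idx))
    stop("probe(s) absent from annotation: ",
         paste(probe_ids[is.na(idx)], collapse = ", "))
  p[idx, , drop = FALSE]
}
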