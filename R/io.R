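#' Read a beta-value matrix, optionally masking low-confidence calls
#'
#' Reads a TSV with probes as rows (first column = probe IDs) and samples as
#' columns. When a parallel detection-p table is supplied, entries with
#' detection p > `detection_max` are set missing: those calls are
#' indistinguishable from background and are excluded from every downstream
#' statistic through the shared missing-value mask.
#'
#' @param path path to the beta TSV (probes x samples, header = sample IDs,
#'   missing = empty cell or `NA`).
#' @param detection_path optional path to a detection-p TSV with identical
#'   layout.
#' @param detection_max detection-p ceiling above which a call is masked.
#' @return numeric matrix with probe IDs as rownames, sample IDs as
#'   colnames, `NA` for missing entries.
#' @export
read_beta_matrix <- function(path, detection_path = NULL,
                             detection_max = 0.01) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  probe_ids <- raw[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicated probe IDs: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                               dimnames = list(probe_ids, colnames(vals))))
  bad <- which(is.na(m) & !(vals == "" | toupper(vals) == "NA"),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric beta value at probe '%s', sample '%s'",
                 probe_ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  tol <- 1e-9
  out_of_range <- !is.na(m) & (m < -tol | m > 1 + tol)
  if (any(out_of_range)) {
    w <- which(out_of_range, arr.ind = TRUE)
    stop(sprintf("beta value outside [0,1] at probe '%s', sample '%s': %g",
                 probe_ids[w[1, 1]], colnames(m)[w[1, 2]], m[w[1, 1], w[1, 2]]))
  }
  m[!is.na(m)] <- pmin(pmax(m[!is.na(m)], 0), 1)
  if (!is.null(detection_path)) {
    det <- utils::read.delim(detection_path, check.names = FALSE)
    if (nrow(det) > 0) {
      dm <- as.matrix(det[, -1, drop = FALSE])
      rownames(dm) <- det[[1]]
      common_p <- intersect(rownames(m), rownames(dm))
      common_s <- intersect(colnames(m), colnames(dm))
      mask <- dm[common_p, common_s, drop = FALSE] > detection_max
      mask[is.na(mask)] <- FALSE
      sub <- m[common_p, common_s, drop = FALSE]
      sub[mask] <- NA_real_
      m[common_p, common_s] <- sub
    }
  }
  m
}

#' Write a beta-value matrix as TSV
#'
#' Inverse of [read_beta_matrix()]: probes as rows, header of sample IDs,
#' missing entries written as `NA`. Full precision is kept so a
#' write-then-read round trip reproduces the matrix.
#'
#' @param beta numeric matrix with dimnames.
#' @param path output path.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta),
                   format(beta, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a probe annotation
#'
#' The manifest TSV carries one row per probe with `;`-separated multi-gene
#' annotations and the nearest island as `chr:start-end` (empty when no
#' island exists); TSS positions travel in a second TSV (`gene`, `tss_pos`).
#'
#' @param ann a `"probe_annotation"` object (see [simulate_manifest()]).
#' @param path manifest TSV path.
#' @param tss_path TSS table TSV path.
#' @return `read_manifest()` returns a `"probe_annotation"` list.
#' @export
write_manifest <- function(ann, path, tss_path) {
  p <- ann$probes
  island <- ifelse(is.na(p$island_start), "",
                   sprintf("%s:%d-%d", p$chr, p$island_start, p$island_end))
  out <- data.frame(probe_id = p$probe_id, chr = p$chr, pos = p$pos,
                    strand = p$strand, gene_symbols = p$gene_symbols,
                    gene_features = p$gene_features, island = island,
                    snp_overlap = p$snp_overlap,
                    is_genotyping = p$is_genotyping,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$tss, tss_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, tss_path = NULL) {
  p <- utils::read.delim(path, check.names = FALSE,
                         colClasses = c(probe_id = "character",
                                        gene_symbols = "character",
                                        gene_features = "character"))
  p$gene_symbols[is.na(p$gene_symbols)] <- ""
  p$gene_features[is.na(p$gene_features)] <- ""
  isl <- strcapture("^[^:]+:([0-9]+)-([0-9]+)$", p$island,
                    data.frame(start = integer(), end = integer()))
  p$island_start <- isl$start
  p$island_end <- isl$end
  p$island <- NULL
  bad <- !is.na(p$island_start) & p$island_start > p$island_end
  if (any(bad)) stop("island_start > island_end for probe(s): ",
                     paste(p$probe_id[bad], collapse = ", "))
  tss <- if (!is.null(tss_path)) {
    utils::read.delim(tss_path, colClasses = c(gene = "character"))
  } else {
    data.frame(gene = character(0), tss_pos = integer(0))
  }
  islands <- unique(stats::na.omit(p[, c("island_start", "island_end")]))
  names(islands) <- c("start", "end")
  rownames(islands) <- NULL
  structure(list(probes = p, tss = tss, islands = islands),
            class = "probe_annotation")
}

#' Read / write a clinical sample sheet
#'
#' CSV with columns `sample_id`, `group` (`nevus`/`primary`/`metastasis`),
#' `survival_months`, `event`, `breslow_mm`, `ulceration` and optionally
#' `til`. Survival fields may be empty for samples without follow-up.
#'
#' @param path CSV path.
#' @return data.frame with validated columns.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "survival_months", "event",
           "breslow_mm", "ulceration")
  miss <- setdiff(req, names(s))
  if (length(miss) > 0)
    stop("sample sheet misses column(s): ", paste(miss, collapse = ", "))
  bad <- !s$group %in% c("nevus", "primary", "metastasis")
  if (any(bad))
    stop("unknown group label(s): ", paste(unique(s$group[bad]), collapse = ", "))
  if (any(s$survival_months < 0, na.rm = TRUE))
    stop("negative survival_months")
  s$event <- as.logical(s$event)
  s$ulceration <- as.logical(s$ulceration)
  s
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write differential-expression tables
#'
#' TSV with columns `gene`, `logFC` (log2; positive = higher expression in
#' the later stage of the contrast), `q` and `source`.
#'
#' @param path TSV path.
#' @return a list of data.frames, one per `source` value.
#' @export
read_de_tables <- function(path) {
  d <- utils::read.delim(path, colClasses = c(gene = "character",
                                              source = "character"))
  req <- c("gene", "logFC", "q", "source")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0)
    stop("DE table misses column(s): ", paste(miss, collapse = ", "))
  split(d, d$source)
}

#' @rdname read_de_tables
#' @param tables list of DE data.frames.
#' @export
write_de_tables <- function(tables, path) {
  utils::write.table(do.call(rbind, unname(tables)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}
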