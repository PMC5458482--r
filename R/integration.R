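#' Call differential expression per gene
#'
#' Applies the conventional two-fold / q significance gate to a
#' differential-expression table: `down` if `logFC <= -fc_min` and
#' `q < q_max`, `up` if `logFC >= fc_min` and `q < q_max`, otherwise `ns`.
#'
#' @param de data.frame with columns `gene`, `logFC` (log2), `q`.
#' @param fc_min minimum absolute log2 fold change (1 = two-fold).
#' @param q_max q-value ceiling.
#' @return named character vector (`down`/`up`/`ns`) keyed by gene.
#' @export
call_expression <- function(de, fc_min = 1, q_max = 0.05) {
  stopifnot(all(c("gene", "logFC", "q") %in% names(de)))
  if (any(!is.finite(de$logFC)))
    stop("non-finite logFC for gene(s): ",
         paste(de$gene[!is.finite(de$logFC)], collapse = ", "))
  call <- rep("ns", nrow(de))
  call[de$logFC <= -fc_min & de$q < q_max] <- "down"
  call[de$logFC >= fc_min & de$q < q_max] <- "up"
  stats::setNames(call, toupper(de$gene))
}

#' Integrate methylation direction with expression calls
#'
#' Joins differentially methylated genes with one or more differential-
#' expression tables (OR semantics over tables) and flags the
#' direction-concordant pairs expected under methylation-driven repression:
#' hypermethylated & downregulated, or hypomethylated & upregulated, in at
#' least one table. Gene symbols match exactly after upper-casing.
#'
#' @param dm_genes data.frame with columns `gene` and `direction`
#'   (`hyper`/`hypo`), one row per differentially methylated gene.
#' @param de_tables list of DE data.frames (`gene`, `logFC`, `q`), e.g.
#'   from [read_de_tables()] or [simulate_expression()].
#' @param fc_min,q_max thresholds passed to [call_expression()].
#' @return list of class `"me_integration"`:
#'   `records` — data.frame `gene`, `direction`, one call column per table,
#'   `testable`, `concordant_negative`; `summary` — list with `n_dm`,
#'   `n_testable`, `n_concordant`, `concordant_pct` (of testable),
#'   `n_hyper_down`, `n_hypo_up`, `hyper_down_pct`, `hypo_up_pct`
#'   (one-decimal shares of the concordant set).
#' @export
integrate_expression <- function(dm_genes, de_tables, fc_min = 1,
                                 q_max = 0.05) {
  stopifnot(is.data.frame(dm_genes),
            all(c("gene", "direction") %in% names(dm_genes)))
  genes <- toupper(dm_genes$gene)
  if (anyDuplicated(genes))
    stop("duplicated gene(s) in dm_genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  dir <- dm_genes$direction
  if (!all(dir %in% c("hyper", "hypo")))
    stop("direction must be 'hyper' or 'hypo'")

  if (length(de_tables) == 0 || is.data.frame(de_tables))
    de_tables <- if (is.data.frame(de_tables)) list(de_tables) else list()
  calls <- lapply(de_tables, function(de) {
    cl <- call_expression(de, fc_min = fc_min, q_max = q_max)
    out <- cl[genes]
    out[is.na(out)] <- "absent"
    unname(out)
  })
  if (length(calls) == 0)
    calls <- list()
  rec <- data.frame(gene = genes, direction = dir, stringsAsFactors = FALSE)
  for (i in seq_along(calls))
    rec[[paste0("call_", if (!is.null(names(de_tables)) &&
                             nzchar(names(de_tables)[i])) names(de_tables)[i]
                         else i)]] <- calls[[i]]
  call_mat <- if (length(calls) > 0) do.call(cbind, calls)
              else matrix("absent", nrow(rec), 0)
  rec$testable <- apply(call_mat != "absent", 1, any)
  conc_dir <- ifelse(dir == "hyper", "down", "up")
  rec$concordant_negative <- vapply(seq_len(nrow(rec)), function(i) {
    any(call_mat[i, ] == conc_dir[i])
  }, TRUE)

  n_conc <- sum(rec$concordant_negative)
  n_hd <- sum(rec$concordant_negative & rec$direction == "hyper")
  n_hu <- sum(rec$concordant_negative & rec$direction == "hypo")
  summary <- list(
    n_dm = nrow(rec),
    n_testable = sum(rec$testable),
    n_concordant = n_conc,
    concordant_pct = share_pct(n_conc, sum(rec$testable)),
    n_hyper_down = n_hd, n_hypo_up = n_hu,
    hyper_down_pct = share_pct(n_hd, n_conc),
    hypo_up_pct = share_pct(n_hu, n_conc)
  )
  structure(list(records = rec, summary = summary), class = "me_integration")
}

#' @export
print.me_integration <- function(x, ...) {
  s <- x$summary
  cat("Methylation-expression integration\n")
  cat(sprintf("  %d DM genes, %d testable in >=1 table\n",
              s$n_dm, s$n_testable))
  cat(sprintf("  concordant-negative: %d (%.1f%% of testable)\n",
              s$n_concordant, s$concordant_pct))
  cat(sprintf("  hyper & down: %d (%.1f%%); hypo & up: %d (%.1f%%)\n",
              s$n_hyper_down, s$hyper_down_pct, s$n_hypo_up, s$hypo_up_pct))
  invisible(x)
}

#' Hypergeometric gene-set overrepresentation
#'
#' For each gene set, the overlap with the query list is scored by the
#' hypergeometric upper tail `P(X >= k)` (drawing `|query|` genes from a
#' universe containing the set), with Benjamini-Hochberg adjustment across
#' sets. Set members outside the universe are dropped before testing
#' (counts logged in the result).
#'
#' @param query_genes character vector of query gene symbols.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of universe gene symbols; must contain
#'   the query.
#' @return data.frame sorted by q: `set`, `set_size`, `overlap`, `p`, `q`,
#'   `dropped` (set members outside the universe).
#' @export
geneset_overlap <- function(query_genes, gene_sets, universe) {
  query <- unique(toupper(query_genes))
  universe <- unique(toupper(universe))
  if (!all(query %in% universe))
    stop("query gene(s) outside the universe: ",
         paste(setdiff(query, universe), collapse = ", "))
  n_u <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set_all <- unique(toupper(gene_sets[[nm]]))
    set <- intersect(set_all, universe)
    k <- length(intersect(set, query))
    # P(X >= k), X ~ Hypergeom(|set| successes, n_u - |set|, |query| draws)
    p <- stats::phyper(k - 1, length(set), n_u - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k,
               p = min(p, 1), dropped = length(set_all) - length(set),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p, out$set), c("set", "set_size", "overlap",
                                             "p", "q", "dropped")]
  rownames(out) <- NULL
  out
}
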