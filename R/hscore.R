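#' IHC H-score from an intensity histogram
#'
#' The H-score summarises immunohistochemical staining of a sample by
#' weighting the percentage of cells at each staining intensity (0-3) by
#' the intensity: `H = 1*pct1 + 2*pct2 + 3*pct3`, giving a value in
#' [0, 300]. Percentages must be non-negative and sum to 100 (tolerance
#' 1e-6); the score depends only on the percentages, never on cell counts.
#'
#' @param staining data.frame with columns `sample_id`, `pct0`, `pct1`,
#'   `pct2`, `pct3` (percentages of cells per intensity level), e.g. from
#'   [read_staining()].
#' @return data.frame `sample_id`, `hscore`.
#' @export
#' @examples
#' compute_hscore(data.frame(sample_id = "s1", pct0 = 10, pct1 = 20,
#'                           pct2 = 30, pct3 = 40))  # 200
compute_hscore <- function(staining) {
  req <- c("sample_id", "pct0", "pct1", "pct2", "pct3")
  miss <- setdiff(req, names(staining))
  if (length(miss) > 0)
    stop("staining table misses column(s): ", paste(miss, collapse = ", "))
  pct <- as.matrix(staining[, c("pct0", "pct1", "pct2", "pct3")])
  if (any(pct < 0))
    stop("negative staining percentage for sample(s): ",
         paste(staining$sample_id[apply(pct < 0, 1, any)], collapse = ", "))
  tot <- rowSums(pct)
  bad <- abs(tot - 100) > 1e-6
  if (any(bad))
    stop("staining percentages do not sum to 100 for sample(s): ",
         paste(staining$sample_id[bad], collapse = ", "))
  data.frame(sample_id = staining$sample_id,
             hscore = as.numeric(pct %*% c(0, 1, 2, 3)),
             stringsAsFactors = FALSE)
}

#' Read / write staining summaries and H-score tables
#'
#' TSV with columns `sample_id`, `pct0`, `pct1`, `pct2`, `pct3`.
#'
#' @param path TSV path.
#' @return data.frame of staining percentages.
#' @export
read_staining <- function(path) {
  utils::read.delim(path, colClasses = c(sample_id = "character"))
}

#' @rdname read_staining
#' @param hscores data.frame from [compute_hscore()].
#' @export
write_hscores <- function(hscores, path) {
  utils::write.table(hscores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
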