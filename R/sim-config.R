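#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data generator. The
#' defaults mirror the discovery-cohort layout of the motivating study design:
#' 14 benign nevi, 33 primary melanomas and 28 metastases, a bimodal 450K-like
#' beta landscape, and planted effects large enough to straddle the DGMB
#' selection cutoff of 0.25.
#'
#' Planted probe classes:
#' * `dev_hyper` / `dev_hypo` — development changes: both tumor groups
#'   (primary and metastasis) are shifted by `+effect_delta` / `-effect_delta`
#'   relative to nevi.
#' * `prog_hyper` / `prog_hypo` — progression changes: only metastases are
#'   shifted relative to nevi and primaries.
#' * `prognostic` — probes shifted by `prognostic_delta` between the
#'   high-risk and low-risk halves of the primary tumors (sign alternating),
#'   tying methylation to survival via [simulate_survival()].
#'
#' @param seed integer seed; every generator draw derives from it.
#' @param n_nevus,n_primary,n_meta samples per progression group.
#' @param n_probes number of probes.
#' @param frac_dev_hyper,frac_dev_hypo,frac_prog_hyper,frac_prog_hypo
#'   fractions of probes planted per class; their sum must be <= 1 after
#'   leaving room for `n_prognostic`.
#' @param effect_delta target shift of the group mean (and hence, closely,
#'   the group median) beta for planted development/progression probes;
#'   in (0, 1).
#' @param prognostic_delta mean-beta shift between survival-risk groups for
#'   `prognostic` probes.
#' @param beta_precision concentration parameter of the Beta noise model
#'   (larger = tighter probes).
#' @param frac_missing fraction of matrix entries masked missing at random.
#' @param n_prognostic count of probes planted as survival-associated.
#' @param hazard_ratio multiplicative hazard for high-risk samples.
#' @param censor_frac target fraction of censored survival records.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_probes = 500)
#' cfg$n_nevus
sim_config <- function(seed = 1L,
                       n_nevus = 14L, n_primary = 33L, n_meta = 28L,
                       n_probes = 5000L,
                       frac_dev_hyper = 0.02, frac_dev_hypo = 0.02,
                       frac_prog_hyper = 0.01, frac_prog_hypo = 0.01,
                       effect_delta = 0.4,
                       prognostic_delta = 0.3,
                       beta_precision = 50,
                       frac_missing = 0.02,
                       n_prognostic = 100L,
                       hazard_ratio = 3,
                       censor_frac = 0.3) {
  cfg <- list(
    seed = as.integer(seed),
    n_nevus = as.integer(n_nevus), n_primary = as.integer(n_primary),
    n_meta = as.integer(n_meta), n_probes = as.integer(n_probes),
    frac_dev_hyper = frac_dev_hyper, frac_dev_hypo = frac_dev_hypo,
    frac_prog_hyper = frac_prog_hyper, frac_prog_hypo = frac_prog_hypo,
    effect_delta = effect_delta, prognostic_delta = prognostic_delta,
    beta_precision = beta_precision, frac_missing = frac_missing,
    n_prognostic = as.integer(n_prognostic),
    hazard_ratio = hazard_ratio, censor_frac = censor_frac
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_dev_hyper, cfg$frac_dev_hypo,
          cfg$frac_prog_hyper, cfg$frac_prog_hypo)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("planted-class fractions must lie in [0, 1]")
  if (sum(fr) > 1)
    stop("planted-class fractions sum to more than 1")
  if (!is.finite(cfg$effect_delta) || cfg$effect_delta <= 0 ||
      cfg$effect_delta >= 1)
    stop("effect_delta must lie in (0, 1)")
  if (cfg$prognostic_delta <= 0 || cfg$prognostic_delta >= 1)
    stop("prognostic_delta must lie in (0, 1)")
  if (any(c(cfg$n_nevus, cfg$n_primary, cfg$n_meta) < 1L))
    stop("each group needs at least one sample")
  if (cfg$n_probes < 1L) stop("n_probes must be >= 1")
  if (cfg$frac_missing < 0 || cfg$frac_missing > 1)
    stop("frac_missing must lie in [0, 1]")
  if (cfg$censor_frac < 0 || cfg$censor_frac >= 1)
    stop("censor_frac must lie in [0, 1)")
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  n_planted <- sum(round(fr * cfg$n_probes)) + cfg$n_prognostic
  if (n_planted > cfg$n_probes)
    stop("planted probes (including prognostic) exceed n_probes")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic methylome configuration\n")
  cat(sprintf("  samples: %d nevi / %d primary / %d metastasis\n",
              x$n_nevus, x$n_primary, x$n_meta))
  cat(sprintf("  probes : %d (dev %0.1f%%, prog %0.1f%%, prognostic %d)\n",
              x$n_probes,
              100 * (x$frac_dev_hyper + x$frac_dev_hypo),
              100 * (x$frac_prog_hyper + x$frac_prog_hypo),
              x$n_prognostic))
  cat(sprintf("  effect_delta %.2f, prognostic_delta %.2f, precision %.0f\n",
              x$effect_delta, x$prognostic_delta, x$beta_precision))
  cat(sprintf("  missing %.1f%%, hazard ratio %.2f, censoring %.0f%%, seed %d\n",
              100 * x$frac_missing, x$hazard_ratio, 100 * x$censor_frac,
              x$seed))
  invisible(x)
}
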