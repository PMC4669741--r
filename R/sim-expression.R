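#' Configuration for the expression simulator
#'
#' Describes a synthetic polysome-profiling experiment on the natural-log
#' expression scale. Each transcript t gets a baseline drawn uniformly from
#' `baseline_range`, main effects for condition and fraction drawn from
#' zero-mean normals, and (for a fraction `frac_interaction` of transcripts)
#' a true interaction effect of magnitude `delta_scale` with random sign:
#' negative delta = helicase-dependent, positive = independent. Observations
#' add replicate noise Normal(0, sigma_bio) and measurement noise
#' Normal(0, s_i) with s_i drawn uniformly from `meas_sd_range` and reported
#' exactly, mirroring how a quantifier's posterior SDs are consumed
#' downstream as known.
#'
#' @param n_transcripts number of transcripts.
#' @param frac_interaction fraction in \[0, 1\] with a true interaction.
#' @param delta_scale magnitude (natural-log units) of the true interaction.
#' @param baseline_range interval for baseline log expression.
#' @param cond_effect_sd,frac_effect_sd SDs of per-transcript condition and
#'   fraction main effects.
#' @param sigma_bio biological replicate noise SD (>= 0).
#' @param meas_sd_range interval for the per-observation posterior SD.
#' @param n_replicates biological replicates per cell (>= 2, default 4).
#' @param include_total also simulate 2 x `n_replicates` total-mRNA samples.
#' @param seed integer seed; per-transcript substreams are derived from it
#'   deterministically so output is byte-identical for a given seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 1000, frac_interaction = 0.1,
                       delta_scale = 1, baseline_range = c(2, 8),
                       cond_effect_sd = 0.5, frac_effect_sd = 0.5,
                       sigma_bio = 0.3, meas_sd_range = c(0.05, 0.3),
                       n_replicates = 4, include_total = FALSE, seed = 1) {
  if (n_transcripts < 1) stop_bad_arg("n_transcripts must be positive")
  if (frac_interaction < 0 || frac_interaction > 1)
    stop_bad_arg("frac_interaction must lie in [0, 1]")
  if (delta_scale <= 0) stop_bad_arg("delta_scale must be > 0")
  if (cond_effect_sd < 0 || frac_effect_sd < 0 || sigma_bio < 0)
    stop_bad_arg("effect SDs and sigma_bio must be >= 0")
  if (length(meas_sd_range) != 2 || any(meas_sd_range < 0) ||
      diff(meas_sd_range) < 0)
    stop_bad_arg("meas_sd_range must be a non-decreasing pair of >= 0 values")
  if (n_replicates < 2) stop_bad_arg("n_replicates must be >= 2")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 frac_interaction = frac_interaction,
                 delta_scale = delta_scale,
                 baseline_range = baseline_range,
                 cond_effect_sd = cond_effect_sd,
                 frac_effect_sd = frac_effect_sd,
                 sigma_bio = sigma_bio,
                 meas_sd_range = meas_sd_range,
                 n_replicates = as.integer(n_replicates),
                 include_total = isTRUE(include_total),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic substream seeds: draws under the master seed, so ordering
# and reseeding elsewhere cannot perturb per-transcript streams.
derive_substreams <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n + 2L)
}

#' Simulate a polysome-profiling posterior-summary matrix
#'
#' Generates observed posterior means and SDs for every transcript x sample
#' under the model described in [sim_config()], plus the ground-truth table
#' needed for recovery tests.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{expression}{long `data.frame`: `transcript_id`, `sample_id`,
#'       `mean_log_expr`, `sd_log_expr`.}
#'     \item{design}{the sample design used (see [standard_design()]).}
#'     \item{truth}{`data.frame`: `transcript_id`, `delta_true`,
#'       `class_true` in `{"dependent", "independent", "null"}`.}
#'   }
#' @examples
#' sim <- simulate_expression(sim_config(n_transcripts = 5, seed = 7))
#' head(sim$expression)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fr <- c("subpolysomal", "polysomal",
          if (config$include_total) "total")
  design <- standard_design(config$n_replicates, fr)
  n <- config$n_transcripts
  seeds <- derive_substreams(config$seed, n)

  # master stream decides which transcripts carry a true interaction
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds[n + 1L])
  n_int <- round(config$frac_interaction * n)
  hit <- sample.int(n, n_int)
  delta_true <- numeric(n)
  if (n_int > 0)
    delta_true[hit] <- config$delta_scale * sample(c(-1, 1), n_int,
                                                   replace = TRUE)
  ids <- sprintf("TX%05d", seq_len(n))

  kd <- design$condition == "knockdown"
  poly <- design$fraction == "polysomal"
  total <- design$fraction == "total"
  m <- nrow(design)

  per_tx <- function(t) {
    set.seed(seeds[t])
    baseline <- runif(1, config$baseline_range[1], config$baseline_range[2])
    cond_eff <- rnorm(1, 0, config$cond_effect_sd)
    poly_eff <- rnorm(1, 0, config$frac_effect_sd)
    total_eff <- rnorm(1, 0, config$frac_effect_sd)
    lp <- baseline + cond_eff * kd + poly_eff * poly + total_eff * total +
      delta_true[t] * (kd & poly)
    s <- runif(m, config$meas_sd_range[1], config$meas_sd_range[2])
    y <- lp + rnorm(m, 0, config$sigma_bio) + rnorm(m, 0, s)
    cbind(y, s)
  }
  obs <- lapply(seq_len(n), per_tx)
  expression <- data.frame(
    transcript_id = rep(ids, each = m),
    sample_id = rep(design$sample_id, n),
    mean_log_expr = unlist(lapply(obs, function(o) o[, 1])),
    sd_log_expr = unlist(lapply(obs, function(o) o[, 2])),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    transcript_id = ids, delta_true = delta_true,
    class_true = ifelse(delta_true < 0, "dependent",
                        ifelse(delta_true > 0, "independent", "null")),
    stringsAsFactors = FALSE)
  list(expression = expression, design = design, truth = truth)
}
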