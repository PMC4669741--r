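#' Construct a sample design table
#'
#' A sample design maps each sequenced sample to its experimental cell:
#' condition (`control` or `knockdown`), sucrose-gradient fraction (`total`,
#' `subpolysomal` or `polysomal`) and biological replicate index. It is the
#' sole source of design matrices for model comparison.
#'
#' @param condition character vector, each element `"control"` or
#'   `"knockdown"`.
#' @param fraction character vector, each element `"total"`,
#'   `"subpolysomal"` or `"polysomal"`.
#' @param replicate integer vector of replicate indices (1-based).
#' @param sample_id optional character vector of unique sample names;
#'   defaults to `<fraction>_<condition>_<replicate>`.
#' @return A `data.frame` with columns `sample_id`, `condition`, `fraction`,
#'   `replicate`.
#' @examples
#' d <- standard_design()
#' head(d)
#' @export
sample_design <- function(condition, fraction, replicate, sample_id = NULL) {
  condition <- as.character(condition)
  fraction <- as.character(fraction)
  if (!all(condition %in% c("control", "knockdown")))
    stop_bad_arg("condition must be 'control' or 'knockdown'")
  if (!all(fraction %in% c("total", "subpolysomal", "polysomal")))
    stop_bad_arg("fraction must be 'total', 'subpolysomal' or 'polysomal'")
  n <- length(condition)
  if (length(fraction) != n || length(replicate) != n)
    stop_bad_arg("condition, fraction and replicate must have equal length")
  if (is.null(sample_id))
    sample_id <- paste(fraction, condition, replicate, sep = "_")
  if (anyDuplicated(sample_id))
    stop_bad_arg("duplicate sample ids in design")
  data.frame(sample_id = as.character(sample_id), condition = condition,
             fraction = fraction, replicate = as.integer(replicate),
             stringsAsFactors = FALSE)
}

#' Canonical polysome-profiling design
#'
#' Builds the standard layout used throughout: for each requested fraction,
#' `n_replicates` knockdown samples followed by `n_replicates` control
#' samples, i.e. rows in consecutive replicate sets per (fraction,
#' condition) cell.
#'
#' @param n_replicates replicates per cell (default 4).
#' @param fractions fractions to include, default subpolysomal + polysomal
#'   (the difference-of-difference layout); add `"total"` for the
#'   unfractionated pool.
#' @return A sample design `data.frame` (see [sample_design()]).
#' @export
standard_design <- function(n_replicates = 4,
                            fractions = c("subpolysomal", "polysomal")) {
  cells <- expand.grid(replicate = seq_len(n_replicates),
                       condition = c("knockdown", "control"),
                       fraction = fractions,
                       stringsAsFactors = FALSE)
  sample_design(cells$condition, cells$fraction, cells$replicate)
}

check_balanced <- function(design, fractions) {
  sub <- design[design$fraction %in% fractions, , drop = FALSE]
  tab <- table(sub$condition, sub$fraction)
  if (!all(dim(tab) == c(2, length(fractions))) || any(tab == 0))
    stop_bad_arg("design must contain both conditions in each requested fraction")
  if (length(unique(as.vector(tab))) != 1L)
    stop_bad_arg("unbalanced design: unequal replicates per condition/fraction cell")
  sub
}

new_design_pair <- function(X0, X1, name, interaction_col = NA_integer_) {
  structure(list(X0 = X0, X1 = X1, name = name,
                 interaction_col = interaction_col),
            class = "design_pair")
}

#' Design matrices for differential expression within one fraction
#'
#' The simple model is intercept-only (no condition effect); the complex
#' model adds a knockdown indicator. Requires a balanced two-condition
#' design within a single fraction.
#'
#' @param design sample design restricted to one fraction (e.g. the 8
#'   total-mRNA samples of a 4+4 experiment).
#' @return A `design_pair`: `X0` (n x 1), `X1` (n x 2), `name = "DE"`.
#' @export
build_design_de <- function(design) {
  fr <- unique(design$fraction)
  if (length(fr) != 1L)
    stop_bad_arg("DE design requires samples from a single fraction, got: ",
                 paste(fr, collapse = ", "))
  sub <- check_balanced(design, fr)
  n <- nrow(sub)
  kd <- as.numeric(sub$condition == "knockdown")
  X0 <- matrix(1, n, 1, dimnames = list(sub$sample_id, "intercept"))
  X1 <- cbind(X0, condition_kd = kd)
  new_design_pair(X0, X1, "DE", interaction_col = 2L)
}

#' Design matrices for the difference-of-difference (interaction) comparison
#'
#' Tests whether the knockdown-vs-control log-fold change differs between
#' the polysomal and subpolysomal fractions. The simple model carries
#' intercept, condition and fraction main effects; the complex model adds an
#' interaction column that is 1 exactly for (knockdown, polysomal) samples,
#' so its coefficient is
#' (poly_KD - poly_ctrl) - (subpoly_KD - subpoly_ctrl).
#'
#' @param design sample design covering both conditions in both the
#'   subpolysomal and polysomal fractions (total samples are ignored).
#' @return A `design_pair`: `X0` (n x 3), `X1` (n x 4), `name = "DoD"`.
#' @export
build_design_dod <- function(design) {
  sub <- design[design$fraction %in% c("subpolysomal", "polysomal"), ,
                drop = FALSE]
  if (!all(c("subpolysomal", "polysomal") %in% sub$fraction))
    stop_bad_arg("DoD design requires both subpolysomal and polysomal samples")
  sub <- check_balanced(sub, c("subpolysomal", "polysomal"))
  kd <- as.numeric(sub$condition == "knockdown")
  poly <- as.numeric(sub$fraction == "polysomal")
  X0 <- cbind(intercept = rep(1, nrow(sub)), condition_kd = kd,
              fraction_poly = poly)
  rownames(X0) <- sub$sample_id
  X1 <- cbind(X0, interaction = kd * poly)
  new_design_pair(X0, X1, "DoD", interaction_col = 4L)
}
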