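test_that("fixed-sigma marginal likelihood matches the conjugate closed form", {
  set.seed(11)
  pr <- prior_spec()
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    p <- sample(1:3, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))[, 1:p, drop = FALSE]
    y <- rnorm(n, 3)
    s <- runif(n, 0.05, 0.5)
    sigma <- runif(1, 0.1, 1)
    got <- log_marginal_likelihood(y, s, X, pr, sigma_fixed = sigma)
    want <- oracle_lml_fixed_sigma(y, s, X,
                                   c(pr$tau_intercept,
                                     rep(pr$tau_coef, p - 1)), sigma)
    expect_equal(as.numeric(got), want, tolerance = 1e-9)
  }
})

test_that("quadrature marginal likelihood matches dense 2-D grid integration", {
  set.seed(12)
  pr <- prior_spec(tau_intercept = 1)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    x <- rnorm(n)
    y <- rnorm(n, 0, 1.2)
    s <- runif(n, 0.05, 0.5)
    got <- log_marginal_likelihood(y, s, matrix(x), pr)
    want <- oracle_lml_grid_1col(y, s, x, 1, pr$sigma_scale)
    expect_lt(abs(as.numeric(got) - want), 1e-3)
  }
})

test_that("constant data prefer the simpler model (Occam penalty)", {
  pair <- build_design_dod(standard_design())
  y <- rep(5, 16)
  s <- rep(0.01, 16)
  res <- compare_models(y, s, pair)
  expect_gt(res$logML0, res$logML1)
  expect_lt(res$post_prob, 0.1)
})

test_that("posterior-probability algebra follows p*BF/(p*BF + 1 - p)", {
  expect_equal(posterior_probability(log(1), 0.1), 0.1)
  expect_equal(posterior_probability(log(9), 0.1), 0.5)
  expect_equal(posterior_probability(Inf, 0.1), 1)
  expect_equal(posterior_probability(-Inf, 0.1), 0)
  # strictly increasing in BF, complementary probabilities sum to 1
  lbf <- seq(-5, 5, length.out = 41)
  p1 <- posterior_probability(lbf, 0.3)
  expect_true(all(diff(p1) > 0))
  expect_equal(p1 + posterior_probability(-lbf, 0.7), rep(1, 41))
})

test_that("Bayes factor is stable under a common shift with a vague intercept", {
  set.seed(13)
  pr <- prior_spec(tau_intercept = 1e3)
  pair <- build_design_dod(standard_design())
  y <- rnorm(16, 5)
  s <- runif(16, 0.05, 0.3)
  r1 <- compare_models(y, s, pair, pr)
  r2 <- compare_models(y + 5, s, pair, pr)
  expect_lt(abs(r1$logML0 - r2$logML0) / abs(r1$logML0), 0.01)
  expect_lt(abs(r1$logML1 - r2$logML1) / abs(r1$logML1), 0.01)
})

test_that("classification applies the threshold and the sign of the shift", {
  expect_equal(classify_transcript(0.25, -0.5), "dependent")
  expect_equal(classify_transcript(0.19, -0.5), "unclassified")
  expect_equal(classify_transcript(0.25, 0.5), "independent")
  expect_equal(classify_transcript(0.25, 0), "unclassified")  # tie rule
  expect_equal(classify_transcript(c(0.9, 0.9, 0.1), c(-1, 1, -1),
                                   threshold = 0.5),
               c("dependent", "independent", "unclassified"))
})

test_that("rank metric is posterior probability times sign of dependence", {
  expect_equal(rank_metric(0.8, -2), 0.8)
  expect_equal(rank_metric(0.8, 2), -0.8)
  expect_equal(rank_metric(0, 1), 0)
  expect_equal(rank_metric(0.3, 0), 0)
})

test_that("gene collapsing keeps the isoform with highest posterior probability", {
  res <- data.frame(transcript_id = c("t1", "t2", "t3", "t4", "t5"),
                    post_prob = c(0.3, 0.5, 0.5, 0.5, 0.9),
                    stringsAsFactors = FALSE)
  map <- data.frame(transcript_id = c("t1", "t2", "t3", "t4", "t5"),
                    gene_id = c("gA", "gA", "gB", "gB", "gC"),
                    stringsAsFactors = FALSE)
  out <- collapse_to_gene(res, map)
  expect_setequal(out$transcript_id, c("t2", "t3", "t5"))  # tie -> t3 < t4
  expect_equal(nrow(out), 3)
  # unmapped transcript kept under its own id, with a warning
  expect_warning(out2 <- collapse_to_gene(res, map[-5, ]), "without gene")
  expect_true("t5" %in% out2$gene_id)
})

test_that("marginal likelihood rejects malformed inputs", {
  pr <- prior_spec()
  expect_error(log_marginal_likelihood(1:4, rep(-0.1, 4),
                                       matrix(1, 4), pr), "negative")
  expect_error(log_marginal_likelihood(1:4, rep(0.1, 3),
                                       matrix(1, 4), pr), "equal length")
  expect_error(log_marginal_likelihood(1:4, rep(0.1, 4),
                                       matrix(1, 4, 2), pr), "singular")
  expect_error(prior_spec(prior_complex = 1), "prior_complex")
  expect_error(prior_spec(tau_coef = 0), "> 0")
})

test_that("few transcripts are flagged when no interaction is present", {
  # generative scales matched to the default prior: the complex model
  # should rarely exceed the liberal 0.2 threshold under the null
  sim <- simulate_expression(sim_config(
    n_transcripts = 150, frac_interaction = 0, cond_effect_sd = 1,
    frac_effect_sd = 1, sigma_bio = 0.5, seed = 77))
  res <- run_model_selection(sim$expression, sim$design)
  expect_lte(mean(res$post_prob >= 0.2), 0.2)
})
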