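fake_cc <- function(family, params) {
  structure(list(family = family, params = params, ks_p = 1,
                 loglik = 0, n = 1000L),
            class = "class_conditional")
}

demo_model <- function(prior_true = 0.549) {
  posterior_model(
    fake_cc("normal-inverse-gaussian",
            c(alpha = 2, beta = 0.5, mu = 0.6, delta = 1)),
    fake_cc("johnson-su", c(gamma = 0.2, delta = 1.3, xi = -0.1,
                            lambda = 0.5)),
    prior_true = prior_true
  )
}

test_that("priors are the fractions of true and false pairs", {
  expect_equal(estimate_priors(549, 451),
               c(prior_true = 0.549, prior_false = 0.451))
  expect_equal(estimate_priors(1, 0), c(prior_true = 1, prior_false = 0))
  for (k in c(1, 7, 120)) {
    expect_equal(unname(estimate_priors(k, k)), c(0.5, 0.5))
  }
  expect_error(estimate_priors(0, 0), "both counts")
})

test_that("posterior reduces to the prior under equal likelihoods", {
  m <- posterior_model(
    fake_cc("johnson-su", c(gamma = 0, delta = 1, xi = 0, lambda = 1)),
    fake_cc("johnson-su", c(gamma = 0, delta = 1, xi = 0, lambda = 1)),
    prior_true = 0.549
  )
  expect_equal(posterior_prob(m, c(-1, 0, 2)), rep(0.549, 3),
               tolerance = 1e-12)
})

test_that("posterior matches direct Bayes arithmetic", {
  m <- demo_model()
  withr::with_seed(51, {
    d <- runif(1000, -3, 3)
    ft <- dnig(d, 2, 0.5, 0.6, 1)
    ff <- djohnson_su(d, 0.2, 1.3, -0.1, 0.5)
    direct <- 0.549 * ft / (0.549 * ft + 0.451 * ff)
    expect_equal(posterior_prob(m, d), direct, tolerance = 1e-12)
  })
  # one-sided certainty: a zero false density forces posterior 1
  p <- posterior_prob(m, 1e6) # JSU tail underflows long before NIG here?
  expect_true(all(p >= 0 & p <= 1))
})

test_that("posterior is monotone in the likelihood ratio", {
  m <- demo_model()
  d <- seq(-2, 2, length.out = 200)
  lr <- dnig(d, 2, 0.5, 0.6, 1) / djohnson_su(d, 0.2, 1.3, -0.1, 0.5)
  p <- posterior_prob(m, d)
  expect_true(all(diff(p[order(lr)]) >= -1e-12))
})

test_that("log-odds penalty inverts cleanly", {
  expect_equal(log_odds_penalty(0.5), 0)
  expect_equal(log_odds_penalty(1 / (1 + exp(1))), 1, tolerance = 1e-12)
  expect_equal(log_odds_penalty(1 / (1 + exp(2))), 2, tolerance = 1e-12)
  expect_equal(log_odds_penalty(0.9), -log(9), tolerance = 1e-12)
  expect_warning(p0 <- log_odds_penalty(0), "clipped")
  expect_true(is.finite(p0) && p0 > 0)
  # positive exactly when p < 0.5
  p <- c(0.1, 0.49, 0.5, 0.51, 0.9)
  expect_equal(log_odds_penalty(p) > 0, p < 0.5)
})

test_that("loop penalties sum failing pairs and flag missing patterns", {
  fx <- shared_fixture()
  bench <- fx$bench
  s <- bench$structure[[1]]
  prof <- bench$profile[[1]]
  pen <- loop_penalties(s, prof, fx$patterns, fx$model)
  expect_true(all(pen$penalty[!is.na(pen$penalty)] >= 0))
  # penalty equals the sum of deltas over pairs with posterior < 0.5
  for (k in seq_len(nrow(pen))) {
    pr <- pen$pairs[[k]]
    ok <- !is.na(pr$posterior)
    expected <- sum(pr$delta[ok & pr$posterior < 0.5])
    if (pen$patterns_available[k]) {
      expect_equal(pen$penalty[k], expected)
      expect_true(all(pr$delta[ok & pr$posterior < 0.5] > 0))
    } else {
      expect_true(is.na(pen$penalty[k]))
    }
  }
  # a motif with no characteristic pattern is flagged, not scored
  s2 <- parse_dotbracket("...(((.........)))...", "AAAGGGAAAAAAAAACCCAAA")
  pen2 <- loop_penalties(s2, shape_profile(runif(22)), fx$patterns, fx$model)
  expect_false(pen2$patterns_available[1])
  expect_true(is.na(pen2$penalty[1]))
})

test_that("penalty is zero when every pattern pair clears the cutoff", {
  fx <- shared_fixture()
  # ideal tetraloop profile: apex high, flanks low, paired residues low
  s <- parse_dotbracket("..((((....))))..", "AAGGGGAAAACCCCAA")
  x <- rep(0.1, 16)
  x[7:10] <- c(0.1, 1.3, 0.5, 0.1) # planted-like reactivities
  pen <- loop_penalties(s, shape_profile(x), fx$patterns, fx$model)
  expect_equal(pen$penalty[1], 0)
})

test_that("model serialization reproduces posteriors exactly", {
  fx <- shared_fixture()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model(fx$model, tmp)
  m2 <- read_model(tmp)
  d <- seq(-2, 2, length.out = 101)
  expect_equal(posterior_prob(m2, d), posterior_prob(fx$model, d),
               tolerance = 1e-12)
  expect_equal(m2$prior_true, fx$model$prior_true)
})

test_that("tidy and glance summarise a posterior model", {
  fx <- shared_fixture()
  td <- tidy(fx$model)
  expect_setequal(unique(td$class), c("true", "false"))
  expect_equal(nrow(td), 8L) # 4 parameters per family
  gl <- glance(fx$model)
  expect_equal(gl$prior_true + gl$prior_false, 1)
})
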