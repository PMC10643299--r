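test_that("response scoring requires an onset inside the window", {
  expect_true(score_response(make_trial("retreat", 1.2), c(0, 5)))
  expect_false(score_response(make_trial(), c(0, 5)))
  expect_false(score_response(make_trial("walk", 7.0), c(0, 5)))
  expect_error(score_response(make_trial("stop", 1, pre_retreat = TRUE)),
               "apply_exclusions")
})

test_that("scoring is monotone in the window", {
  set.seed(41)
  for (i in 1:50) {
    tr <- make_trial(sample(c("stop", "retreat", "walk"), 3, replace = TRUE),
                     runif(3, -1, 8))
    w1 <- sort(runif(2, 0, 6))
    w2 <- c(w1[1] - runif(1, 0, 2), w1[2] + runif(1, 0, 2))
    if (score_response(tr, w1)) expect_true(score_response(tr, w2))
  }
})

test_that("exclusion removes exactly the pre-stimulus full retreats", {
  trials <- list(make_trial("stop", 1), make_trial("walk", 2),
                 make_trial("retreat", 0.5, pre_retreat = TRUE))
  suppressMessages({
    split1 <- apply_exclusions(trials)
    expect_length(split1$kept, 2)
    expect_length(split1$excluded, 1)
    expect_true(split1$excluded[[1]]$excluded)
    # idempotent
    split2 <- apply_exclusions(split1$kept)
    expect_length(split2$kept, 2)
    expect_length(split2$excluded, 0)
    # no flags: nothing excluded
    expect_length(apply_exclusions(trials[1:2])$excluded, 0)
  })

  df <- data.frame(crab_id = c("a", "b", "c"), pre_stim_retreat = c(FALSE, TRUE, FALSE))
  suppressMessages(spl <- apply_exclusions(df))
  expect_equal(spl$kept$crab_id, c("a", "c"))
})

test_that("sigmoid fit recovers noiseless parameters from its model class", {
  x <- seq(-0.4, 0.4, length.out = 9)
  p <- sigmoid_response(x, bottom = 0, top = 1, x50 = 0.2, slope = 10)
  fit <- fit_sigmoid(x, p, n = rep(20, 9))
  expect_equal(fit$x50, 0.2, tolerance = 1e-6)
  expect_equal(fit$slope, 10, tolerance = 1e-4)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
})

test_that("degenerate and underdetermined sigmoid inputs are flagged", {
  x <- seq(0, 0.5, length.out = 8)
  flat <- fit_sigmoid(x, rep(0.6, 8), n = rep(10, 8))
  expect_false(flat$x50_reliable)
  expect_error(fit_sigmoid(c(0, 0.1, 0.2), c(0, 0.5, 1), n = rep(5, 3)),
               "4 distinct")
})

test_that("sigmoid fit handles decreasing response curves", {
  x <- seq(-0.4, 0.4, length.out = 9)
  p <- sigmoid_response(x, bottom = 0.1, top = 0.9, x50 = -0.1, slope = -8)
  fit <- fit_sigmoid(x, p, n = rep(15, 9))
  expect_equal(fit$x50, -0.1, tolerance = 1e-5)
  expect_lt(fit$slope, 0)
})

test_that("habituation line fit recovers exact and constant responses", {
  # mean responses 1.0, 0.9, ..., 0.6 across orders 1..5
  order <- rep(1:5, each = 10)
  response <- unlist(lapply(c(10, 9, 8, 7, 6),
                            function(k) c(rep(1, k), rep(0, 10 - k))))
  fit <- fit_habituation(order, response)
  expect_equal(fit$h, -0.1, tolerance = 1e-12)

  allones <- fit_habituation(rep(1:4, each = 3), rep(1, 12))
  expect_equal(allones$h, 0)
  expect_equal(allones$intercept, 1)

  expect_error(fit_habituation(rep(1, 10), rbinom(10, 1, 0.5)), "2 distinct")
})

test_that("glmm with no group variance matches plain logistic regression", {
  trials <- simulate_logit_trials(beta0 = -0.5, beta_contrast = 3,
                                  crab_sd = 0, n_crabs = 30,
                                  contrast_set = seq(-0.5, 0.5, length.out = 9),
                                  seed = 42)
  mixed <- fit_glmm(trials, fixed = c("contrast", "order"), nagq = 20)
  plain <- glm(response ~ contrast + order, data = trials, family = binomial)
  expect_lt(max(abs(mixed$coefficients - coef(plain))), 1e-3)
  expect_lt(mixed$random_intercept_sd, 0.05)
})

test_that("glmm mean contrast coefficient is recovered across replicates", {
  set.seed(314)
  coefs <- replicate(200, {
    trials <- simulate_logit_trials(beta0 = -1, beta_contrast = 4,
                                    crab_sd = 0.5, n_crabs = 50,
                                    contrast_set = seq(-0.5, 0.5,
                                                       length.out = 9))
    fit_glmm(trials, fixed = c("contrast", "order"),
             nagq = 1)$coefficients["contrast"]
  })
  expect_equal(mean(coefs), 4, tolerance = 0.3 / 4)
})

test_that("single-group data falls back to plain logistic with a warning", {
  trials <- simulate_logit_trials(0, 2, 0, 1, seq(-0.5, 0.5, length.out = 9),
                                  seed = 8)
  expect_warning(fit <- fit_glmm(trials, fixed = "contrast"), "single group")
  expect_equal(fit$random_intercept_sd, 0)
  expect_equal(fit$n_groups, 1L)
})

test_that("likelihood-ratio test follows the chi-squared reference", {
  trials <- simulate_logit_trials(0, 3, 0.4, 12, seq(-0.5, 0.5, length.out = 9),
                                  seed = 5)
  full <- fit_glmm(trials, fixed = c("contrast", "order"), nagq = 1)
  expect_equal(lrt(full, full), list(chi2 = 0, df = 0, p = 1))

  fake <- function(ll, df, terms)
    structure(list(loglik = ll, df = df, n_obs = 100, terms = terms),
              class = "glmm_result")
  out <- lrt(fake(-50, 3, c("contrast", "order")), fake(-51.9205, 2, "order"))
  expect_equal(out$df, 1)
  expect_equal(out$p, 0.05, tolerance = 1e-3)   # chi2 = 3.841 at df = 1

  expect_error(lrt(fake(-50, 3, c("contrast", "order")),
                   fake(-51, 2, "species")), "not nested")
  bad_n <- fake(-51, 2, "order"); bad_n$n_obs <- 99
  expect_error(lrt(fake(-50, 3, c("contrast", "order")), bad_n),
               "different numbers")
})

test_that("polarity splits partition the trials and agree for symmetric curves", {
  model <- observer_model(bottom = 0.1, top = 0.9, x50_pos = 0.2,
                          x50_neg = 0.2, slope = 6, crab_sd = 0.3)
  trials <- simulate_trials(model, 40, seq(-0.5, 0.5, length.out = 9),
                            seed = 23)
  pos <- trials[trials$contrast >= 0, ]
  neg <- trials[trials$contrast <= 0, ]
  n_controls <- sum(trials$contrast == 0)
  expect_equal(nrow(pos) + nrow(neg) - n_controls, nrow(trials))

  ps <- polarity_split_fits(trials, nagq = 1)
  cp <- ps$positive$fit$coefficients["contrast"]
  cn <- ps$negative$fit$coefficients["contrast"]
  expect_gt(cp, 0)
  expect_lt(cn, 0)   # response rises as contrast moves away from control
  expect_equal(abs(cp), abs(cn), tolerance = 0.5)
  expect_lt(ps$positive$lrt$p, 0.001)
  expect_lt(ps$negative$lrt$p, 0.001)
})

test_that("a constant-response polarity subset is flagged non-identifiable", {
  trials <- data.frame(
    crab_id = rep(c("a", "b"), each = 6),
    contrast = rep(c(-0.4, -0.2, 0, 0, 0.2, 0.4), 2),
    order = rep(1:6, 2),
    response = rep(c(0, 0, 0, 0, 1, 1), 2))
  expect_warning(ps <- polarity_split_fits(trials, nagq = 1),
                 "constant response")
  expect_true(ps$negative$non_identifiable)
})

test_that("one-sided data yields a partial polarity split with a warning", {
  trials <- simulate_logit_trials(0, 2, 0.3, 10, seq(0, 0.5, length.out = 5),
                                  seed = 3)
  expect_warning(ps <- polarity_split_fits(trials, nagq = 1), "no negative")
  expect_null(ps$negative)
  expect_false(is.null(ps$positive))
})
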