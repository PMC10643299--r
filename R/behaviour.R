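# Behavioural analysis of looming-stimulus trials: response scoring and
# exclusions, sigmoid contrast-response curves with half-maximum thresholds,
# habituation line fits, and mixed-effects binary logistic regression
# compared by likelihood-ratio test.

BEHAVIOUR_KINDS <- c("stop", "retreat", "walk")

#' Construct a single trial record
#'
#' One stimulus presentation to one animal. A trial can carry any number of
#' scored behaviours (`stop`: the animal became stationary; `retreat`: it
#' withdrew partially or fully into its shell; `walk`: it started walking),
#' each with an onset time relative to loom onset. Trials in which the
#' animal performed a full retreat before stimulus onset are flagged for
#' exclusion.
#'
#' @param crab_id Animal identifier.
#' @param species Species code (e.g. `"C_rugosus"`, `"C_brevimanus"`,
#'   `"P_bernhardus"`).
#' @param modality `"intensity"` or `"polarization"`.
#' @param contrast Signed stimulus contrast.
#' @param order Presentation index within the series (>= 1).
#' @param behaviours Data frame with columns `kind` (stop/retreat/walk) and
#'   `onset_s` (seconds from loom onset); zero rows for no behaviour.
#' @param pre_stimulus_full_retreat Flag: full retreat before stimulus onset.
#' @return Object of class `trial_record`.
#' @export
trial_record <- function(crab_id, species, modality, contrast, order,
                         behaviours = data.frame(kind = character(),
                                                 onset_s = numeric()),
                         pre_stimulus_full_retreat = FALSE) {
  if (order < 1) stop("presentation order must be >= 1", call. = FALSE)
  if (nrow(behaviours)) {
    if (!all(behaviours$kind %in% BEHAVIOUR_KINDS))
      stop("behaviour kinds must be stop/retreat/walk", call. = FALSE)
    if (!all(is.finite(behaviours$onset_s)))
      stop("behaviour onsets must be finite", call. = FALSE)
  }
  structure(list(crab_id = as.character(crab_id), species = species,
                 modality = modality, contrast = contrast,
                 order = as.integer(order), behaviours = behaviours,
                 pre_stimulus_full_retreat = isTRUE(pre_stimulus_full_retreat),
                 excluded = isTRUE(pre_stimulus_full_retreat)),
            class = "trial_record")
}

#' Did the animal respond to the stimulus?
#'
#' An animal is scored as responding if any scored behaviour (stop, retreat
#' or walk) has its onset inside the scoring window, which defaults to the
#' whole stimulus: loom onset through the end of the hold period (0-5 s for
#' the terrestrial 3 s + 2 s loom; use 0-12 s for the marine 10 s + 2 s one).
#'
#' @param trial A [trial_record()]. Excluded trials are an error: run
#'   [apply_exclusions()] first and analyse the kept set.
#' @param window Length-2 numeric, scoring window in seconds.
#' @return Logical.
#' @export
score_response <- function(trial, window = c(0, 5)) {
  stopifnot(inherits(trial, "trial_record"))
  if (trial$excluded)
    stop("trial is excluded; apply_exclusions() first and score the kept set",
         call. = FALSE)
  b <- trial$behaviours
  nrow(b) > 0 && any(b$onset_s >= window[1] & b$onset_s <= window[2])
}

#' Partition trials into kept and excluded sets
#'
#' The single exclusion rule: a trial is dropped when the animal performed
#' a full retreat before the onset of the visual stimulus. Idempotent.
#'
#' @param trials List of [trial_record()] objects, or a data frame with a
#'   logical/0-1 `pre_stim_retreat` column.
#' @return List with elements `kept` and `excluded` of the same type as the
#'   input.
#' @export
apply_exclusions <- function(trials) {
  if (is.data.frame(trials)) {
    flag <- as.logical(trials$pre_stim_retreat)
    out <- list(kept = trials[!flag, , drop = FALSE],
                excluded = trials[flag, , drop = FALSE])
    counts <- c(nrow(out$kept), nrow(out$excluded))
  } else {
    flag <- vapply(trials, function(tr) tr$pre_stimulus_full_retreat, logical(1))
    excl <- lapply(trials[flag], function(tr) { tr$excluded <- TRUE; tr })
    out <- list(kept = trials[!flag], excluded = excl)
    counts <- c(length(out$kept), length(out$excluded))
  }
  message(sprintf("apply_exclusions: kept %d, excluded %d trials",
                  counts[1], counts[2]))
  out
}

#' Four-parameter logistic psychometric function
#'
#' `p(x) = bottom + (top - bottom) / (1 + 10^((x50 - x) * slope))`, the
#' base-10 sigmoid conventional in psychometric curve fitting; `x50` is the
#' half-maximum point (the detection threshold) and `slope` has units of
#' 1/contrast.
#'
#' @param x Stimulus contrast(s).
#' @param bottom,top Lower and upper response-probability asymptotes.
#' @param x50 Contrast at half-maximum response.
#' @param slope Steepness (1/contrast); negative for decreasing curves.
#' @return Response probability.
#' @export
sigmoid_response <- function(x, bottom, top, x50, slope) {
  bottom + (top - bottom) / (1 + 10^((x50 - x) * slope))
}

#' Fit a sigmoid contrast-response curve
#'
#' Least-squares fit of the 4-parameter logistic [sigmoid_response()] to
#' per-contrast response proportions, weighted by the number of trials at
#' each contrast (the binomial information weight). Binary per-trial input
#' is aggregated to proportions first. The asymptotes are box-constrained to
#' `[0, 1]` and the half-maximum to the fitted contrast range. At least four
#' distinct contrast levels are required (four free parameters).
#'
#' `converged` reflects optimizer success; `on_boundary` marks estimates
#' pinned at a box constraint, and `x50_reliable` is `FALSE` for degenerate
#' fits (flat curve or threshold at the edge of the tested range) whose
#' half-maximum should not be interpreted.
#'
#' @param contrast Stimulus contrasts, one per observation (or one per
#'   proportion when `n` is given).
#' @param response Binary responses (0/1), or response proportions when `n`
#'   is supplied.
#' @param n Number of trials behind each proportion (implies `response` are
#'   proportions).
#' @param weighted Weight proportions by trial count (default) or fit
#'   unweighted.
#' @param start Optional named list (`bottom`, `top`, `x50`, `slope`) of
#'   starting values; skips the default multi-start search (used e.g. for
#'   bootstrap refits seeded at the point estimate).
#' @return Object of class `psychometric_fit` with fields `bottom`, `top`,
#'   `x50`, `slope`, `converged`, `on_boundary`, `x50_reliable`, `data`.
#' @export
fit_sigmoid <- function(contrast, response, n = NULL, weighted = TRUE,
                        start = NULL) {
  if (is.null(n)) {
    agg <- stats::aggregate(response ~ contrast,
                            data = data.frame(contrast, response),
                            FUN = function(z) c(p = mean(z), n = length(z)))
    x <- agg$contrast; p <- agg$response[, "p"]; n <- agg$response[, "n"]
  } else {
    x <- contrast; p <- response
  }
  if (length(unique(x)) < 4)
    stop("sigmoid fit needs >= 4 distinct contrast levels", call. = FALSE)
  o <- order(x); x <- x[o]; p <- p[o]; n <- n[o]
  w <- if (weighted) n else rep(1, length(n))
  rng <- range(x); span <- diff(rng)

  if (is.null(start)) {
    up <- all(p == p[1]) || isTRUE(suppressWarnings(stats::cor(x, p)) >= 0)
    starts <- list()
    for (s0 in c(2 / span, 8 / span) * if (up) 1 else -1)
      for (m0 in stats::quantile(x, c(0.35, 0.5, 0.65), names = FALSE))
        starts[[length(starts) + 1L]] <-
          list(bottom = max(min(p), 1e-3), top = min(max(p), 1 - 1e-3),
               x50 = m0, slope = s0)
  } else {
    start$x50 <- min(max(start$x50, rng[1]), rng[2])
    start$bottom <- min(max(start$bottom, 0), 1)
    start$top <- min(max(start$top, 0), 1)
    starts <- list(start)
  }
  fits <- list()
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        p ~ sigmoid_response(x, bottom, top, x50, slope),
        start = s,
        lower = c(0, 0, rng[1], -500), upper = c(1, 1, rng[2], 500),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) {
    return(structure(list(bottom = NA_real_, top = NA_real_, x50 = NA_real_,
                          slope = NA_real_, converged = FALSE,
                          on_boundary = FALSE, x50_reliable = FALSE,
                          data = data.frame(contrast = x, p = p, n = n)),
                     class = "psychometric_fit"))
  }
  best <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  cf <- stats::coef(best)
  tol <- 1e-7
  on_boundary <- cf["bottom"] <= tol || cf["top"] >= 1 - tol ||
    cf["x50"] <= rng[1] + tol || cf["x50"] >= rng[2] - tol ||
    abs(cf["slope"]) >= 500 - tol
  # bottom <= top cannot be a box constraint; repair a crossed fit
  if (cf["bottom"] > cf["top"]) {
    cf[c("bottom", "top")] <- cf[c("top", "bottom")]
    cf["slope"] <- -cf["slope"]
  }
  converged <- isTRUE(best$convInfo$isConv) || is.null(best$convInfo)
  reliable <- converged &&
    (cf["top"] - cf["bottom"]) > 1e-3 && abs(cf["slope"]) > 1e-3 &&
    cf["x50"] > rng[1] + tol && cf["x50"] < rng[2] - tol
  structure(list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                 x50 = unname(cf["x50"]), slope = unname(cf["slope"]),
                 converged = converged, on_boundary = on_boundary,
                 x50_reliable = reliable,
                 data = data.frame(contrast = x, p = p, n = n)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "psychometric_fit: bottom %.3f, top %.3f, x50 %.4f, slope %.2f%s\n",
    x$bottom, x$top, x$x50, x$slope,
    if (!x$x50_reliable) "  [x50 unreliable]" else ""))
  invisible(x)
}

#' Bootstrap confidence interval for the half-maximum threshold
#'
#' Percentile bootstrap interval for `x50`. Two resampling schemes:
#'
#' * `"parametric"` (default): responses at each contrast level are
#'   redrawn from a binomial distribution at the fitted curve's
#'   probabilities — the model-based bootstrap, well calibrated for
#'   binomial proportion data at modest sample sizes.
#' * `"nonparametric"`: animals (rows) are resampled with replacement —
#'   making no model assumption and robust to between-animal
#'   heterogeneity, at the cost of mild undercoverage at small animal
#'   counts.
#'
#' @param responses Matrix of 0/1 responses, animals in rows, contrast
#'   levels in columns.
#' @param contrasts Contrast level of each column.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param type Resampling scheme, see above.
#' @param seed Optional integer seed.
#' @return List with `x50` (point estimate), `lower`, `upper`,
#'   `n_boot_used` (resamples with a successful fit).
#' @export
sigmoid_boot_ci <- function(responses, contrasts, n_boot = 199, conf = 0.95,
                            type = c("parametric", "nonparametric"),
                            seed = NULL) {
  stopifnot(is.matrix(responses), ncol(responses) == length(contrasts))
  type <- match.arg(type)
  nc <- nrow(responses)
  nlev <- rep(nc, length(contrasts))
  point <- fit_sigmoid(contrasts, colMeans(responses), n = nlev)
  boot_start <- if (point$converged && is.finite(point$x50))
    list(bottom = point$bottom, top = point$top, x50 = point$x50,
         slope = point$slope)
  phat <- pmin(pmax(sigmoid_response(contrasts, point$bottom, point$top,
                                     point$x50, point$slope), 0), 1)
  local_seed(seed, {
    bs <- vapply(seq_len(n_boot), function(b) {
      pb <- if (type == "parametric") {
        stats::rbinom(length(contrasts), nc, phat) / nc
      } else {
        colMeans(responses[sample.int(nc, nc, replace = TRUE), , drop = FALSE])
      }
      f <- tryCatch(fit_sigmoid(contrasts, pb, n = nlev, start = boot_start),
                    error = function(e) NULL)
      if (is.null(f) || !is.finite(f$x50)) NA_real_ else f$x50
    }, numeric(1))
    bs <- bs[is.finite(bs)]
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE)
    list(x50 = point$x50, lower = qs[1], upper = qs[2], n_boot_used = length(bs))
  })
}

#' Fit a habituation line
#'
#' Ordinary least squares of mean response probability against presentation
#' order, pooled across stimuli at each order. The slope `h` is the
#' habituation rate: the change in response probability per trial.
#'
#' @param order Presentation indices, one per trial.
#' @param response Binary responses (0/1).
#' @return Object of class `habituation_fit` with fields `h`, `intercept`,
#'   `by_order` (per-order means) and `fit` (the `lm`).
#' @export
fit_habituation <- function(order, response) {
  if (length(unique(order)) < 2)
    stop("habituation fit needs >= 2 distinct order values", call. = FALSE)
  by_order <- stats::aggregate(response ~ order,
                               data = data.frame(order, response), FUN = mean)
  fit <- stats::lm(response ~ order, data = by_order)
  cf <- stats::coef(fit)
  structure(list(h = unname(cf["order"]), intercept = unname(cf["(Intercept)"]),
                 by_order = by_order, fit = fit),
            class = "habituation_fit")
}

#' @export
print.habituation_fit <- function(x, ...) {
  cat(sprintf("habituation_fit: h = %+.4f per trial, intercept %.3f\n",
              x$h, x$intercept))
  invisible(x)
}

#' Mixed-effects binary logistic regression
#'
#' Fits `response ~ fixed effects + (1 | group)` with a binomial link via
#' maximum likelihood, integrating over the Gaussian random intercept with
#' adaptive Gauss-Hermite quadrature (`nagq` nodes; `nagq = 1` is the
#' Laplace approximation). The random intercept per animal accounts for the
#' repeated-measures design. With a single group the random effect is not
#' identifiable and a plain logistic regression is fitted with a warning.
#'
#' When `quadratic = TRUE` a squared centred-contrast term is added
#' (used where residual diagnostics show curvature in contrast).
#'
#' @param trials Data frame with the response, fixed-effect and group
#'   columns.
#' @param fixed Character vector of fixed-effect column names (possibly
#'   empty for an intercept-only model).
#' @param quadratic Add `I(centred contrast^2)`? Requires `"contrast"` among
#'   the columns.
#' @param group Grouping column name (animal ID).
#' @param response Response column name (0/1).
#' @param nagq Number of adaptive Gauss-Hermite nodes (1 = Laplace).
#' @return Object of class `glmm_result`: `coefficients` (logit scale),
#'   `random_intercept_sd`, `loglik`, `df`, `n_obs`, `n_groups`,
#'   `converged`, `terms`, `model`.
#' @export
fit_glmm <- function(trials, fixed = c("contrast", "order"),
                     quadratic = FALSE, group = "crab_id",
                     response = "response", nagq = 20) {
  stopifnot(is.data.frame(trials), response %in% names(trials),
            group %in% names(trials), all(fixed %in% names(trials)))
  dat <- trials
  terms <- fixed
  if (quadratic) {
    dat$contrast_sq <- (dat$contrast - mean(dat$contrast))^2
    terms <- c(terms, "contrast_sq")
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  n_groups <- length(unique(dat[[group]]))
  msgs <- character()
  if (n_groups < 2) {
    warning("single group: random intercept not identifiable, fitting plain logistic regression")
    fml <- stats::as.formula(paste(response, "~", rhs))
    m <- stats::glm(fml, data = dat, family = stats::binomial())
    ll <- stats::logLik(m)
    return(structure(list(coefficients = stats::coef(m),
                          random_intercept_sd = 0,
                          loglik = as.numeric(ll), df = attr(ll, "df"),
                          n_obs = nrow(dat), n_groups = n_groups,
                          converged = m$converged, terms = terms, model = m),
                     class = "glmm_result"))
  }
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", group, ")"))
  m <- withCallingHandlers(
    lme4::glmer(fml, data = dat, family = stats::binomial(), nAGQ = nagq),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  conv_msgs <- c(msgs, unlist(m@optinfo$conv$lme4$messages))
  # a singular fit (random-intercept SD estimated at 0) is a valid boundary
  # estimate, not a convergence failure
  conv_msgs <- conv_msgs[!grepl("singular", conv_msgs, ignore.case = TRUE)]
  ll <- stats::logLik(m)
  structure(list(coefficients = lme4::fixef(m),
                 random_intercept_sd =
                   sqrt(as.numeric(lme4::VarCorr(m)[[group]])),
                 loglik = as.numeric(ll), df = attr(ll, "df"),
                 n_obs = nrow(dat), n_groups = n_groups,
                 converged = length(conv_msgs) == 0,
                 messages = conv_msgs, terms = terms, model = m),
            class = "glmm_result")
}

#' @export
print.glmm_result <- function(x, ...) {
  cat(sprintf(
    "glmm_result: %d obs, %d groups, logLik %.3f, random-intercept SD %.3f%s\n",
    x$n_obs, x$n_groups, x$loglik, x$random_intercept_sd,
    if (!x$converged) "  [convergence flagged]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Brute-force marginal log-likelihood of a random-intercept logistic model
#'
#' Recomputes the marginal log-likelihood of a fitted [fit_glmm()] model by
#' direct one-dimensional numerical integration (`stats::integrate`) of the
#' random intercept out of each group's conditional likelihood, at the
#' fitted coefficients and random-intercept SD. This is an independent
#' check on the quadrature approximation used by the fitting engine.
#'
#' @param fit A `glmm_result` from a true mixed fit (>= 2 groups).
#' @return Marginal log-likelihood (numeric scalar).
#' @export
glmm_loglik_bruteforce <- function(fit) {
  stopifnot(inherits(fit, "glmm_result"))
  m <- fit$model
  if (!methods::is(m, "glmerMod"))
    stop("brute-force likelihood needs a mixed fit", call. = FALSE)
  X <- lme4::getME(m, "X")
  y <- m@resp$y
  g <- m@flist[[1]]
  eta0 <- as.numeric(X %*% fit$coefficients)
  sd_b <- fit$random_intercept_sd
  total <- 0
  for (lev in levels(g)) {
    sel <- g == lev
    eta_g <- eta0[sel]; y_g <- y[sel]
    grp_loglik_at <- function(b)
      sum(stats::dbinom(y_g, 1, stats::plogis(eta_g + b), log = TRUE))
    if (sd_b < 1e-10) { total <- total + grp_loglik_at(0); next }
    # scale by the peak so the integrand is O(1)
    peak <- stats::optimize(function(b) -grp_loglik_at(b) +
                              -stats::dnorm(b, 0, sd_b, log = TRUE),
                            interval = c(-10 * sd_b, 10 * sd_b))$minimum
    log_peak <- grp_loglik_at(peak) + stats::dnorm(peak, 0, sd_b, log = TRUE)
    integrand <- function(b) vapply(b, function(bb)
      exp(grp_loglik_at(bb) + stats::dnorm(bb, 0, sd_b, log = TRUE) - log_peak),
      numeric(1))
    val <- stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-10)$value
    total <- total + log(val) + log_peak
  }
  total
}

#' Likelihood-ratio test between nested mixed models
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)`, with degrees of freedom equal
#' to the difference in parameter count, referred to the upper tail of the
#' chi-squared distribution.
#'
#' @param full,reduced `glmm_result` objects fitted to the same data, the
#'   reduced model's fixed effects a subset of the full model's.
#' @return List with `chi2`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "glmm_result"), inherits(reduced, "glmm_result"))
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted to different numbers of observations", call. = FALSE)
  if (!all(reduced$terms %in% full$terms))
    stop("reduced model is not nested in the full model", call. = FALSE)
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < -1e-6)
    stop(sprintf("negative LRT statistic (%.3g): full model did not converge to at least the reduced model's likelihood", chi2),
         call. = FALSE)
  chi2 <- max(chi2, 0)
  df <- full$df - reduced$df
  p <- if (df == 0) {
    if (chi2 < 1e-8) 1 else stop("identical parameter counts but different likelihoods", call. = FALSE)
  } else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Polarity-split contrast models
#'
#' Fits the contrast GLMM and its likelihood-ratio test separately on the
#' positive-contrast and negative-contrast subsets, with the zero-contrast
#' control trials included in both so each split has an anchor. Used when a
#' response curve is symmetric about the control and a pooled signed-contrast
#' model would cancel the two arms.
#'
#' @param trials Per-trial data frame (`response`, `contrast`, `order`,
#'   group column).
#' @param group Grouping column name.
#' @param nagq Quadrature nodes for [fit_glmm()].
#' @return List with elements `positive` and `negative`; each is either
#'   `list(fit, reduced, lrt)` or `list(non_identifiable = TRUE)` when the
#'   subset's response is constant, or `NULL` (with a warning) when that
#'   polarity is absent.
#' @export
polarity_split_fits <- function(trials, group = "crab_id", nagq = 20) {
  split_one <- function(sub, label) {
    if (!any(sub$contrast != 0)) {
      warning(sprintf("no %s-contrast trials; returning partial result", label))
      return(NULL)
    }
    if (length(unique(sub$response)) < 2) {
      warning(sprintf("%s subset has constant response; model not identifiable", label))
      return(list(non_identifiable = TRUE))
    }
    full <- fit_glmm(sub, fixed = c("contrast", "order"), group = group, nagq = nagq)
    reduced <- fit_glmm(sub, fixed = "order", group = group, nagq = nagq)
    list(fit = full, reduced = reduced, lrt = lrt(full, reduced))
  }
  list(positive = split_one(trials[trials$contrast >= 0, , drop = FALSE], "positive"),
       negative = split_one(trials[trials$contrast <= 0, , drop = FALSE], "negative"))
}
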