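# Simulation studies validating each pipeline stage against its ground
# truth: closed-loop polarimetry recovery, psychometric parameter recovery
# with bootstrap coverage, LRT type-I calibration and power, habituation
# slope recovery, and a brute-force check on the GLMM marginal likelihood.
# Defaults are the package's reference study conditions; the same functions
# back both the test suite and scripts/acceptance.R.

#' Closed-loop polarimetry recovery study
#'
#' Draws random uniform-field Stokes scenes, renders each through the
#' noiseless Malus-law forward model to a quantized 12-bit mosaic, runs the
#' full inverse pipeline (demosaic, Stokes, DoP/AoP), and measures the
#' worst-case recovery error over all valid pixels. Scenes use bright but
#' unsaturated exposure (the regime in which integer rounding keeps DoP
#' errors below 2 counts-equivalent) and a DoP floor of 0.05 so the angle
#' of polarization is defined everywhere.
#'
#' @param n_scenes Number of random scenes.
#' @param grid Scene size in superpixels.
#' @param s0_range,dop_range Uniform sampling ranges for intensity (counts)
#'   and DoP.
#' @param bit_depth Sensor bit depth.
#' @param seed Integer seed.
#' @return List: `max_dop_err`, `max_aop_err_deg`, `n_pixels`.
#' @export
study_polarimetry_roundtrip <- function(n_scenes = 100, grid = c(8, 8),
                                        s0_range = c(3600, 4080),
                                        dop_range = c(0.05, 1),
                                        bit_depth = 12L, seed = 1) {
  local_seed(seed, {
    max_dop <- 0; max_aop <- 0; n_px <- 0L
    for (i in seq_len(n_scenes)) {
      npx <- prod(grid)
      scene <- stokes_scene(
        s0 = matrix(stats::runif(npx, s0_range[1], s0_range[2]), grid[1]),
        dop = matrix(stats::runif(npx, dop_range[1], dop_range[2]), grid[1]),
        aop = matrix(stats::runif(npx, -90, 90), grid[1]))
      mosaic <- render_mosaic(scene, bit_depth = bit_depth, noise_sd = 0)
      maps <- dop_aop(compute_stokes(
        demosaic(mosaic)$I0, demosaic(mosaic)$I45,
        demosaic(mosaic)$I90, demosaic(mosaic)$I135), mosaic)
      valid <- maps$mask == "valid"
      max_dop <- max(max_dop, abs(maps$dop[valid] - scene$dop[valid]))
      aop_err <- abs(wrap_aop(maps$aop[valid] - scene$aop[valid] + 90) - 90)
      aop_err <- pmin(aop_err, 180 - aop_err)
      max_aop <- max(max_aop, aop_err)
      n_px <- n_px + sum(valid)
    }
    list(max_dop_err = max_dop, max_aop_err_deg = max_aop, n_pixels = n_px)
  })
}

#' Psychometric threshold recovery and bootstrap coverage study
#'
#' Simulates replicate experiments from a known psychometric observer
#' (binomial responses, no animal heterogeneity, so the binomial model
#' behind the parametric bootstrap is exactly the generating model),
#' refits the sigmoid to each, and reports the recovered half-maximum
#' distribution and the empirical coverage of the percentile bootstrap
#' confidence interval.
#'
#' @param n_sims Number of replicate experiments.
#' @param n_crabs Animals per experiment.
#' @param contrast_set Contrast levels (one trial per level per animal).
#' @param truth [observer_model()] generating the data.
#' @param n_boot Bootstrap resamples per experiment (0 skips coverage).
#' @param conf Bootstrap confidence level.
#' @param type Bootstrap scheme passed to [sigmoid_boot_ci()].
#' @param seed Integer seed.
#' @return List: `x50_estimates`, `median_x50`, `coverage` (NA when
#'   `n_boot = 0`), `n_sims`.
#' @export
study_psychometric_recovery <- function(n_sims = 500, n_crabs = 20,
                                        contrast_set = seq(0.05, 0.45,
                                                           length.out = 9),
                                        truth = observer_model(
                                          bottom = 0, top = 1, x50_pos = 0.2,
                                          x50_neg = 0.2, slope = 8,
                                          crab_sd = 0),
                                        n_boot = 199, conf = 0.95,
                                        type = "parametric", seed = 1) {
  local_seed(seed, {
    est <- numeric(n_sims); covered <- logical(n_sims)
    for (i in seq_len(n_sims)) {
      trials <- simulate_trials(truth, n_crabs, contrast_set, seed = NULL)
      resp <- matrix(NA_integer_, n_crabs, length(contrast_set))
      ord <- order(contrast_set)
      for (j in seq_along(contrast_set)) {
        sel <- trials$contrast == contrast_set[ord[j]]
        resp[, j] <- trials$response[sel][order(trials$crab_id[sel])]
      }
      if (n_boot > 0) {
        ci <- sigmoid_boot_ci(resp, contrast_set[ord], n_boot = n_boot,
                              conf = conf, type = type, seed = NULL)
        est[i] <- ci$x50
        covered[i] <- ci$lower <= truth$x50_pos && truth$x50_pos <= ci$upper
      } else {
        est[i] <- fit_sigmoid(contrast_set[ord], colMeans(resp),
                              n = rep(n_crabs, length(contrast_set)))$x50
      }
    }
    list(x50_estimates = est, median_x50 = stats::median(est),
         coverage = if (n_boot > 0) mean(covered) else NA_real_,
         n_sims = n_sims)
  })
}

#' LRT type-I-error calibration and power study
#'
#' Replicates are drawn from the linear-logit generating model matched to
#' the analysis ([simulate_logit_trials()]): under the null the contrast
#' slope is zero but between-animal heterogeneity remains
#' (`crab_sd = 0.5`); under the alternative the reference effect size is
#' `logit p = -1 + 4 contrast`. Each replicate fits the full
#' (`contrast + order`) and reduced (`order`) random-intercept logistic
#' models and records the contrast LRT p-value. Fitting uses the Laplace
#' approximation (`nagq = 1`), adequate for calibration at this scale.
#'
#' @param n_null Null replicates (0 skips).
#' @param n_power Alternative replicates (0 skips).
#' @param n_crabs Animals per replicate.
#' @param contrast_set Contrast levels.
#' @param null_pars,alt_pars Named lists `beta0`, `beta_contrast`,
#'   `crab_sd` for the two regimes.
#' @param alpha Test level.
#' @param nagq Quadrature nodes for [fit_glmm()].
#' @param seed Integer seed.
#' @return List: `rejection_null`, `power`, `null_pvalues`, `n_null`,
#'   `n_power`.
#' @export
study_lrt_calibration <- function(n_null = 1000, n_power = 200, n_crabs = 20,
                                  contrast_set = seq(-0.5, 0.5,
                                                     length.out = 9),
                                  null_pars = list(beta0 = 0,
                                                   beta_contrast = 0,
                                                   crab_sd = 0.5),
                                  alt_pars = list(beta0 = -1,
                                                  beta_contrast = 4,
                                                  crab_sd = 0.5),
                                  alpha = 0.05, nagq = 1, seed = 1) {
  one_p <- function(pars) {
    trials <- simulate_logit_trials(pars$beta0, pars$beta_contrast,
                                    pars$crab_sd, n_crabs, contrast_set,
                                    seed = NULL)
    tryCatch({
      full <- fit_glmm(trials, fixed = c("contrast", "order"), nagq = nagq)
      reduced <- fit_glmm(trials, fixed = "order", nagq = nagq)
      lrt(full, reduced)$p
    }, error = function(e) NA_real_)
  }
  local_seed(seed, {
    p_null <- if (n_null > 0) vapply(seq_len(n_null),
                                     function(i) one_p(null_pars),
                                     numeric(1))
    p_alt <- if (n_power > 0) vapply(seq_len(n_power),
                                     function(i) one_p(alt_pars),
                                     numeric(1))
    list(rejection_null = if (n_null > 0) mean(p_null < alpha, na.rm = TRUE)
           else NA_real_,
         power = if (n_power > 0) mean(p_alt < alpha, na.rm = TRUE)
           else NA_real_,
         null_pvalues = if (n_null > 0) p_null,
         n_null = n_null, n_power = n_power)
  })
}

#' Habituation-rate recovery study
#'
#' Simulates observers whose response probability drops by a fixed amount
#' per successive presentation and checks that the habituation line fit
#' recovers that decrement as its slope `h`. Observer asymptotes and the
#' random-intercept SD are set so probabilities stay inside (0, 1) and the
#' additive decrement is never clipped.
#'
#' @param n_reps Replicate experiments.
#' @param n_crabs Animals per replicate.
#' @param contrast_set Contrast levels.
#' @param truth Generating [observer_model()] (its
#'   `habituation_decrement` is the target).
#' @param seed Integer seed.
#' @return List: `h_estimates`, `mean_h`, `true_h`, `n_reps`.
#' @export
study_habituation_recovery <- function(n_reps = 500, n_crabs = 15,
                                       contrast_set = seq(-0.5, 0.5,
                                                          length.out = 9),
                                       truth = observer_model(
                                         bottom = 0.55, top = 0.95,
                                         x50_pos = 0.2, x50_neg = 0.2,
                                         slope = 6, crab_sd = 0.2,
                                         habituation_decrement = 0.05),
                                       seed = 1) {
  local_seed(seed, {
    h <- vapply(seq_len(n_reps), function(i) {
      trials <- simulate_trials(truth, n_crabs, contrast_set, seed = NULL)
      fit_habituation(trials$order, trials$response)$h
    }, numeric(1))
    list(h_estimates = h, mean_h = mean(h),
         true_h = -truth$habituation_decrement, n_reps = n_reps)
  })
}

#' Toy dataset for checking the GLMM marginal likelihood
#'
#' A fixed two-animal, ten-trials-each binary dataset with a clear
#' between-animal difference, small enough for the random intercept to be
#' integrated out by brute-force quadrature.
#'
#' @return Per-trial data frame (`crab_id`, `contrast`, `order`,
#'   `response`).
#' @export
glmm_toy_data <- function() {
  contrast <- rep(seq(-0.5, 0.4, by = 0.1), 2)
  data.frame(
    crab_id = rep(c("A", "B"), each = 10),
    contrast = contrast,
    order = rep(1:10, 2),
    response = c(0, 0, 1, 0, 1, 1, 1, 1, 1, 1,
                 0, 0, 0, 1, 0, 0, 0, 1, 1, 0))
}

#' Quadrature-accuracy check on the GLMM marginal likelihood
#'
#' Fits the random-intercept logistic model to [glmm_toy_data()] with
#' adaptive Gauss-Hermite quadrature and recomputes the marginal
#' log-likelihood at the fitted parameters by brute-force numerical
#' integration ([glmm_loglik_bruteforce()]).
#'
#' @param nagq Quadrature nodes for the fit.
#' @return List: `loglik_fit`, `loglik_bruteforce`, `gap` (absolute
#'   difference), `n_obs`.
#' @export
study_glmm_quadrature_gap <- function(nagq = 25) {
  toy <- glmm_toy_data()
  fit <- fit_glmm(toy, fixed = "contrast", nagq = nagq)
  bf <- glmm_loglik_bruteforce(fit)
  list(loglik_fit = fit$loglik, loglik_bruteforce = bf,
       gap = abs(fit$loglik - bf), n_obs = fit$n_obs)
}
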