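# Trial-table I/O, configuration validation, and the umbrella pipeline that
# binds polarimetry, stimulus design, simulation and behavioural analysis
# into one reproducible run.

TRIAL_HEADER <- c("crab_id", "species", "modality", "contrast", "order",
                  "behaviour", "onset_s", "pre_stim_retreat")

#' Read a behavioural trial table
#'
#' Long-format CSV, one scored behaviour per row and an empty `behaviour`
#' field for trials without any: columns
#' `crab_id,species,modality,contrast,order,behaviour,onset_s,pre_stim_retreat`.
#' Every row is validated (numeric contrast, integer order >= 1, known
#' behaviour kind, finite onset, boolean retreat flag); all offending rows
#' are reported together and the run aborts if any are invalid.
#'
#' @param path CSV file path.
#' @return Typed long-format data frame of class `trial_table`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(raw), TRIAL_HEADER))
    stop("malformed trial-table header; expected: ",
         paste(TRIAL_HEADER, collapse = ","), call. = FALSE)
  if (nrow(raw) == 0) {
    out <- data.frame(crab_id = character(), species = character(),
                      modality = character(), contrast = numeric(),
                      order = integer(), behaviour = character(),
                      onset_s = numeric(), pre_stim_retreat = logical())
    class(out) <- c("trial_table", "data.frame")
    return(out)
  }
  errs <- character()
  bad <- function(row, field, why)
    errs <<- c(errs, sprintf("row %d, %s: %s", row, field, why))
  contrast <- suppressWarnings(as.numeric(raw$contrast))
  ord <- suppressWarnings(as.numeric(raw$order))
  onset <- suppressWarnings(as.numeric(raw$onset_s))
  flag <- tolower(trimws(raw$pre_stim_retreat))
  for (i in seq_len(nrow(raw))) {
    if (is.na(contrast[i])) bad(i, "contrast", "not a number")
    if (is.na(ord[i]) || ord[i] < 1 || ord[i] != round(ord[i]))
      bad(i, "order", "must be an integer >= 1")
    b <- trimws(raw$behaviour[i])
    if (!(b %in% c("", BEHAVIOUR_KINDS)))
      bad(i, "behaviour", paste0("unknown kind '", b, "'"))
    if (b != "" && (is.na(onset[i]) || !is.finite(onset[i])))
      bad(i, "onset_s", "behaviour rows need a finite onset")
    if (!(flag[i] %in% c("true", "false", "0", "1")))
      bad(i, "pre_stim_retreat", "must be boolean")
  }
  if (length(errs))
    stop("invalid trial table:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  out <- data.frame(crab_id = raw$crab_id, species = raw$species,
                    modality = raw$modality, contrast = contrast,
                    order = as.integer(ord),
                    behaviour = trimws(raw$behaviour), onset_s = onset,
                    pre_stim_retreat = flag %in% c("true", "1"))
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write a trial table as CSV
#'
#' Accepts either a long-format table (as from [read_trials()]) or a
#' per-trial table with a binary `response` column (as from
#' [simulate_trials()]); the latter is expanded to the long dialect with a
#' single nominal `retreat` behaviour at 1 s for responding trials.
#'
#' @param trials Data frame in either format.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if ("response" %in% names(trials)) {
    long <- data.frame(crab_id = trials$crab_id, species = trials$species,
                       modality = trials$modality,
                       contrast = trials$contrast, order = trials$order,
                       behaviour = ifelse(trials$response == 1, "retreat", ""),
                       onset_s = ifelse(trials$response == 1, 1, NA),
                       pre_stim_retreat = trials$pre_stim_retreat)
  } else {
    long <- trials[, TRIAL_HEADER]
  }
  long$onset_s <- ifelse(is.na(long$onset_s), "", format(long$onset_s))
  long$pre_stim_retreat <- ifelse(long$pre_stim_retreat, "true", "false")
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse a long trial table to per-trial scored responses
#'
#' Groups behaviour rows by presentation and applies the response rule of
#' [score_response()]: a trial counts as a response if any behaviour onset
#' falls inside the scoring window.
#'
#' @param trials Long-format `trial_table`.
#' @param window Scoring window in seconds.
#' @return Per-trial data frame with a binary `response` column.
#' @export
score_trials <- function(trials, window = c(0, 5)) {
  key <- interaction(trials$crab_id, trials$species, trials$modality,
                     trials$contrast, trials$order, drop = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  rows <- lapply(idx, function(ii) {
    first <- trials[ii[1], ]
    hit <- trials$behaviour[ii] != "" &
      !is.na(trials$onset_s[ii]) &
      trials$onset_s[ii] >= window[1] & trials$onset_s[ii] <= window[2]
    data.frame(crab_id = first$crab_id, species = first$species,
               modality = first$modality, contrast = first$contrast,
               order = first$order, response = as.integer(any(hit)),
               pre_stim_retreat = any(trials$pre_stim_retreat[ii]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$crab_id, out$order), ]
  rownames(out) <- NULL
  out
}

RESULTS_SCHEMA_VERSION <- "1.0.0"

check_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  required <- c("seed", "out_dir")
  missing <- setdiff(required, names(config))
  if (!("trials" %in% names(config)) && !("synthdata" %in% names(config)))
    missing <- c(missing, "trials|synthdata")
  if (length(missing))
    stop("config is missing required block(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  defaults <- list(window = c(0, 5), nagq = 20, quadratic = FALSE,
                   figures = TRUE)
  config$behaviour <- utils::modifyList(defaults,
                                        as.list(config$behaviour %||% list()))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analyse_group <- function(per_trial, long, behaviour_cfg) {
  res <- list(n_trials = nrow(per_trial),
              n_crabs = length(unique(per_trial$crab_id)))
  stage <- function(name, expr) tryCatch(expr, error = function(e) {
    warning(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    list(error = conditionMessage(e), stage = name)
  })
  abs_fit <- function(sub) {
    f <- fit_sigmoid(abs(sub$contrast), sub$response)
    list(bottom = f$bottom, top = f$top, x50 = f$x50, slope = f$slope,
         converged = f$converged, x50_reliable = f$x50_reliable)
  }
  pos <- per_trial[per_trial$contrast >= 0, ]
  neg <- per_trial[per_trial$contrast <= 0, ]
  res$sigmoid <- stage("sigmoid", list(
    positive = if (length(unique(pos$contrast)) >= 4) abs_fit(pos),
    negative = if (length(unique(neg$contrast)) >= 4) abs_fit(neg)))
  res$habituation <- stage("habituation", {
    h <- fit_habituation(per_trial$order, per_trial$response)
    list(h = h$h, intercept = h$intercept)
  })
  res$glmm <- stage("glmm", {
    full <- fit_glmm(per_trial, fixed = c("contrast", "order"),
                     quadratic = behaviour_cfg$quadratic,
                     nagq = behaviour_cfg$nagq)
    no_contrast <- fit_glmm(per_trial, fixed = "order",
                            nagq = behaviour_cfg$nagq)
    no_order <- fit_glmm(per_trial,
                         fixed = "contrast",
                         quadratic = behaviour_cfg$quadratic,
                         nagq = behaviour_cfg$nagq)
    list(coefficients = as.list(full$coefficients),
         random_intercept_sd = full$random_intercept_sd,
         loglik = full$loglik, converged = full$converged,
         lrt_contrast = lrt(full, no_contrast),
         lrt_order = lrt(full, no_order))
  })
  if (any(per_trial$contrast > 0) && any(per_trial$contrast < 0)) {
    res$polarity_split <- stage("polarity_split", {
      ps <- polarity_split_fits(per_trial, nagq = behaviour_cfg$nagq)
      lapply(ps, function(side) {
        if (is.null(side)) return(NULL)
        if (isTRUE(side$non_identifiable)) return(list(non_identifiable = TRUE))
        list(contrast_coef = unname(side$fit$coefficients["contrast"]),
             lrt = side$lrt)
      })
    })
  }
  res
}

group_figures <- function(per_trial, long, out_prefix) {
  by_contrast <- stats::aggregate(response ~ contrast, data = per_trial, mean)
  p1 <- ggplot2::ggplot(by_contrast,
                        ggplot2::aes(x = contrast, y = response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "stimulus contrast", y = "response probability",
                  title = "Contrast response") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  by_order <- stats::aggregate(response ~ order, data = per_trial, mean)
  hfit <- fit_habituation(per_trial$order, per_trial$response)
  p2 <- ggplot2::ggplot(by_order, ggplot2::aes(x = order, y = response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = hfit$intercept, slope = hfit$h,
                         colour = "blue") +
    ggplot2::labs(x = "stimulus order", y = "response probability",
                  title = sprintf("Habituation (h = %+.3f)", hfit$h)) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  ggplot2::ggsave(paste0(out_prefix, "_contrast.png"), p1,
                  width = 4, height = 3, dpi = 120)
  ggplot2::ggsave(paste0(out_prefix, "_order.png"), p2,
                  width = 4, height = 3, dpi = 120)
  if (!is.null(long) && any(long$behaviour != "")) {
    bl <- long[long$behaviour != "", ]
    p3 <- ggplot2::ggplot(bl, ggplot2::aes(x = onset_s, fill = behaviour)) +
      ggplot2::geom_histogram(binwidth = 0.5, position = "stack") +
      ggplot2::scale_fill_manual(values = c(stop = "red", retreat = "gold",
                                            walk = "blue")) +
      ggplot2::labs(x = "behaviour onset (s from loom onset)", y = "count",
                    title = "Behaviour timing") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(paste0(out_prefix, "_timing.png"), p3,
                    width = 4, height = 3, dpi = 120)
  }
  invisible(NULL)
}

#' Run the full behavioural analysis pipeline
#'
#' Loads (or simulates) a trial table, applies the pre-stimulus-retreat
#' exclusion, and for every species-by-modality group fits the sigmoid
#' contrast-response curves (per contrast polarity, on absolute contrast)
#' with half-maximum thresholds, the habituation line, and the
#' random-intercept logistic models with likelihood-ratio tests for
#' contrast and order, plus polarity-split models where both polarities are
#' present. Writes `results.json` (schema-versioned), per-group summary
#' CSVs, and report figures into `out_dir`.
#'
#' @param config Configuration list or path to a YAML file. Required:
#'   `seed`, `out_dir`, and either `trials` (CSV path) or a `synthdata`
#'   block (`n_crabs`, `contrast_set`, optional `modality`, `species` and
#'   [observer_model()] parameters under `observer`). Optional `behaviour`
#'   block: `window`, `nagq`, `quadratic`, `figures`.
#' @return The results list, invisibly; also written to
#'   `file.path(out_dir, "results.json")`.
#' @export
run_pipeline <- function(config) {
  config <- check_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  long <- NULL
  if (!is.null(config$trials)) {
    long <- read_trials(config$trials)
    per_trial <- score_trials(long, window = config$behaviour$window)
  } else {
    sd_cfg <- config$synthdata
    obs <- do.call(observer_model, as.list(sd_cfg$observer %||% list()))
    per_trial <- simulate_trials(
      obs, n_crabs = sd_cfg$n_crabs,
      contrast_set = unlist(sd_cfg$contrast_set),
      modality = sd_cfg$modality %||% "polarization",
      species = sd_cfg$species %||% "synthetic", seed = NULL)
  }
  split_res <- apply_exclusions(per_trial)
  kept <- split_res$kept

  results <- list(schema_version = RESULTS_SCHEMA_VERSION,
                  seed = config$seed,
                  n_trials_total = nrow(per_trial),
                  n_trials_excluded = nrow(split_res$excluded),
                  groups = list())
  for (sp in unique(kept$species)) for (mo in unique(kept$modality)) {
    sub <- kept[kept$species == sp & kept$modality == mo, , drop = FALSE]
    if (!nrow(sub)) next
    sub_long <- if (!is.null(long))
      long[long$species == sp & long$modality == mo, , drop = FALSE]
    label <- paste(sp, mo, sep = "_")
    results$groups[[label]] <- analyse_group(sub, sub_long, config$behaviour)
    by_contrast <- stats::aggregate(response ~ contrast, data = sub, mean)
    utils::write.csv(by_contrast,
                     file.path(config$out_dir,
                               paste0(label, "_contrast_response.csv")),
                     row.names = FALSE)
    by_order <- stats::aggregate(response ~ order, data = sub, mean)
    utils::write.csv(by_order,
                     file.path(config$out_dir,
                               paste0(label, "_order_response.csv")),
                     row.names = FALSE)
    if (isTRUE(config$behaviour$figures))
      tryCatch(group_figures(sub, sub_long, file.path(config$out_dir, label)),
               error = function(e)
                 warning("figure rendering failed: ", conditionMessage(e)))
  }
  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
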