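#' Response transformations
#'
#' Element-wise transforms used before linear mixed modelling: `"none"`,
#' `"log10"` (for right-skewed positive distances), and
#' `"log10_one_minus"` (`log10(1 - r)` for correlation coefficients, which
#' pile up near 1).
#'
#' @param values Numeric vector.
#' @param transform One of `"none"`, `"log10"`, `"log10_one_minus"`.
#' @return Transformed vector.
#' @export
apply_transform <- function(values,
                            transform = c("none", "log10",
                                          "log10_one_minus")) {
  transform <- match.arg(transform)
  switch(transform,
    none = values,
    log10 = {
      bad <- which(!is.na(values) & values <= 0)
      if (length(bad)) {
        stop("log10 transform needs positive values; offending rows: ",
             paste(bad, collapse = ", "))
      }
      log10(values)
    },
    log10_one_minus = {
      bad <- which(!is.na(values) & values >= 1)
      if (length(bad)) {
        stop("log10(1 - r) transform needs values < 1; offending rows: ",
             paste(bad, collapse = ", "))
      }
      log10(1 - values)
    }
  )
}

# inverse transforms, for reporting on the response scale
invert_transform <- function(values, transform) {
  switch(transform,
    none = values,
    log10 = 10^values,
    log10_one_minus = 1 - 10^values
  )
}

#' Response-to-model mapping
#'
#' Which model family, transformation, integerisation unit (for the
#' negative-binomial family) and speed-covariate refit apply to each
#' response measure.
#'
#' @return Data frame with columns `response`, `family`, `transform`,
#'   `integer_unit`, `speed_covariate`.
#' @export
response_model_map <- function() {
  data.frame(
    response = c("mean_centroid_dist", "modal_nnd", "median_speed",
                 "max_speed_corr", "max_dir_corr", "dir_delay_s",
                 "mean_perp", "mean_para", "mean_bearing_front",
                 "mean_bearing_behind", "mean_heading_diff"),
    family = c(rep("lmm", 6), rep("nb_glmm", 5)),
    transform = c("log10", "log10", "none", "log10_one_minus",
                  "log10_one_minus", "none", rep("none", 5)),
    integer_unit = c(rep(NA, 6), "mm", "mm", "deg", "deg", "deg"),
    speed_covariate = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                        rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
}

# continuous response -> counts for the NB family: offsets in cm are
# expressed in mm, angles stay in degrees; then rounded
integerize <- function(values, unit) {
  v <- switch(unit, mm = values * 10, deg = values,
              stop("unknown integer unit: ", unit))
  if (any(!is.na(v) & v < 0)) stop("negative values cannot be counts")
  as.integer(round(v))
}

model_frame <- function(data, response, transform = "none",
                        integer_unit = NA) {
  validate_fish_half(data)
  if (!response %in% names(data)) stop("no response column ", response)
  y <- data[[response]]
  if (all(is.na(y))) stop("response ", response, " is entirely missing")
  y <- if (!is.na(integer_unit)) {
    integerize(y, integer_unit)
  } else {
    apply_transform(y, transform)
  }
  mf <- data.frame(
    y = y,
    treatment = factor(data$treatment, levels = c("ambient",
                                                  "pile_driving")),
    half = factor(data$half, levels = c("first", "second")),
    trial = factor(data$trial),
    trial_half = factor(paste(data$trial, data$half)),
    fish = factor(paste(data$trial, data$fish)),
    median_speed = if ("median_speed" %in% names(data)) {
      data$median_speed
    } else {
      NA_real_
    }
  )
  mf[!is.na(mf$y), ]
}

#' Linear mixed model on a per-fish-per-half response
#'
#' Fits `response ~ treatment * half` with random intercepts for trial,
#' for trial-half (the split-plot whole-plot error: the four fish of a
#' trial share group-level fluctuations between halves, and the
#' treatment x half test must be referenced to that stratum), and for fish
#' within trial (REML). The treatment x half interaction is
#' tested with the balanced split-plot whole-plot F (a between-treatment
#' comparison of trial-mean half-differences, F with 1 and
#' `n_trials - 2` df), which stays exact whatever the sign of the
#' within-trial correlation of fish changes; when its p-value is at or above
#' `alpha_prune` the interaction is dropped and the model refitted with
#' main effects only (the reported fixed effects then come from the
#' refit). Optionally adds the fish's median speed as a covariate.
#'
#' @param data Per-fish-per-half response table (see
#'   [fish_half_summaries()]).
#' @param response Response column name.
#' @param covariate_speed Add `median_speed` as a main effect?
#' @param alpha_prune Pruning level for the interaction (default 0.05).
#' @param transform Transformation applied before fitting; defaults to the
#'   mapping in [response_model_map()].
#' @return A `model_fit_result`.
#' @export
fit_lmm <- function(data, response, covariate_speed = FALSE,
                    alpha_prune = 0.05, transform = NULL) {
  map <- response_model_map()
  if (is.null(transform)) {
    transform <- if (response %in% map$response) {
      map$transform[map$response == response]
    } else {
      "none"
    }
  }
  mf <- model_frame(data, response, transform = transform)
  if (length(unique(mf$trial[mf$treatment == "ambient"])) < 2 ||
      length(unique(mf$trial[mf$treatment == "pile_driving"])) < 2) {
    stop("need at least 2 trials per treatment")
  }
  cov_term <- if (covariate_speed) " + median_speed" else ""
  f_full <- stats::as.formula(paste0(
    "y ~ treatment * half", cov_term,
    " + (1 | trial) + (1 | trial_half) + (1 | fish)"))
  fit_full <- suppressMessages(lmerTest::lmer(f_full, data = mf, REML = TRUE))
  interaction <- whole_plot_interaction(mf, covariate_speed)
  pruned <- interaction$p >= alpha_prune
  fit_rep <- fit_full
  if (pruned) {
    f_main <- stats::as.formula(paste0(
      "y ~ treatment + half", cov_term,
      " + (1 | trial) + (1 | trial_half) + (1 | fish)"))
    fit_rep <- suppressMessages(lmerTest::lmer(f_main, data = mf, REML = TRUE))
  }
  cf <- summary(fit_rep)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit_rep))
  structure(
    list(
      response = response, family = "lmm", transform = transform,
      covariate_speed = covariate_speed,
      interaction = interaction,
      pruning = if (pruned) "interaction_dropped" else "interaction_kept",
      fixef = cf,
      varcomp = vc[, c("grp", "vcov", "sdcor")],
      singular = lme4::isSingular(fit_rep),
      dispersion = NA_real_, k = NA_real_,
      df_method = "within-between (whole-plot F on trial-half means)",
      n_obs = nrow(mf),
      model = fit_rep
    ),
    class = "model_fit_result"
  )
}

# Balanced split-plot whole-plot F test for the treatment x half
# interaction: trials are the whole plots, so the interaction contrast is
# identified by the trial-mean half-differences, and comparing those
# between treatments is exact regardless of how fish within a trial are
# correlated (centroid-based measures are negatively correlated within a
# group, which random intercepts cannot express). With the speed
# covariate, the trial-mean speed change joins the whole-plot regression.
whole_plot_interaction <- function(mf, covariate_speed = FALSE) {
  agg <- stats::aggregate(y ~ trial + treatment + half, data = mf,
                          FUN = mean)
  wide <- merge(agg[agg$half == "first", c("trial", "treatment", "y")],
                agg[agg$half == "second", c("trial", "y")],
                by = "trial", suffixes = c("_1", "_2"))
  wide$delta <- wide$y_2 - wide$y_1
  if (covariate_speed) {
    sp <- stats::aggregate(median_speed ~ trial + half, data = mf,
                           FUN = mean)
    dsp <- merge(sp[sp$half == "first", c("trial", "median_speed")],
                 sp[sp$half == "second", c("trial", "median_speed")],
                 by = "trial", suffixes = c("_1", "_2"))
    wide$dspeed <- dsp$median_speed_2 - dsp$median_speed_1
    fit <- stats::lm(delta ~ treatment + dspeed, data = wide)
  } else {
    fit <- stats::lm(delta ~ treatment, data = wide)
  }
  cf <- summary(fit)$coefficients["treatmentpile_driving", ]
  ddf <- stats::df.residual(fit)
  list(statistic = unname(cf["t value"]^2), ndf = 1L, ddf = ddf,
       p = unname(cf["Pr(>|t|)"]))
}

#' Negative-binomial GLMM on a per-fish-per-half response
#'
#' Fits a negative-binomial (log link, variance `mu * (1 + mu / k)`) GLMM
#' with the same fixed and random structure as [fit_lmm()], for the
#' right-skewed angle and offset responses. Continuous responses are
#' integerised first (degrees for angles, millimetres for offsets). The
#' interaction is tested by a likelihood-ratio chi-square against the
#' main-effects model and pruned by the same rule; the shape `k` and the
#' fixed-effects-GLM dispersion statistic (see [dispersion_check()]) are
#' reported.
#'
#' @inheritParams fit_lmm
#' @return A `model_fit_result`.
#' @export
fit_nb_glmm <- function(data, response, alpha_prune = 0.05) {
  map <- response_model_map()
  unit <- if (response %in% map$response) {
    map$integer_unit[map$response == response]
  } else {
    "deg"
  }
  mf <- model_frame(data, response, integer_unit = unit)
  if (all(mf$y == 0)) stop("all-zero response: nothing to model")
  f_full <- y ~ treatment * half + (1 | trial) + (1 | trial_half) +
    (1 | fish)
  f_main <- y ~ treatment + half + (1 | trial) + (1 | trial_half) +
    (1 | fish)
  nb_fit <- function(f, fix_shape = FALSE) {
    args <- list(f, data = mf, family = glmmTMB::nbinom2())
    if (fix_shape) {
      # underdispersed data push the NB shape to its k -> Inf (Poisson)
      # boundary, where the Hessian degenerates; pin the shape there
      args$map <- list(betad = factor(NA))
      args$start <- list(betad = log(1e4))
    }
    tryCatch(suppressWarnings(do.call(glmmTMB::glmmTMB, args)),
             error = function(e) NULL)
  }
  # glmmTMB::logLik returns NA for boundary fits, so read the optimizer
  # objective (the negative log-likelihood) directly
  ll_of <- function(fit) {
    if (is.null(fit)) return(NA_real_)
    -fit$fit$objective
  }
  usable <- function(fit) is.finite(ll_of(fit))
  clean <- function(fit) {
    usable(fit) && isTRUE(fit$sdr$pdHess) &&
      (is.null(fit$fit$convergence) || fit$fit$convergence == 0)
  }
  shape_boundary <- FALSE
  fit_full <- nb_fit(f_full)
  fit_main <- nb_fit(f_main)
  if (!(clean(fit_full) && clean(fit_main))) {
    # underdispersed data push the NB shape to its k -> Inf (Poisson)
    # boundary, where the Hessian degenerates and the optimizer stalls;
    # pin the shape there, in BOTH models so the LRT stays nested
    shape_boundary <- TRUE
    fit_full <- nb_fit(f_full, fix_shape = TRUE)
    fit_main <- nb_fit(f_main, fix_shape = TRUE)
  }
  if (!usable(fit_full) || !usable(fit_main)) {
    stop("negative-binomial GLMM did not converge for ", response)
  }
  # a non-PD Hessian with a usable likelihood means a variance component
  # sits on its zero boundary: the GLMM analogue of a singular LMM fit;
  # reported as a diagnostic, not an error
  singular <- !isTRUE(fit_full$sdr$pdHess)
  chisq <- max(0, 2 * (ll_of(fit_full) - ll_of(fit_main)))
  interaction <- list(
    statistic = chisq, df = 1L,
    p = stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  )
  k <- stats::sigma(fit_full)  # nbinom2 dispersion parameter = NB shape k
  if (!is.finite(k) || k <= 0) stop("estimated NB shape k is not positive")
  pruned <- interaction$p >= alpha_prune
  fit_rep <- if (pruned) fit_main else fit_full
  disp <- dispersion_check(data, response)
  cf <- summary(fit_rep)$coefficients$cond
  structure(
    list(
      response = response, family = "nb_glmm", transform = "none",
      integer_unit = unit,
      interaction = interaction,
      pruning = if (pruned) "interaction_dropped" else "interaction_kept",
      fixef = cf,
      varcomp = as.data.frame(glmmTMB::VarCorr(fit_rep)$cond),
      singular = singular,
      dispersion = disp$dispersion, dispersion_ok = disp$pass,
      k = k, shape_boundary = shape_boundary,
      df_method = "likelihood_ratio_chisq",
      n_obs = nrow(mf),
      model = fit_rep
    ),
    class = "model_fit_result"
  )
}

check_tmb_convergence <- function(fit) {
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0) {
    stop("negative-binomial GLMM did not converge: ", fit$fit$message)
  }
  invisible(fit)
}

#' Dispersion check for the negative-binomial family
#'
#' Refits the model as a fixed-effects-only negative-binomial GLM (same
#' fixed structure, no random effects) and reports the Pearson dispersion
#' statistic, chi-square over residual degrees of freedom. The variance
#' model is judged adequate when the statistic is more than 0.5 and less
#' than 2.
#'
#' @inheritParams fit_lmm
#' @return List with `dispersion`, `pass`, `df`.
#' @export
dispersion_check <- function(data, response) {
  map <- response_model_map()
  unit <- if (response %in% map$response) {
    map$integer_unit[map$response == response]
  } else {
    "deg"
  }
  if (is.na(unit)) unit <- "deg"
  mf <- model_frame(data, response, integer_unit = unit)
  fit <- suppressWarnings(
    MASS::glm.nb(y ~ treatment * half, data = mf)
  )
  if (!fit$converged) stop("dispersion-check GLM did not converge")
  disp <- sum(stats::residuals(fit, type = "pearson")^2) /
    stats::df.residual(fit)
  list(dispersion = disp, pass = disp > 0.5 && disp < 2,
       df = stats::df.residual(fit))
}

#' Effect size of the playback-induced change
#'
#' Cohen's d comparing the two treatments on the per-fish change score
#' (second-half value minus first-half value), aggregated to trial means
#' first so that fish within a trial do not count as independent. Positive
#' d means the pile-driving treatment increased the response more (or
#' decreased it less) than the ambient treatment.
#'
#' @inheritParams fit_lmm
#' @return List with `d`, `n_trials` (per treatment), and the per-trial
#'   mean changes.
#' @export
effect_size_of_change <- function(data, response) {
  validate_fish_half(data)
  w <- data[, c("trial", "fish", "treatment", "half", response)]
  names(w)[5] <- "value"
  wide <- merge(
    w[w$half == "first", c("trial", "fish", "treatment", "value")],
    w[w$half == "second", c("trial", "fish", "value")],
    by = c("trial", "fish"), suffixes = c("_1", "_2")
  )
  wide$delta <- wide$value_2 - wide$value_1
  tm <- stats::aggregate(delta ~ trial + treatment, data = wide, FUN = mean)
  amb <- tm$delta[tm$treatment == "ambient"]
  pile <- tm$delta[tm$treatment == "pile_driving"]
  if (length(amb) < 2 || length(pile) < 2) {
    stop("need at least 2 trials per treatment")
  }
  sp <- sqrt(((length(amb) - 1) * stats::var(amb) +
                (length(pile) - 1) * stats::var(pile)) /
               (length(amb) + length(pile) - 2))
  d <- if (sp == 0) 0 else (mean(pile) - mean(amb)) / sp
  list(d = d, n_trials = c(ambient = length(amb),
                           pile_driving = length(pile)),
       trial_changes = tm)
}

#' Fit all response models
#'
#' Applies the family/transform mapping of [response_model_map()] to every
#' response present in the table: LMMs for the distance, speed,
#' correlation and delay measures (with speed-covariate refits where
#' mapped), negative-binomial GLMMs for the angle and offset measures, and
#' effect sizes of change throughout. The speed delay flagged as excluded
#' from inference is not modelled.
#'
#' @param data Per-fish-per-half response table.
#' @param alpha_prune Interaction-pruning level.
#' @return List with `fits` (named `model_fit_result`s, covariate refits
#'   under `<response>__speed_cov`), `summary` (tidy data frame: response,
#'   family, transform, interaction statistic/df/p, pruning, dispersion,
#'   k, singular), and `effect_sizes` (response, d, n_trials).
#' @export
fit_all_models <- function(data, alpha_prune = 0.05) {
  map <- response_model_map()
  fits <- list()
  srows <- list()
  erows <- list()
  for (r in seq_len(nrow(map))) {
    resp <- map$response[r]
    if (!resp %in% names(data) || all(is.na(data[[resp]]))) next
    fit <- if (map$family[r] == "lmm") {
      fit_lmm(data, resp, alpha_prune = alpha_prune)
    } else {
      fit_nb_glmm(data, resp, alpha_prune = alpha_prune)
    }
    fits[[resp]] <- fit
    srows[[resp]] <- summarise_fit(fit)
    if (map$speed_covariate[r]) {
      cfit <- fit_lmm(data, resp, covariate_speed = TRUE,
                      alpha_prune = alpha_prune)
      fits[[paste0(resp, "__speed_cov")]] <- cfit
      s <- summarise_fit(cfit)
      s$response <- paste0(resp, "__speed_cov")
      srows[[paste0(resp, "__speed_cov")]] <- s
    }
    es <- effect_size_of_change(data, resp)
    erows[[resp]] <- data.frame(response = resp, d = es$d,
                                n_trials_ambient = es$n_trials[["ambient"]],
                                n_trials_pile = es$n_trials[["pile_driving"]])
  }
  list(
    fits = fits,
    summary = do.call(rbind, c(srows, list(make.row.names = FALSE))),
    effect_sizes = do.call(rbind, c(erows, list(make.row.names = FALSE)))
  )
}

summarise_fit <- function(fit) {
  data.frame(
    response = fit$response,
    family = fit$family,
    transform = fit$transform,
    interaction_stat = fit$interaction$statistic,
    interaction_ndf = if (fit$family == "lmm") fit$interaction$ndf else
      fit$interaction$df,
    interaction_ddf = if (fit$family == "lmm") fit$interaction$ddf else
      NA_real_,
    interaction_p = fit$interaction$p,
    pruning = fit$pruning,
    dispersion = fit$dispersion,
    k = fit$k,
    singular = fit$singular,
    df_method = fit$df_method,
    n_obs = fit$n_obs
  )
}

#' @export
print.model_fit_result <- function(x, ...) {
  cat(sprintf(
    "<model_fit_result> %s (%s, transform %s)\n  interaction: stat %.3f, p %.4g (%s)\n",
    x$response, x$family, x$transform, x$interaction$statistic,
    x$interaction$p, x$pruning))
  if (x$family == "nb_glmm") {
    cat(sprintf("  k = %.3f, dispersion = %.3f\n", x$k, x$dispersion))
  }
  invisible(x)
}
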