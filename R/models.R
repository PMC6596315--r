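# Mixed-effects analyses: per-descriptor linear mixed models of production,
# the logistic mixed model of 2AFC perception, per-subject cue-weight
# extraction (fixed effect + BLUP), and perception-production coupling
# correlations. Factors are coded 0/1 (Tone1/NH reference) so random slopes
# stay numeric and a diagonal-covariance refit is always available for
# singular fits.

#' Fit the production linear mixed-effects model for one descriptor
#'
#' Maximum-likelihood fit of
#' `value ~ 1 + tone * hearing + (1 + tone | participant)`: fixed effects
#' for the lexical tone contrast (Tone 4 vs Tone 1), hearing status (CI vs
#' NH) and their interaction, with a per-participant random intercept and
#' random contrast slope. t statistics use residual-style degrees of freedom
#' (`n - 4`; 446 for the 75-speaker, 3-repetition design). A singular
#' random-effects fit is retried with a diagonal covariance and flagged.
#'
#' @param observations Tidy descriptor table (from [analyze_cohort()] or
#'   [simulate_descriptors()]): columns `speaker` (or `participant`),
#'   `group`, `tone`, and the descriptor column.
#' @param parameter Name of the descriptor column to analyze (default
#'   `"duration_ratio"`).
#' @param reml Use REML instead of ML (default FALSE).
#' @return A `tone_lme`: list with `coefficients` (term, estimate, se, t,
#'   df, p), `model` (the merMod), `parameter`, `n_obs`, `singular_refit`.
#' @export
fit_production_lme <- function(observations, parameter = "duration_ratio",
                               reml = FALSE) {
  d <- as.data.frame(observations)
  if (is.null(d$participant)) d$participant <- d$speaker
  stopifnot(parameter %in% names(d),
            length(unique(d$group)) >= 2, length(unique(d$tone)) >= 2)
  d$value <- d[[parameter]]
  d <- d[is.finite(d$value), ]
  d$tone4 <- as.numeric(d$tone == "Tone4")
  d$ci <- as.numeric(d$group == "CI")

  fit <- lme4::lmer(value ~ tone4 * ci + (1 + tone4 | participant),
                    data = d, REML = reml)
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    fit <- lme4::lmer(value ~ tone4 * ci + (1 + tone4 || participant),
                      data = d, REML = reml)
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  df <- nrow(d) - length(est)
  tval <- est / se
  coefs <- data.frame(term = c("(Intercept)", "contrast", "hearing",
                               "contrast:hearing"),
                      estimate = unname(est), se = unname(se),
                      t = unname(tval), df = df,
                      p = 2 * stats::pt(-abs(unname(tval)), df))
  structure(list(coefficients = coefs, model = fit, parameter = parameter,
                 n_obs = nrow(d), singular_refit = singular),
            class = "tone_lme")
}

#' @export
print.tone_lme <- function(x, ...) {
  cat(sprintf("Linear mixed model for '%s' (%d observations%s)\n",
              x$parameter, x$n_obs,
              if (x$singular_refit) ", diagonal random covariance" else ""))
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  se = signif(se, 3), t = round(t, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Fit the perception logistic mixed-effects model
#'
#' Logistic mixed model of the probability of a "Tone 1" response:
#' fixed effects `population * F0variation * duration` (F0 variation as fall
#' magnitude in octaves; duration as log-transformed percent centered at the
#' grid's log-mean; population CI vs NH) and per-participant random
#' intercept plus random slopes for F0 variation, duration and F0 height
#' (height contrast-coded +/-0.5, not a fixed factor). Responses are
#' aggregated to binomial counts per participant and token before fitting.
#'
#' @param responses Response records from [simulate_responses()] /
#'   [simulate_experiment()] (columns listener, group, f0var or
#'   f0_slope_oct, duration_pct or logdur_c, height_c or f0_height_hz,
#'   response).
#' @param nAGQ Integrator fidelity passed to [lme4::glmer()]; 0 (the fast
#'   penalized-likelihood approximation) by default, 1 for the Laplace fit.
#' @return A `tone_glmm`: `coefficients` (z-based table),
#'   `group_coefficients` (per-group F0-variation and duration coefficients
#'   with SEs and the interaction tests), `model`, `listener_groups`,
#'   `separated` (listeners with all-identical responses, flagged),
#'   `singular_refit`.
#' @export
fit_perception_glmm <- function(responses, nAGQ = 1) {
  d <- as.data.frame(responses)
  if (is.null(d$f0var)) d$f0var <- -d$f0_slope_oct
  if (is.null(d$logdur_c)) d$logdur_c <- log(d$duration_pct / 100) - logdur_center()
  if (is.null(d$height_c)) {
    d$height_c <- ifelse(d$f0_height_hz == max(d$f0_height_hz), 0.5, -0.5)
  }
  stopifnot(length(unique(d$group)) >= 2)
  d$ci <- as.numeric(d$group == "CI")
  agg <- stats::aggregate(response ~ listener + ci + f0var + logdur_c + height_c,
                          data = d, FUN = function(x) c(k = sum(x), n = length(x)))
  agg <- cbind(agg[setdiff(names(agg), "response")], agg$response)
  agg$fail <- agg$n - agg$k

  per_mean <- tapply(d$response, d$listener, mean)
  separated <- names(per_mean)[per_mean %in% c(0, 1)]

  ctrl <- lme4::glmerControl(optimizer = "bobyqa",
                             check.conv.singular = "ignore")
  form <- cbind(k, fail) ~ ci * f0var * logdur_c +
    (1 + f0var + logdur_c + height_c | listener)
  fit <- lme4::glmer(form, data = agg, family = stats::binomial(),
                     nAGQ = nAGQ, control = ctrl)
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    form2 <- cbind(k, fail) ~ ci * f0var * logdur_c +
      (1 + f0var + logdur_c + height_c || listener)
    fit <- lme4::glmer(form2, data = agg, family = stats::binomial(),
                       nAGQ = nAGQ, control = ctrl)
  }
  est <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = 2 * stats::pnorm(-abs(unname(z))))

  # per-group coefficients: NH = main effect, CI = main + interaction
  comb <- function(main, inter) {
    cvec <- numeric(length(est)); names(cvec) <- names(est)
    cvec[main] <- 1; if (!is.null(inter)) cvec[inter] <- 1
    c(estimate = sum(cvec * est), se = sqrt(drop(t(cvec) %*% V %*% cvec)))
  }
  gc <- rbind(
    data.frame(group = "NH", cue = "f0_variation", t(comb("f0var", NULL))),
    data.frame(group = "CI", cue = "f0_variation", t(comb("f0var", "ci:f0var"))),
    data.frame(group = "NH", cue = "duration", t(comb("logdur_c", NULL))),
    data.frame(group = "CI", cue = "duration", t(comb("logdur_c", "ci:logdur_c"))))

  lg <- unique(d[, c("listener", "group")])
  structure(list(coefficients = coefs, group_coefficients = gc, model = fit,
                 listener_groups = stats::setNames(lg$group, lg$listener),
                 separated = separated, singular_refit = singular,
                 nAGQ = nAGQ),
            class = "tone_glmm")
}

#' @export
print.tone_glmm <- function(x, ...) {
  cat(sprintf("Logistic mixed model of P(Tone 1) (%d listeners%s)\n",
              length(x$listener_groups),
              if (length(x$separated))
                paste0("; separated: ", paste(x$separated, collapse = ","))
              else ""))
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  se = signif(se, 3), z = round(z, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Extract per-subject cue weights from a perception fit
#'
#' A subject's weight on a cue is the applicable group fixed effect plus that
#' subject's predicted random slope (BLUP); `include_fixed = FALSE` returns
#' the BLUPs alone. The F0-variation weight is additionally expressed as
#' log10 of its absolute value for cross-group comparability.
#'
#' @param fit A `tone_glmm` from [fit_perception_glmm()].
#' @param include_fixed Add the group fixed effect to the BLUP (default
#'   TRUE).
#' @return Data frame: participant, group, w_f0slope, w_logdur, w_f0height,
#'   w_f0slope_log10abs.
#' @export
extract_subject_weights <- function(fit, include_fixed = TRUE) {
  stopifnot(inherits(fit, "tone_glmm"))
  re <- lme4::ranef(fit$model)$listener
  ids <- rownames(re)
  groups <- unname(fit$listener_groups[ids])
  gc <- fit$group_coefficients
  fixed_for <- function(grp, cue) {
    if (!include_fixed) return(0)
    gc$estimate[gc$group == grp & gc$cue == cue]
  }
  w_f0 <- re[["f0var"]] + vapply(groups, fixed_for, numeric(1), cue = "f0_variation")
  w_dur <- re[["logdur_c"]] + vapply(groups, fixed_for, numeric(1), cue = "duration")
  w_h <- re[["height_c"]]   # no fixed height effect in the model
  data.frame(participant = ids, group = groups,
             w_f0slope = w_f0, w_logdur = w_dur, w_f0height = w_h,
             w_f0slope_log10abs = ifelse(w_f0 == 0, NA_real_, log10(abs(w_f0))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-participant production summary for coupling analyses
#'
#' Averages descriptors over repetitions into the per-participant quantities
#' used in the coupling correlations: Tone 1 relative F0 median, Tone 4 F0
#' movement, and the Tone 1 - Tone 4 contrasts in duration ratio and
#' relative intensity peak.
#'
#' @param descriptors Tidy descriptor table.
#' @return Data frame: participant, group, tone1_f0_median_rel_st,
#'   tone4_f0_movement_st, duration_ratio_contrast, int_peak_diff_contrast.
#' @export
summarize_production <- function(descriptors) {
  d <- as.data.frame(descriptors)
  if (is.null(d$participant)) d$participant <- d$speaker
  per <- function(col, tone) {
    s <- d[d$tone == tone, ]
    tapply(s[[col]], s$participant, mean, na.rm = TRUE)
  }
  ids <- sort(unique(d$participant))
  grp <- d$group[match(ids, d$participant)]
  data.frame(
    participant = ids, group = grp,
    tone1_f0_median_rel_st = per("f0_median_rel_st", "Tone1")[ids],
    tone4_f0_movement_st = per("f0_movement_st", "Tone4")[ids],
    duration_ratio_contrast =
      per("duration_ratio", "Tone1")[ids] - per("duration_ratio", "Tone4")[ids],
    int_peak_diff_contrast =
      per("intensity_peak_diff_db", "Tone1")[ids] - per("intensity_peak_diff_db", "Tone4")[ids],
    row.names = NULL, stringsAsFactors = FALSE)
}

# the coupling pairs examined: the two reported relationships and the two
# null checks
default_coupling_pairs <- data.frame(
  weight = c("w_logdur", "w_f0slope_log10abs", "w_logdur", "w_f0slope"),
  descriptor = c("tone4_f0_movement_st", "tone1_f0_median_rel_st",
                 "duration_ratio_contrast", "tone4_f0_movement_st"),
  stringsAsFactors = FALSE)

#' Correlate perception cue weights with production descriptors
#'
#' Per-group Pearson correlations between per-subject cue weights and
#' per-participant production summaries, for each requested pair.
#'
#' @param weights Output of [extract_subject_weights()] (or any data frame
#'   with `participant`, `group` and weight columns).
#' @param production Output of [summarize_production()] (or a compatible
#'   per-participant table).
#' @param pairs Data frame with columns `weight` and `descriptor`; defaults
#'   to the two reported couplings plus the two null checks.
#' @return Data frame: group, weight, descriptor, n, r, r2, p.
#' @export
correlate_perception_production <- function(weights, production,
                                            pairs = default_coupling_pairs) {
  j <- merge(weights, production, by = c("participant", "group"))
  out <- list()
  for (g in unique(j$group)) {
    sub <- j[j$group == g, ]
    for (i in seq_len(nrow(pairs))) {
      w <- pairs$weight[i]; dsc <- pairs$descriptor[i]
      ok <- is.finite(sub[[w]]) & is.finite(sub[[dsc]])
      if (sum(ok) < 3L) {
        stop(sprintf("fewer than 3 joined participants in group %s for (%s, %s)",
                     g, w, dsc))
      }
      ct <- stats::cor.test(sub[[w]][ok], sub[[dsc]][ok])
      out[[length(out) + 1L]] <- data.frame(
        group = g, weight = w, descriptor = dsc, n = sum(ok),
        r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
        p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
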