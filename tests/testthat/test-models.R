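test_that("production LME recovers null and reports residual-style df", {
  d <- simulate_descriptors(6, 6, reps = 3, seed = 31, null_groups = TRUE,
                            jitter_sd = list(duration = 0.01,
                                             intensity_db = 0.1,
                                             f0_st = 0.1))
  fit <- fit_production_lme(d, "duration_ratio")
  co <- fit$coefficients
  expect_equal(co$df[1], nrow(d) - 4)
  # no group differences generated: hearing and interaction terms near zero
  for (term in c("hearing", "contrast:hearing")) {
    expect_lt(abs(co$estimate[co$term == term]), 0.05)
  }

  full <- simulate_descriptors(35, 40, reps = 3, seed = 32)
  f2 <- fit_production_lme(full, "duration_ratio")
  expect_equal(f2$coefficients$df[1], 446)   # the study-size design
  inter <- f2$coefficients[f2$coefficients$term == "contrast:hearing", ]
  expect_lt(inter$estimate, 0)               # CI shortens Tone 4 vs Tone 1
  expect_lt(inter$p, 0.001)

  expect_error(fit_production_lme(d[d$group == "NH", ], "duration_ratio"))
})

test_that("headline production effects reproduce their sign pattern", {
  d <- simulate_descriptors(20, 20, reps = 3, seed = 77)
  coef_of <- function(param, term) {
    co <- fit_production_lme(d, param)$coefficients
    co[co$term == term, ]
  }
  # intensity: contrast effect without interaction
  expect_lt(coef_of("intensity_peak_diff_db", "contrast")$p, 0.05)
  expect_gt(coef_of("intensity_peak_diff_db", "contrast:hearing")$p, 0.05)
  # F0 median and movement: group-dependent tone contrasts
  expect_lt(coef_of("f0_median_rel_st", "contrast:hearing")$p, 0.05)
  expect_lt(coef_of("f0_movement_st", "contrast:hearing")$p, 0.05)
})

test_that("perception GLMM recovers group coefficients and flags separation", {
  exp <- simulate_experiment(10, 10, n_sessions = 2, seed = 41,
                             group_means = list(NH = list(beta_f0slope = -18),
                                                CI = list(beta_f0slope = -4)))
  fit <- fit_perception_glmm(exp$responses, nAGQ = 0)
  gc <- fit$group_coefficients
  truth <- aggregate(beta_f0slope ~ group, exp$truth, mean)
  for (g in c("NH", "CI")) {
    row <- gc[gc$group == g & gc$cue == "f0_variation", ]
    expect_within(row$estimate, truth$beta_f0slope[truth$group == g],
                  2.5 * row$se)
  }
  inter <- fit$coefficients[fit$coefficients$term == "ci:f0var", ]
  expect_lt(inter$p, 0.001)
  # duration coefficient shared between groups by construction
  expect_gt(fit$coefficients$p[fit$coefficients$term == "ci:logdur_c"], 0.05)

  # degenerate all-Tone1 listener is flagged, fit still converges
  r <- exp$responses
  r$response[r$listener == "NH01"] <- 1L
  fit2 <- fit_perception_glmm(r, nAGQ = 0)
  expect_true("NH01" %in% fit2$separated)
})

test_that("subject weights are fixed effect + BLUP with the log10 transform", {
  exp <- simulate_experiment(8, 8, n_sessions = 2, seed = 51)
  fit <- fit_perception_glmm(exp$responses, nAGQ = 0)
  w <- extract_subject_weights(fit)
  expect_equal(nrow(w), 16)
  blup <- extract_subject_weights(fit, include_fixed = FALSE)
  gc <- fit$group_coefficients
  for (g in c("NH", "CI")) {
    fixed <- gc$estimate[gc$group == g & gc$cue == "f0_variation"]
    expect_equal(w$w_f0slope[w$group == g] - blup$w_f0slope[blup$group == g],
                 rep(fixed, sum(w$group == g)), tolerance = 1e-9)
  }
  expect_equal(w$w_f0slope_log10abs, log10(abs(w$w_f0slope)))
  expect_within(log10(abs(-20)), 1.301, 0.001)

  # heterogeneous duration weights are recovered in rank order
  rho <- cor(w$w_logdur,
             exp$truth$beta_logdur[match(w$participant, exp$truth$listener)],
             method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("coupling correlations recover signs, nulls and degeneracies", {
  set.seed(61)
  n <- 40
  mov <- rnorm(n, -4.5, 1.2)
  wdur <- 10 - 1.5 * abs(mov) + rnorm(n, 0, 1.2)  # anti-correlated with |mov|
  weights <- data.frame(participant = sprintf("CI%02d", 1:n), group = "CI",
                        w_f0slope = rnorm(n, -4, 1), w_logdur = wdur,
                        w_f0height = rnorm(n, 0, 0.5))
  weights$w_f0slope_log10abs <- log10(abs(weights$w_f0slope))
  prod <- data.frame(participant = weights$participant, group = "CI",
                     tone1_f0_median_rel_st = rnorm(n, 3, 1),
                     tone4_f0_movement_st = mov,
                     duration_ratio_contrast = rnorm(n, 0.3, 0.1),
                     int_peak_diff_contrast = rnorm(n, -1, 0.5))
  res <- correlate_perception_production(weights, prod)
  hit <- res[res$weight == "w_logdur" &
               res$descriptor == "tone4_f0_movement_st", ]
  expect_gt(hit$r, 0)    # weight rises as the signed movement rises toward 0
  expect_lt(hit$p, 0.05)
  null <- res[res$weight == "w_logdur" &
                res$descriptor == "duration_ratio_contrast", ]
  expect_gt(null$p, 0.01)

  weights2 <- weights
  weights2$w_logdur <- 2 * mov + 1          # perfectly collinear pair
  collinear <- correlate_perception_production(
    weights2, prod,
    pairs = data.frame(weight = "w_logdur",
                       descriptor = "tone4_f0_movement_st"))
  expect_equal(collinear$r2, 1, tolerance = 1e-9)

  expect_error(correlate_perception_production(weights[1:2, ], prod),
               "fewer than 3")
})

test_that("production summary aggregates per participant", {
  fix <- test_cohort()
  s <- summarize_production(fix$descriptors)
  expect_equal(nrow(s), 4)
  one <- fix$descriptors[fix$descriptors$speaker == s$participant[1] &
                           fix$descriptors$tone == "Tone4", ]
  expect_equal(s$tone4_f0_movement_st[1], mean(one$f0_movement_st))
})
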