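# Simulated 2AFC responses: the generative twin of the logistic mixed-model
# analysis. P(Tone 1) is a logistic function of the F0 fall magnitude
# (octaves), centered log-duration, and F0-height contrast, optionally mixed
# with a lapse rate.

# model covariates for a set of token specs
response_covariates <- function(token_specs) {
  data.frame(
    f0var = -token_specs$f0_slope_oct,                   # fall magnitude, 0..1
    logdur_c = log(token_specs$duration_pct / 100) - logdur_center(),
    height_c = ifelse(token_specs$f0_height_hz == max(continuum_heights),
                      0.5, -0.5))
}

#' Simulate one listener's 2AFC responses over the continuum
#'
#' One Bernoulli draw per token per session with
#' `P(Tone1) = lapse/2 + (1 - lapse) * plogis(eta)`, where `eta` is the
#' listener's linear predictor in F0-fall magnitude, centered log-duration
#' and F0-height contrast.
#'
#' @param listener A `listener_profile`.
#' @param token_specs Data frame of token specs (normally
#'   [build_token_grid()]).
#' @param n_sessions Number of repeated sessions (study: 3 or 4; default 3).
#' @param seed Integer seed.
#' @param listener_id Identifier stamped on the records.
#' @return Data frame: listener, group, session, token parameters, model
#'   covariates, `p_tone1`, and the binary `response` (1 = Tone 1).
#' @export
simulate_responses <- function(listener, token_specs, n_sessions = 3, seed = 1,
                               listener_id = "L01") {
  stopifnot(inherits(listener, "listener_profile"), n_sessions >= 1)
  if (nrow(token_specs) == 0L) stop("empty token set")
  cov <- response_covariates(token_specs)
  eta <- listener$beta_intercept + listener$beta_f0slope * cov$f0var +
    listener$beta_logdur * cov$logdur_c + listener$beta_f0height * cov$height_c
  p <- listener$lapse_rate / 2 + (1 - listener$lapse_rate) * stats::plogis(eta)
  out <- do.call(rbind, lapply(seq_len(n_sessions), function(s) {
    resp <- with_seed(derive_seed(seed, listener$seed, s, 17),
                      stats::rbinom(nrow(token_specs), 1L, p))
    data.frame(listener = listener_id, group = listener$group, session = s,
               token_specs[, c("token_id", "f0_slope_oct", "duration_pct",
                               "f0_height_hz")],
               cov, p_tone1 = p, response = resp,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a full perception experiment
#'
#' Draws `n_nh` NH and `n_ci` CI listeners (seeded between-listener
#' variation around group-default cue weights) and simulates all of their
#' sessions over the 96-token grid.
#'
#' @param n_nh,n_ci Listeners per group (study sizes: 35 NH, 40 CI).
#' @param n_sessions Sessions per listener (default 3).
#' @param seed Master seed.
#' @param lapse_rate Shared lapse rate (default 0).
#' @param group_means Optional list like
#'   `list(NH = list(beta_f0slope = -20), CI = list(beta_f0slope = -4))`
#'   overriding group-default coefficient means before the between-listener
#'   draw.
#' @return List: `responses` (stacked record data frame), `listeners`
#'   (profiles), `truth` (per-listener true coefficients).
#' @export
simulate_experiment <- function(n_nh = 35, n_ci = 40, n_sessions = 3, seed = 1,
                                lapse_rate = 0, group_means = NULL) {
  grid <- build_token_grid()
  groups <- c(rep("NH", n_nh), rep("CI", n_ci))
  ids <- c(sprintf("NH%02d", seq_len(n_nh)), sprintf("CI%02d", seq_len(n_ci)))
  listeners <- vector("list", length(ids))
  rows <- vector("list", length(ids))
  truth <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    prof <- make_listener_profile(groups[i], seed = derive_seed(seed, i, 23),
                                  lapse_rate = lapse_rate)
    shift <- group_means[[groups[i]]]
    for (nm in names(shift)) {
      d <- listener_group_defaults(groups[i])[[nm]]
      prof[[nm]] <- prof[[nm]] - d + shift[[nm]]
    }
    listeners[[i]] <- prof
    rows[[i]] <- simulate_responses(prof, grid, n_sessions,
                                    seed = derive_seed(seed, i, 29),
                                    listener_id = ids[i])
    truth[[i]] <- data.frame(listener = ids[i], group = groups[i],
                             beta_intercept = prof$beta_intercept,
                             beta_f0slope = prof$beta_f0slope,
                             beta_logdur = prof$beta_logdur,
                             beta_f0height = prof$beta_f0height,
                             stringsAsFactors = FALSE)
  }
  names(listeners) <- ids
  list(responses = do.call(rbind, rows), listeners = listeners,
       truth = do.call(rbind, truth))
}
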