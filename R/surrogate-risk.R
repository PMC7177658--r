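#' Crash-risk parameters
#'
#' Parameters of the stopping-distance surrogate: road friction `mu`
#' (dimensionless, 0.7), gravitational acceleration `g` (9.8 m/s^2), and the
#' driver reaction time `tau`, which is regime-dependent: 1.5 s while the
#' follower is accelerating, 0.7 s while decelerating or idling.
#'
#' @param mu Friction coefficient.
#' @param g Gravitational acceleration (m/s^2).
#' @param tau_accel Reaction time while accelerating (s).
#' @param tau_decel Reaction time while decelerating or idling (s).
#' @param dt Sampling interval (s).
#' @return Object of class `risk_params`.
#' @export
risk_params <- function(mu = 0.7, g = 9.8, tau_accel = 1.5, tau_decel = 0.7,
                        dt = 0.1) {
  stopifnot(mu > 0, g > 0, tau_accel > 0, tau_decel > 0, dt > 0,
            tau_accel >= tau_decel)
  structure(list(mu = mu, g = g, tau_accel = tau_accel,
                 tau_decel = tau_decel, dt = dt),
            class = "risk_params")
}

#' Difference of space distance and stopping distance (DSS)
#'
#' Signed safety margin, in metres, between the spacing available to the
#' follower and the spacing it needs when both vehicles brake at `mu * g`,
#' allowing a reaction time `tau`:
#' `DSS = (v_l^2 - v_f^2) / (2 mu g) + d - tau * v_f`.
#' Negative values signal rear-end collision risk.
#'
#' @param v_l,v_f Leader / follower speed (m/s), non-negative. Vectorised.
#' @param d Gap (m), non-negative.
#' @param tau Reaction time (s); see [select_tau()].
#' @param params [risk_params()].
#' @return DSS in metres.
#' @export
compute_dss <- function(v_l, v_f, d, tau, params = risk_params()) {
  if (any(v_l < 0) || any(v_f < 0)) {
    stop_acr("speeds must be non-negative", class = "acr_domain_error")
  }
  if (any(d < 0)) stop_acr("gap must be non-negative", class = "acr_domain_error")
  (v_l^2 - v_f^2) / (2 * params$mu * params$g) + d - tau * v_f
}

#' Reaction-time regime
#'
#' The follower's instantaneous acceleration decides the reaction time used
#' in the DSS: strictly positive acceleration selects `tau_accel` (1.5 s);
#' deceleration or idling (a_f <= 0) selects `tau_decel` (0.7 s).
#'
#' @param a_f Follower acceleration (m/s^2). Vectorised.
#' @param params [risk_params()].
#' @return Reaction time(s) in seconds.
#' @export
select_tau <- function(a_f, params = risk_params()) {
  stopifnot(all(is.finite(a_f)))
  ifelse(a_f > 0, params$tau_accel, params$tau_decel)
}

#' Instantaneous crash risk (CR)
#'
#' Zero when DSS is positive (the follower can stop in time); otherwise the
#' magnitude of the deficit expressed as a time, `|DSS| / v_f`, in seconds.
#' A stationary follower (`v_f = 0`) with non-positive DSS is assigned risk
#' 0: that state is reachable only at zero gap and zero leader speed, where
#' the follower cannot close the remaining distance.
#'
#' @param dss DSS values (m). Vectorised.
#' @param v_f Follower speed (m/s), non-negative.
#' @return Crash risk in seconds, non-negative.
#' @export
compute_cr <- function(dss, v_f) {
  if (any(v_f < 0)) stop_acr("v_f must be non-negative", class = "acr_domain_error")
  ifelse(dss > 0, 0, ifelse(v_f > 0, abs(dss) / v_f, 0))
}

#' Average crash risk (ACR) of an episode
#'
#' Per-step DSS (with the regime-dependent reaction time) and crash risk,
#' aggregated as `ACR = (1/T) * sum(CR * dt)` with `T = N * dt`, i.e. the
#' arithmetic mean of the CR samples. ACR is the per-driver aggressiveness
#' statistic, in seconds.
#'
#' @param episode A [cf_episode].
#' @param params [risk_params()].
#' @return Object of class `risk_series` with elements `dss`, `cr` (series),
#'   `acr` (scalar, s), `T` (episode duration used for normalisation, s),
#'   and `frac_dss_negative`.
#' @export
compute_acr <- function(episode, params = risk_params()) {
  stopifnot(inherits(episode, "cf_episode"))
  tau <- select_tau(episode$a_f, params)
  dss <- compute_dss(episode$v_l, episode$v_f, episode$d, tau, params)
  cr <- compute_cr(dss, episode$v_f)
  structure(list(dss = dss, cr = cr, acr = mean(cr),
                 T = length(cr) * episode$dt,
                 frac_dss_negative = mean(dss <= 0),
                 follower_id = episode$follower_id,
                 leader_id = episode$leader_id),
            class = "risk_series")
}

#' @export
print.risk_series <- function(x, ...) {
  cat(sprintf("<risk_series> follower %d: ACR = %.4f s over %.1f s (%.0f%% of steps DSS<=0)\n",
              x$follower_id, x$acr, x$T, 100 * x$frac_dss_negative))
  invisible(x)
}

#' Per-driver risk table
#'
#' Computes ACR for every episode and returns one row per episode. When a
#' follower has several episodes, `aggregate_followers = TRUE` collapses
#' them to a duration-weighted ACR per follower.
#'
#' @param episodes List of [cf_episode] objects.
#' @param params [risk_params()].
#' @param aggregate_followers Collapse multiple episodes per follower?
#' @return Data frame: `follower_id`, `leader_id`, `duration_s`, `acr`,
#'   `frac_steps_dss_negative`.
#' @export
acr_table <- function(episodes, params = risk_params(),
                      aggregate_followers = FALSE) {
  rs <- lapply(episodes, compute_acr, params = params)
  out <- data.frame(
    follower_id = vapply(rs, `[[`, integer(1), "follower_id"),
    leader_id = vapply(rs, `[[`, integer(1), "leader_id"),
    duration_s = vapply(rs, `[[`, numeric(1), "T"),
    acr = vapply(rs, `[[`, numeric(1), "acr"),
    frac_steps_dss_negative = vapply(rs, `[[`, numeric(1), "frac_dss_negative"))
  if (aggregate_followers && anyDuplicated(out$follower_id)) {
    sp <- split(out, out$follower_id)
    out <- do.call(rbind, lapply(sp, function(g) {
      w <- g$duration_s / sum(g$duration_s)
      data.frame(follower_id = g$follower_id[1],
                 leader_id = g$leader_id[which.max(g$duration_s)],
                 duration_s = sum(g$duration_s),
                 acr = sum(w * g$acr),
                 frac_steps_dss_negative = sum(w * g$frac_steps_dss_negative))
    }))
    rownames(out) <- NULL
  }
  out
}
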