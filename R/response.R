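#' Classify a tumour growth curve as responder / non-responder / intermediate
#'
#' Deterministic rule mirroring the surgical study design: a mouse is a
#' non-responder if its tumour reaches `progression_area` (default 100 mm2)
#' within `window_days` (default 28) of treatment start; a responder if the
#' tumour regresses to `regression_area` (default 0 mm2) and stays there
#' through the last measurement inside the window; anything else (growth
#' delay, partial regression) is an intermediate responder, conventionally
#' excluded from downstream analysis.
#'
#' @param curves long tibble: mouse_id, cage_id (optional), day, area_mm2.
#' @param progression_area area threshold defining progression (reached with
#'   `>=`).
#' @param window_days assessment window after treatment start, days.
#' @param regression_area area at/below which the tumour counts as regressed.
#' @return tibble: mouse_id, cage_id (if present), call.
#' @export
classify_response <- function(curves, progression_area = 100,
                              window_days = 28, regression_area = 0) {
  if (!all(c("mouse_id", "day", "area_mm2") %in% names(curves))) {
    abort("curves must have columns mouse_id, day, area_mm2")
  }
  if (nrow(curves) == 0) abort("empty growth-curve table")
  has_cage <- "cage_id" %in% names(curves)
  per_mouse <- split(curves, curves$mouse_id)
  calls <- purrr::map(per_mouse, function(d) {
    d <- d[order(d$day), , drop = FALSE]
    if (nrow(d) < 2) abort(sprintf("mouse '%s' has fewer than 2 measurements",
                                   d$mouse_id[1]))
    inwin <- d[d$day <= window_days, , drop = FALSE]
    call <- if (any(inwin$area_mm2 >= progression_area)) {
      "non_responder"
    } else {
      reg_at <- which(inwin$area_mm2 <= regression_area)
      if (length(reg_at) > 0 &&
          all(inwin$area_mm2[min(reg_at):nrow(inwin)] <= regression_area)) {
        "responder"
      } else {
        "intermediate"
      }
    }
    out <- tibble(mouse_id = d$mouse_id[1], call = call)
    if (has_cage) out$cage_id <- d$cage_id[1]
    out
  })
  out <- bind_rows(calls)
  if (has_cage) out <- out[, c("mouse_id", "cage_id", "call")]
  out
}

#' Cage dichotomy filter
#'
#' Keeps only cages that, after excluding intermediate responders, contain
#' at least one responder and at least one non-responder (the internal
#' consistency rule for the surgical experiments).
#'
#' @param calls tibble from [classify_response()] with a `cage_id` column.
#' @return character vector of kept cage ids.
#' @export
dichotomy_filter <- function(calls) {
  if (!all(c("cage_id", "call") %in% names(calls))) {
    abort("calls must have columns cage_id and call")
  }
  keep <- calls |>
    filter(.data$call != "intermediate") |>
    group_by(.data$cage_id) |>
    summarise(ok = any(.data$call == "responder") &
                any(.data$call == "non_responder"), .groups = "drop") |>
    filter(.data$ok)
  keep$cage_id
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Standard two-group log-rank test: at each distinct event time the
#' observed-minus-expected events in one group accumulate with the
#' hypergeometric variance; the statistic is chi-squared with 1 df.
#'
#' @param time_a,event_a,time_b,event_b survival times and event indicators
#'   (1 = event, 0 = censored) per group, each of length >= 2.
#' @return tibble: chi2, p.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b))
  if (length(time_a) < 2 || length(time_b) < 2) {
    abort("each group needs at least 2 subjects")
  }
  if (sum(event_a) + sum(event_b) == 0) {
    warn("no events observed; log-rank test is undefined, returning p = 1")
    return(tibble(chi2 = 0, p = 1))
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(0L, 1L), c(length(time_a), length(time_b)))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  chi2 <- unname(sd_fit$chisq)
  tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Power design specification for the log-rank simulation
#'
#' Defaults mirror the study's design: hazard ratio 5 of control relative to
#' experimental subjects, 10 animals per arm, two-sided alpha 0.05, control
#' median survival 35 days, all events observed.
#'
#' @param hazard_ratio control-vs-experimental hazard ratio.
#' @param n_per_group animals per arm.
#' @param alpha two-sided significance level.
#' @param control_median_days control median survival, days.
#' @param admin_censor_day optional administrative censoring day.
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return a `power_spec` list.
#' @export
power_spec <- function(hazard_ratio = 5, n_per_group = 10, alpha = 0.05,
                       control_median_days = 35, admin_censor_day = NULL,
                       reps = 10000, seed = 1L) {
  if (hazard_ratio <= 0) abort("hazard_ratio must be positive")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (n_per_group < 2) abort("n_per_group must be at least 2")
  structure(list(hazard_ratio = hazard_ratio, n_per_group = n_per_group,
                 alpha = alpha, control_median_days = control_median_days,
                 admin_censor_day = admin_censor_day, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "power_spec")
}

#' Monte-Carlo power of the two-group log-rank test
#'
#' Simulates `reps` experiments under the exponential survival model of
#' [simulate_survival()] and reports the fraction rejected at the two-sided
#' `alpha`, with its Monte-Carlo standard error.
#'
#' @param spec a [power_spec()].
#' @return a `power_sim` tibble: power_estimate, mc_se, reps, n_events_mean,
#'   plus the design parameters.
#' @export
simulate_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$reps < 1000) abort("use at least 1000 replicates")
  rep_seeds <- with_seed(spec$seed,
                         sample.int(.Machine$integer.max, spec$reps))
  rej <- logical(spec$reps)
  n_events <- numeric(spec$reps)
  for (i in seq_len(spec$reps)) {
    d <- simulate_survival(
      hazard_ratio = spec$hazard_ratio, n_per_group = spec$n_per_group,
      control_median_days = spec$control_median_days,
      admin_censor_day = spec$admin_censor_day, seed = rep_seeds[i]
    )
    a <- d[d$group == "control", ]
    b <- d[d$group == "experimental", ]
    lr <- logrank_test(a$time, a$event, b$time, b$event)
    rej[i] <- lr$p < spec$alpha
    n_events[i] <- sum(d$event)
  }
  p_hat <- mean(rej)
  out <- tibble(
    power_estimate = p_hat,
    mc_se = sqrt(p_hat * (1 - p_hat) / spec$reps),
    reps = spec$reps,
    n_events_mean = mean(n_events),
    hazard_ratio = spec$hazard_ratio,
    n_per_group = spec$n_per_group,
    alpha = spec$alpha
  )
  class(out) <- c("power_sim", class(out))
  out
}

#' Schoenfeld closed-form power of the log-rank test
#'
#' `Phi(sqrt(d/4) * |log(HR)| - z_{1-alpha/2})` with `d` total events --
#' the analytic companion to [simulate_power()] under 1:1 allocation.
#'
#' @param spec a [power_spec()].
#' @param total_events total observed events `d` (>= 1).
#' @return analytic power (probability).
#' @export
schoenfeld_power <- function(spec, total_events) {
  stopifnot(inherits(spec, "power_spec"), total_events >= 1)
  pnorm(sqrt(total_events / 4) * abs(log(spec$hazard_ratio)) -
          qnorm(1 - spec$alpha / 2))
}
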