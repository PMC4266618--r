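#' Treatment schedules
#'
#' Builds the scenario schedule that decides, at every solver step, whether
#' anti-angiogenic (AA) suppression is active and how the angiogenic rate is
#' scaled:
#'
#' * `"full"` -- untreated tumour; AA never active.
#' * `"aa"` -- AA active from `aa_start` onward (default step 0, emulating
#'   bevacizumab from the start of the simulation).
#' * `"treatment"` -- the full model until `aa_start` (default 2500), AA
#'   active on `[aa_start, aa_stop)` (default `[2500, 3500)`), then lifted,
#'   reproducing the clinical sequence of response followed by rebound.
#' * `"normalization"` -- full model until `aa_start`; then a transient
#'   vascular-normalization window of `boost_window` steps during which the
#'   angiogenic rate is multiplied by `boost_factor`; AA suppression from
#'   the end of the window onward.
#'
#' @param mode One of `"full"`, `"aa"`, `"treatment"`, `"normalization"`.
#' @param aa_start First step index of therapy (default 0 for `"aa"`,
#'   2500 otherwise).
#' @param aa_stop First step index after which treatment is lifted
#'   (`"treatment"` only; default 3500; use `Inf` to never lift).
#' @param boost_factor Multiplier on the angiogenic rate during the
#'   normalization window (default 2).
#' @param boost_window Length of the normalization window in steps
#'   (default 500).
#' @return A `gbm_schedule` object.
#' @examples
#' make_schedule("treatment")
#' aa_active(make_schedule("treatment"), 3000)
#' @export
make_schedule <- function(mode = c("full", "aa", "treatment", "normalization"),
                          aa_start = NULL, aa_stop = 3500,
                          boost_factor = 2, boost_window = 500) {
  mode <- match.arg(mode)
  if (is.null(aa_start)) aa_start <- if (mode == "aa") 0 else 2500
  if (mode == "treatment" && !(aa_start < aa_stop)) {
    stop("treatment schedule needs aa_start < aa_stop", call. = FALSE)
  }
  if (boost_factor < 1) stop("boost_factor must be >= 1", call. = FALSE)
  structure(
    list(mode = mode, aa_start = aa_start, aa_stop = aa_stop,
         boost_factor = boost_factor, boost_window = boost_window),
    class = "gbm_schedule"
  )
}

#' @export
print.gbm_schedule <- function(x, ...) {
  cat("<gbm_schedule> mode =", x$mode)
  if (x$mode %in% c("aa", "treatment", "normalization")) {
    cat(" | aa_start =", x$aa_start)
  }
  if (x$mode == "treatment") cat(" | aa_stop =", x$aa_stop)
  if (x$mode == "normalization") {
    cat(" | boost x", x$boost_factor, "for", x$boost_window, "steps")
  }
  cat("\n")
  invisible(x)
}

#' Therapy state at a given step
#'
#' Pure function of the schedule and the zero-based step index.  Returns
#' whether AA suppression is active and the multiplier applied to the
#' angiogenic rate when it is not (1 normally, `boost_factor` inside a
#' normalization window).
#'
#' @param schedule A `gbm_schedule`.
#' @param step_index Zero-based step index (>= 0).
#' @return A list with elements `active` (logical) and `alpha_mult`
#'   (numeric).
#' @export
aa_active <- function(schedule, step_index) {
  stopifnot(step_index >= 0)
  s <- schedule
  switch(s$mode,
    full = list(active = FALSE, alpha_mult = 1),
    aa = if (step_index >= s$aa_start) list(active = TRUE, alpha_mult = 0)
         else list(active = FALSE, alpha_mult = 1),
    treatment =
      if (step_index >= s$aa_start && step_index < s$aa_stop) {
        list(active = TRUE, alpha_mult = 0)
      } else {
        list(active = FALSE, alpha_mult = 1)
      },
    normalization =
      if (step_index < s$aa_start) {
        list(active = FALSE, alpha_mult = 1)
      } else if (step_index < s$aa_start + s$boost_window) {
        list(active = FALSE, alpha_mult = s$boost_factor)
      } else {
        list(active = TRUE, alpha_mult = 0)
      }
  )
}

#' Matched-mass calibration of one migration mechanism against the other
#'
#' The active-transport-only and passive-diffusion-only configurations are
#' compared at equal final proliferative mass.  This routine calibrates the
#' free transport coefficient (`gamma` for AT-only, `d0` for PD-only) by
#' bisection until the final-time P mass of the calibrated run matches a
#' reference mass to relative tolerance `tol`.  The final P mass is monotone
#' non-decreasing in either coefficient over the pre-saturation regime, which
#' is what makes bisection valid; the bracket is found by doubling from the
#' supplied starting value.
#'
#' @param domain A `brain_domain`.
#' @param params Base `gbm_params`; the non-calibrated transport coefficient
#'   is forced to zero according to `transport_mode`.
#' @param transport_mode `"at"` (calibrates `gamma`, sets `d0 = 0`) or
#'   `"pd"` (calibrates `d0`, sets `gamma = 0`).
#' @param reference_p_mass Final-time proliferative mass to match.
#' @param n_steps Simulation horizon used for every probe run.
#' @param schedule Treatment schedule for the probe runs.
#' @param tol Relative mass tolerance (default 0.05).
#' @param lower,upper Optional starting bracket for the coefficient; the
#'   upper end is doubled (up to `max_doublings`) until it brackets.
#' @param max_doublings Bracket-expansion limit (default 12).
#' @param max_iter Bisection iteration limit (default 40).
#' @param record_every Observable stride for probe runs.
#' @return A list: `parameter` (name), `value`, `achieved_mass`,
#'   `reference_mass`, `relative_error`, `iterations`, and `run` (the final
#'   calibrated `gbm_sim`).
#' @export
calibrate_matched_mass <- function(domain, params, transport_mode = c("at", "pd"),
                                   reference_p_mass, n_steps,
                                   schedule = make_schedule("full"),
                                   tol = 0.05, lower = NULL, upper = NULL,
                                   max_doublings = 12, max_iter = 40,
                                   record_every = 500) {
  transport_mode <- match.arg(transport_mode)
  par_name <- if (transport_mode == "at") "gamma" else "d0"
  base <- if (transport_mode == "at") {
    update_params(params, d0 = 0)
  } else {
    update_params(params, gamma = 0)
  }
  final_mass <- function(value) {
    p <- base
    p[[par_name]] <- value
    sim <- run_simulation(domain, p, schedule, n_steps,
                          record_every = record_every)
    list(mass = sim$series$P_mass[nrow(sim$series)], run = sim)
  }
  rel_err <- function(m) (m - reference_p_mass) / reference_p_mass

  if (is.null(lower)) lower <- 0
  if (is.null(upper)) upper <- if (base[[par_name]] > 0) base[[par_name]] else 1
  lo <- final_mass(lower)
  if (rel_err(lo$mass) > tol) {
    stop("calibration error: final P mass at the lower bracket (",
         format(lo$mass, digits = 5), ") already exceeds the reference (",
         format(reference_p_mass, digits = 5), ")", call. = FALSE)
  }
  hi <- final_mass(upper)
  n_dbl <- 0
  while (rel_err(hi$mass) < -tol && n_dbl < max_doublings) {
    upper <- upper * 2
    hi <- final_mass(upper)
    n_dbl <- n_dbl + 1
  }
  if (rel_err(hi$mass) < -tol) {
    stop("calibration error: could not bracket the reference mass; after ",
         max_doublings, " doublings ", par_name, " = ",
         format(upper, digits = 5), " reaches P mass ",
         format(hi$mass, digits = 5), " < reference ",
         format(reference_p_mass, digits = 5), call. = FALSE)
  }
  best <- if (abs(rel_err(hi$mass)) <= abs(rel_err(lo$mass))) {
    list(value = upper, res = hi)
  } else {
    list(value = lower, res = lo)
  }
  iter <- 0
  while (abs(rel_err(best$res$mass)) > tol && iter < max_iter) {
    mid <- (lower + upper) / 2
    res <- final_mass(mid)
    if (abs(rel_err(res$mass)) < abs(rel_err(best$res$mass))) {
      best <- list(value = mid, res = res)
    }
    if (res$mass < reference_p_mass) lower <- mid else upper <- mid
    iter <- iter + 1
  }
  if (abs(rel_err(best$res$mass)) > tol) {
    warning("matched-mass calibration stopped after ", iter,
            " bisections at relative error ",
            format(rel_err(best$res$mass), digits = 3), call. = FALSE)
  }
  list(parameter = par_name, value = best$value,
       achieved_mass = best$res$mass, reference_mass = reference_p_mass,
       relative_error = rel_err(best$res$mass),
       iterations = iter, run = best$res$run)
}
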