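#' Total cell density
#'
#' The total number of cells per unit area, the sum of the proliferative,
#' invasive, healthy-brain and necrotic densities.  The local hypoxic state
#' is a function of this total: oxygen/nutrient availability is assumed
#' inversely related to how crowded the tissue is, dead cells included.
#'
#' @param state A `tissue_state` (see [seed_tumor()]).
#' @return A matrix, `P + I + B + N` elementwise.
#' @export
total_density <- function(state) {
  stopifnot(inherits(state, "tissue_state"))
  if (!same_shape(state$P, state$I, state$B, state$N)) {
    stop("tissue_state fields disagree in shape", call. = FALSE)
  }
  state$P + state$I + state$B + state$N
}

#' Local hypoxic state
#'
#' `H = clamp(C / c_ref, 0, 1)`: zero in empty tissue, saturating at 1 once
#' the total density reaches the reference density `c_ref`.  Monotone
#' non-decreasing in `C`.
#'
#' @param C Total-density matrix (from [total_density()]).
#' @param params A `gbm_params` object.
#' @return Matrix of hypoxic states in `[0, 1]`.
#' @export
hypoxic_state <- function(C, params) {
  if (params$c_ref <= 0) stop("`c_ref` must be > 0", call. = FALSE)
  if (any(C < 0)) stop("total density must be >= 0", call. = FALSE)
  clamp01(C / params$c_ref)
}

#' Mitotic coefficient
#'
#' Proliferative cells divide at their maximal rate `m_max` while the tissue
#' is normoxic (`H <= tau_h`).  Beyond the hypoxic threshold the rate decays
#' linearly; under the default `"saturating"` form it vanishes only at
#' maximal hypoxia (H = 1), so growth continues -- slowed -- past the lethal
#' threshold, which is what lets crowded tissue overshoot `tau_l` and die.
#' The `"banded"` form instead vanishes already at `tau_l`.
#' Both forms are continuous in H.
#'
#' @param H Hypoxic-state matrix.
#' @param tau_h,tau_l Threshold matrices (spatial fields).
#' @param params A `gbm_params` object.
#' @return Matrix of mitotic rates in `[0, m_max]`.
#' @export
mitotic_coefficient <- function(H, tau_h, tau_l, params) {
  if (any(tau_h >= tau_l)) {
    stop("threshold ordering violated: tau_h must be < tau_l everywhere",
         call. = FALSE)
  }
  upper <- switch(params$mitosis_form,
    saturating = 1,
    banded = tau_l
  )
  params$m_max * clamp01((upper - H) / (upper - tau_h))
}

#' Necrotic rate
#'
#' Zero while `H < tau_l`; above the lethal threshold cells of all living
#' types die.  The default `"steep"` form ramps up to `mu_max` over a narrow
#' band of width `lethal_width` above `tau_l` (rapid necrosis once the
#' lethal threshold is crossed); the `"gradual"` form ramps linearly up to
#' `mu_max` at H = 1.  Continuous and monotone non-decreasing in H either
#' way, and equal to `mu_max` at H = 1.
#'
#' @inheritParams mitotic_coefficient
#' @return Matrix of death rates in `[0, mu_max]`.
#' @export
necrotic_rate <- function(H, tau_l, params) {
  width <- switch(params$death_form,
    steep = pmin(params$lethal_width, 1 - tau_l + 1e-12),
    gradual = 1 - tau_l
  )
  params$mu_max * clamp01((H - tau_l) / width)
}

#' Proliferative-to-invasive switch rate
#'
#' No switching in normoxic tissue (`H <= tau_h`); above the hypoxic
#' threshold the rate ramps linearly, reaching `beta_pi` at maximal hypoxia.
#'
#' @inheritParams mitotic_coefficient
#' @return Matrix of switch rates in `[0, beta_pi]`.
#' @export
switch_rate_pi <- function(H, tau_h, params) {
  params$beta_pi * clamp01((H - tau_h) / (1 - tau_h))
}

#' Invasive-to-proliferative switch rate
#'
#' Elevated when hypoxia is low: equal to `beta_ip` for `H <= tau_h`,
#' decaying linearly to zero at the lethal threshold.  Invasive cells that
#' reach fresh, uncrowded brain revert to the proliferative phenotype.
#'
#' @inheritParams mitotic_coefficient
#' @return Matrix of switch rates in `[0, beta_ip]`.
#' @export
switch_rate_ip <- function(H, tau_h, tau_l, params) {
  params$beta_ip * clamp01((tau_l - H) / (tau_l - tau_h))
}

#' Advance the angiogenic threshold fields by one step
#'
#' Without therapy, angiogenesis driven by the local proliferative density
#' raises both thresholds towards their caps:
#' `d tau/dt = alpha * P * (cap - tau)` (explicit Euler).  While
#' anti-angiogenic therapy is active the angiogenic term is suppressed and
#' the thresholds relax back towards `(tau_h0, tau_l0)` at `relax_rate`
#' (`Inf` resets them in a single call).
#'
#' @param state A `tissue_state`.
#' @param params A `gbm_params` object.
#' @param aa_active Logical flag: is anti-angiogenic suppression active?
#' @param dt Time step (defaults to `params$dt`).
#' @param alpha_mult Multiplier on the angiogenic rate (used by the
#'   vascular-normalization protocol); ignored while `aa_active` is `TRUE`.
#' @return The state with updated `tau_h`, `tau_l`.
#' @export
update_thresholds <- function(state, params, aa_active, dt = params$dt,
                              alpha_mult = 1) {
  stopifnot(dt > 0)
  if (aa_active) {
    r <- params$relax_rate
    if (is.infinite(r)) {
      state$tau_h[] <- params$tau_h0
      state$tau_l[] <- params$tau_l0
    } else {
      f <- min(r * dt, 1)  # do not overshoot the baseline
      state$tau_h <- state$tau_h + f * (params$tau_h0 - state$tau_h)
      state$tau_l <- state$tau_l + f * (params$tau_l0 - state$tau_l)
    }
  } else {
    a <- params$alpha * alpha_mult * dt * state$P
    state$tau_h <- state$tau_h + a * (params$tau_h_cap - state$tau_h)
    state$tau_l <- state$tau_l + a * (params$tau_l_cap - state$tau_l)
  }
  state
}

#' One explicit-Euler step of the local (per-cell) kinetics
#'
#' Applies mitosis, phenotype switching and death from the pre-step state.
#' Switching and death conserve total density exactly (dying P, I and B
#' cells are collected into N with weight 1); mitosis is the sole source
#' term.  Per-cell outflows are capped at the available density so no field
#' goes negative; a cap event means `dt` is too coarse for the configured
#' rates and is reported via a warning.
#'
#' @param state A `tissue_state`.
#' @param params A `gbm_params` object.
#' @param dt Time step (defaults to `params$dt`).
#' @return The updated `tissue_state` (time advanced by `dt`).
#' @export
reaction_step <- function(state, params, dt = params$dt) {
  C <- total_density(state)
  H <- hypoxic_state(C, params)
  M <- mitotic_coefficient(H, state$tau_h, state$tau_l, params)
  mu <- necrotic_rate(H, state$tau_l, params)
  s_pi <- switch_rate_pi(H, state$tau_h, params)
  s_ip <- switch_rate_ip(H, state$tau_h, state$tau_l, params)

  # fractional outflows this step, capped at the available density
  out_p <- (s_pi + mu) * dt
  out_i <- (s_ip + mu) * dt
  out_b <- mu * dt
  capped <- any(out_p > 1) || any(out_i > 1) || any(out_b > 1)
  if (capped) {
    warning("reaction outflow exceeded available density in ",
            sum(out_p > 1 | out_i > 1 | out_b > 1),
            " cell(s); outflows capped -- consider a smaller dt",
            call. = FALSE)
  }
  scale_p <- ifelse(out_p > 1, 1 / out_p, 1)
  scale_i <- ifelse(out_i > 1, 1 / out_i, 1)
  out_b <- pmin(out_b, 1)

  p_to_i <- s_pi * dt * scale_p * state$P
  p_dead <- mu * dt * scale_p * state$P
  i_to_p <- s_ip * dt * scale_i * state$I
  i_dead <- mu * dt * scale_i * state$I
  b_dead <- out_b * state$B

  state$P <- state$P + M * state$P * dt - p_to_i - p_dead + i_to_p
  state$I <- state$I + p_to_i - i_to_p - i_dead
  state$B <- state$B - b_dead
  state$N <- state$N + p_dead + i_dead + b_dead
  state$t <- state$t + dt
  state
}
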