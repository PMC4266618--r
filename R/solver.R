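#' Necrotic region of a tissue state
#'
#' Cells where at least `necrosis_cutoff` (default 90%) of the initial
#' healthy-brain density has died.  The necrotic region excludes transport:
#' invasive cells neither diffuse nor advect across faces into it, so they
#' never move back into the dead centre of the tumour.
#'
#' @param state A `tissue_state`.
#' @param domain A `brain_domain`.
#' @param params A `gbm_params` object.
#' @return Logical matrix.
#' @export
necrotic_region <- function(state, domain, params) {
  dead <- domain$b_init - state$B
  domain$mask & (dead >= params$necrosis_cutoff * domain$b_init)
}

#' Spatial diffusion coefficient of invasive cells
#'
#' `D = d0 * (1 + wm * (kappa_wm - 1))` inside the brain: base rate `d0` in
#' pure grey matter rising to `kappa_wm * d0` along white-matter tracks.
#' Zero outside the mask and inside the necrotic region.
#'
#' @inheritParams necrotic_region
#' @return Matrix of diffusion coefficients (length^2 / time).
#' @export
diffusion_field <- function(domain, state, params) {
  D <- params$d0 * (1 + domain$wm * (params$kappa_wm - 1))
  D[!domain$mask] <- 0
  D[necrotic_region(state, domain, params)] <- 0
  D
}

# face openness: both adjacent cells inside the mask and non-necrotic
open_cells <- function(state, domain, params) {
  domain$mask & !necrotic_region(state, domain, params)
}

#' One conservative passive-diffusion step
#'
#' Flux-form 5-point update of `dI/dt = div(D grad I)` with zero flux across
#' the mask boundary and across any face into a necrotic cell.  Total
#' invasive mass is conserved to round-off and the field stays
#' non-negative under the stability bound.
#'
#' @param I Invasive-density matrix.
#' @param D Diffusion-coefficient matrix (see [diffusion_field()]).
#' @param domain A `brain_domain`.
#' @param dt Time step.
#' @param open Optional logical matrix of transport-open cells; computed
#'   from `D > 0` if omitted.
#' @return Updated invasive-density matrix.
#' @export
passive_diffusion_step <- function(I, D, domain, dt, open = NULL) {
  h <- domain$h
  d_max <- max(D)
  if (d_max > 0 && dt * 4 * d_max / h^2 > 1) {
    stop("diffusion CFL violated: dt * 4 * D_max / h^2 = ",
         format(dt * 4 * d_max / h^2, digits = 4),
         " > 1; reduce dt (see stable_dt())", call. = FALSE)
  }
  if (is.null(open)) open <- domain$mask & (D > 0)
  flux_from <- function(Dn, In, on) {
    f <- 0.5 * (D + Dn) * (In - I) * dt / h^2
    f[!(open & on)] <- 0
    f
  }
  # each f is the net pairwise exchange with one neighbour (antisymmetric
  # across the face), so summing a cell's four faces conserves mass exactly
  fU <- flux_from(shift_up(D), shift_up(I), shift_up(open))
  fD <- flux_from(shift_down(D), shift_down(I), shift_down(open))
  fL <- flux_from(shift_left(D), shift_left(I), shift_left(open))
  fR <- flux_from(shift_right(D), shift_right(I), shift_right(open))
  I + fU + fD + fL + fR
}

#' One conservative upwind active-transport step
#'
#' First-order upwind advection of invasive cells with face velocity
#' `v = gamma * grad(B)`, i.e. bulk migration toward higher healthy-brain
#' density.  Where `grad(B) = 0` (uniform healthy brain) nothing moves.
#' Fluxes vanish across the mask boundary and across faces into necrotic
#' cells; per-cell outflow is capped at the available density so the update
#' is conservative and non-negative even on degenerate geometries.
#'
#' @param I Invasive-density matrix.
#' @param B Healthy-brain density matrix.
#' @param domain A `brain_domain`.
#' @param params A `gbm_params` object.
#' @param dt Time step.
#' @param open Optional logical matrix of transport-open cells.
#' @return Updated invasive-density matrix.
#' @export
active_transport_step <- function(I, B, domain, params, dt, open = NULL) {
  g <- params$gamma
  if (g == 0) return(I)
  h <- domain$h
  if (is.null(open)) {
    # without a state we cannot see necrosis; default to the mask only
    open <- domain$mask
  }
  grad_max <- max(abs(diff(B)), abs(t(diff(t(B))))) / h
  if (grad_max > 0 && g * grad_max * dt / h > 1) {
    stop("advection CFL violated: gamma * |grad B|_max * dt / h = ",
         format(g * grad_max * dt / h, digits = 4),
         " > 1; reduce dt (see stable_dt())", call. = FALSE)
  }
  # signed upwind flux across each face; positive = leaving this cell.
  # The donor convention makes the face flux antisymmetric between the two
  # adjacent cells, so subtracting a cell's four face fluxes is conservative.
  flux_to <- function(Bn, In, on) {
    v <- g * (Bn - B) / h
    f <- ifelse(v > 0, v * I, v * In) * dt / h
    f[!(open & on)] <- 0
    f
  }
  fU <- flux_to(shift_up(B), shift_up(I), shift_up(open))
  fD <- flux_to(shift_down(B), shift_down(I), shift_down(open))
  fL <- flux_to(shift_left(B), shift_left(I), shift_left(open))
  fR <- flux_to(shift_right(B), shift_right(I), shift_right(open))
  # cap each cell's total outflow at its density (keeps I >= 0 and mass
  # exactly conserved); the scale applies to the donor side of every face
  out_total <- pmax(fU, 0) + pmax(fD, 0) + pmax(fL, 0) + pmax(fR, 0)
  scale <- ifelse(out_total > I & out_total > 0, I / out_total, 1)
  eff <- function(f, scale_n) ifelse(f > 0, f * scale, f * scale_n)
  fU <- eff(fU, shift_up(scale)); fD <- eff(fD, shift_down(scale))
  fL <- eff(fL, shift_left(scale)); fR <- eff(fR, shift_right(scale))
  I - (fU + fD + fL + fR)
}

#' Stable time step for the transport operators
#'
#' `0.9 * min(h^2 / (4 D_max), h / (gamma |grad B|_max + eps))`, capped at
#' the configured `dt` (which is also returned when both transport terms
#' vanish).
#'
#' @param params A `gbm_params` object.
#' @param d_max Maximal diffusion coefficient on the grid.
#' @param grad_b_max Maximal healthy-brain gradient magnitude.
#' @param h Cell edge length.
#' @param safety Safety factor (default 0.9).
#' @return A time step.
#' @export
stable_dt <- function(params, d_max, grad_b_max, h, safety = 0.9) {
  stopifnot(h > 0)
  bounds <- c()
  if (d_max > 0) bounds <- c(bounds, h^2 / (4 * d_max))
  adv <- params$gamma * grad_b_max
  if (adv > 0) bounds <- c(bounds, h / adv)
  if (length(bounds) == 0) return(params$dt)
  min(safety * min(bounds), params$dt)
}

#' One full solver step
#'
#' Operator-split update in fixed order: local kinetics
#' ([reaction_step()]), threshold dynamics ([update_thresholds()], with the
#' anti-angiogenic flag and angiogenic multiplier taken from the schedule),
#' then active transport and passive diffusion of invasive cells.
#'
#' @param state A `tissue_state`.
#' @param domain A `brain_domain`.
#' @param params A `gbm_params` object.
#' @param schedule A `gbm_schedule` (see [make_schedule()]).
#' @param step_index Zero-based index of this step.
#' @return The advanced `tissue_state`.
#' @export
simulate_step <- function(state, domain, params, schedule = make_schedule("full"),
                          step_index = 0) {
  dt <- params$dt
  aa <- aa_active(schedule, step_index)
  seed <- attr(state, "seed")
  state <- reaction_step(state, params, dt)
  state <- update_thresholds(state, params, aa_active = aa$active, dt = dt,
                             alpha_mult = aa$alpha_mult)
  open <- open_cells(state, domain, params)
  if (params$gamma > 0) {
    state$I <- active_transport_step(state$I, state$B, domain, params, dt,
                                     open = open)
  }
  if (params$d0 > 0) {
    D <- params$d0 * (1 + domain$wm * (params$kappa_wm - 1))
    D[!open] <- 0
    state$I <- passive_diffusion_step(state$I, D, domain, dt, open = open)
  }
  attr(state, "seed") <- seed
  state
}

#' Run a full simulation
#'
#' Seeds a tumour into the domain and advances the solver `n_steps` steps
#' under the given treatment schedule, recording the standard observables
#' (proliferative and invasive mass, percent necrosis, invasion and
#' proliferation) at step 0 and every `record_every` steps.  The dynamics
#' contain no randomness: identical inputs give bit-identical results.
#'
#' @param domain A `brain_domain`.
#' @param params A `gbm_params` object.
#' @param schedule A `gbm_schedule`.
#' @param n_steps Number of solver steps (>= 0).
#' @param record_every Observable sampling stride (default 50).
#' @param snapshot_steps Integer vector of step indices at which to keep a
#'   full copy of the state (the final state is always kept).
#' @param location Seed location passed to [seed_tumor()].
#' @return A `gbm_sim` object: `series` (a tibble of observables over
#'   time), `final` (the last `tissue_state`), `snapshots`, plus the
#'   domain, parameters and schedule used.
#' @examples
#' dom <- synthetic_brain(c(48, 48), seed = 1)
#' sim <- run_simulation(dom, gbm_params(), make_schedule("full"),
#'                       n_steps = 20, record_every = 10)
#' sim$series
#' @export
run_simulation <- function(domain, params = gbm_params(),
                           schedule = make_schedule("full"),
                           n_steps, record_every = 50,
                           snapshot_steps = integer(), location = NULL) {
  stopifnot(n_steps >= 0)
  state <- seed_tumor(domain, params, location)
  h2 <- domain$h^2
  n_mask <- sum(domain$mask)
  rec <- function(state, step) {
    necro <- necrotic_region(state, domain, params)
    tibble::tibble(
      step = step,
      t = state$t,
      P_mass = sum(state$P) * h2,
      I_mass = sum(state$I) * h2,
      pct_necrosis = 100 * sum(necro) / n_mask,
      pct_invasion = 100 * sum(state$I >= params$invasion_cutoff &
                                 domain$mask) / n_mask,
      pct_proliferation = 100 * sum(state$P >= params$invasion_cutoff &
                                      domain$mask) / n_mask
    )
  }
  rows <- vector("list", n_steps %/% record_every + 2L)
  rows[[1]] <- rec(state, 0L)
  ri <- 1L
  snapshots <- list()
  for (s in seq_len(n_steps)) {
    state <- simulate_step(state, domain, params, schedule, step_index = s - 1L)
    if (s %% record_every == 0 || s == n_steps) {
      ri <- ri + 1L
      rows[[ri]] <- rec(state, s)
    }
    if (s %in% snapshot_steps) snapshots[[as.character(s)]] <- state
  }
  series <- dplyr::distinct(dplyr::bind_rows(rows[seq_len(ri)]))
  structure(
    list(series = series, final = state, snapshots = snapshots,
         domain = domain, params = params, schedule = schedule,
         n_steps = n_steps),
    class = "gbm_sim"
  )
}

#' @export
print.gbm_sim <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat("<gbm_sim> ", x$n_steps, " steps (", x$schedule$mode, " protocol) on ",
      x$domain$shape[1], "x", x$domain$shape[2], " brain\n", sep = "")
  cat("  final: P mass ", format(last$P_mass, digits = 4),
      " | I mass ", format(last$I_mass, digits = 4),
      " | necrosis ", format(last$pct_necrosis, digits = 3),
      "% | invasion ", format(last$pct_invasion, digits = 3), "%\n", sep = "")
  invisible(x)
}
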