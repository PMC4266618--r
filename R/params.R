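#' Model parameters for the go-or-grow glioblastoma simulator
#'
#' Collects every kinetic, transport, angiogenesis and numerical constant of
#' the model into a validated list.  All densities are expressed per carrying
#' capacity (`c_ref`), lengths in grid-cell edges and time in arbitrary model
#' units; one solver step advances time by `dt`.
#'
#' The defaults place the simulator in the regime where the classical
#' multilayer structure (necrotic core, proliferative rim, invasive margin)
#' develops on a 127 x 127 brain within a few thousand steps; see the
#' methods vignette for the reasoning behind each value.
#'
#' @param m_max Maximal mitotic rate of proliferative cells (per time unit).
#' @param mu_max Maximal death rate once the hypoxic state exceeds the lethal
#'   threshold (per time unit); applied identically to P, I and B cells.
#' @param beta_pi Maximal switch rate from proliferative to invasive
#'   phenotype.  Must stay below `m_max` for a seeded tumour to densify
#'   faster than it drains (see vignette).
#' @param beta_ip Maximal switch rate from invasive back to proliferative
#'   phenotype in normoxic tissue.
#' @param d0 Base passive-diffusion coefficient of invasive cells in grey
#'   matter (length^2 / time).
#' @param kappa_wm White-matter diffusion multiplier: diffusion in a pure
#'   white-matter cell is `kappa_wm * d0`.
#' @param gamma Active-transport coefficient: invasive cells advect with
#'   velocity `gamma * grad(B)` towards higher healthy-brain density.
#' @param alpha Angiogenic rate; local thresholds rise as
#'   `d tau/dt = alpha * P * (cap - tau)`.
#' @param tau_h0,tau_l0 Initial hypoxic and lethal thresholds of the local
#'   hypoxic state H.
#' @param tau_h_cap,tau_l_cap Ceilings the thresholds approach under
#'   angiogenesis.
#' @param c_ref Total cell density at which the hypoxic state saturates at 1.
#' @param b0 Initial healthy-brain density inside the mask.
#' @param lethal_width Width of the band above `tau_l` over which the death
#'   rate ramps from 0 up to `mu_max` ("rapid necrosis"); only used by the
#'   default `"steep"` death form.
#' @param mitosis_form `"saturating"` (default): mitosis at `m_max` below
#'   `tau_h`, then a linear ramp that vanishes at H = 1.  `"banded"`: the
#'   ramp instead vanishes already at `tau_l`.
#' @param death_form `"steep"` (default): ramp from 0 at `tau_l` to `mu_max`
#'   at `tau_l + lethal_width`.  `"gradual"`: ramp from 0 at `tau_l` to
#'   `mu_max` at H = 1.
#' @param necrosis_cutoff Fraction of the initial brain density that must
#'   have died for a cell to count as necrotic (default 0.90).
#' @param invasion_cutoff Invasive-cell density at or above which a cell
#'   counts as invaded (default 1e-4).
#' @param p_enh Proliferative density at or above which a cell is labelled
#'   "enhancing rim" in the virtual-MRI map (default `0.1 * c_ref`).
#' @param p_seed,i_seed Densities seeded into the single initial tumour cell.
#' @param dt Solver time step.
#' @param relax_rate Rate at which thresholds relax back towards
#'   `(tau_h0, tau_l0)` while anti-angiogenic therapy is active; `Inf`
#'   (default) resets them instantly.
#'
#' @return An object of class `gbm_params` (a named list).
#' @examples
#' p <- gbm_params()
#' p$m_max
#' gbm_params(gamma = 0)$gamma   # passive-diffusion-only variant
#' @export
gbm_params <- function(m_max = 0.1,
                       mu_max = 2,
                       beta_pi = 0.05,
                       beta_ip = 0.15,
                       d0 = 0.02,
                       kappa_wm = 5,
                       gamma = 4,
                       alpha = 1,
                       tau_h0 = 0.7,
                       tau_l0 = 0.85,
                       tau_h_cap = 0.9,
                       tau_l_cap = 0.97,
                       c_ref = 1,
                       b0 = 0.5,
                       lethal_width = 0.02,
                       mitosis_form = c("saturating", "banded"),
                       death_form = c("steep", "gradual"),
                       necrosis_cutoff = 0.9,
                       invasion_cutoff = 1e-4,
                       p_enh = 0.1,
                       p_seed = 1e-2,
                       i_seed = 1e-3,
                       dt = 0.1,
                       relax_rate = Inf) {
  p <- list(
    m_max = m_max, mu_max = mu_max,
    beta_pi = beta_pi, beta_ip = beta_ip,
    d0 = d0, kappa_wm = kappa_wm, gamma = gamma, alpha = alpha,
    tau_h0 = tau_h0, tau_l0 = tau_l0,
    tau_h_cap = tau_h_cap, tau_l_cap = tau_l_cap,
    c_ref = c_ref, b0 = b0,
    lethal_width = lethal_width,
    mitosis_form = match.arg(mitosis_form),
    death_form = match.arg(death_form),
    necrosis_cutoff = necrosis_cutoff,
    invasion_cutoff = invasion_cutoff,
    p_enh = p_enh,
    p_seed = p_seed, i_seed = i_seed,
    dt = dt, relax_rate = relax_rate
  )
  class(p) <- "gbm_params"
  validate_params(p)
  p
}

#' Validate a parameter set against the model invariants
#'
#' @param p A `gbm_params` object (or plain named list with the same fields).
#' @return `p`, invisibly, if valid; otherwise an error describing the first
#'   violated invariant.
#' @export
validate_params <- function(p) {
  num_fields <- c("m_max", "mu_max", "beta_pi", "beta_ip", "d0", "kappa_wm",
                  "gamma", "alpha", "tau_h0", "tau_l0", "tau_h_cap",
                  "tau_l_cap", "c_ref", "b0", "lethal_width",
                  "necrosis_cutoff", "invasion_cutoff", "p_enh",
                  "p_seed", "i_seed", "dt", "relax_rate")
  for (f in num_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("parameter `", f, "` must be a single finite-or-Inf number",
           call. = FALSE)
    }
  }
  rates <- c("m_max", "mu_max", "beta_pi", "beta_ip", "d0", "gamma", "alpha",
             "relax_rate")
  for (f in rates) {
    if (p[[f]] < 0) stop("rate `", f, "` must be >= 0", call. = FALSE)
  }
  if (p$c_ref <= 0) stop("`c_ref` must be > 0", call. = FALSE)
  if (p$dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (!(p$tau_h0 > 0)) stop("`tau_h0` must be > 0", call. = FALSE)
  if (!(p$tau_h0 < p$tau_l0)) {
    stop("threshold ordering violated: need tau_h0 < tau_l0", call. = FALSE)
  }
  if (!(p$tau_l0 <= p$tau_l_cap)) {
    stop("`tau_l_cap` must be >= tau_l0 (caps cannot sit below the initial ",
         "thresholds)", call. = FALSE)
  }
  if (!(p$tau_l_cap <= 1)) stop("`tau_l_cap` must be <= 1", call. = FALSE)
  if (!(p$tau_h_cap < p$tau_l_cap)) {
    stop("need tau_h_cap < tau_l_cap", call. = FALSE)
  }
  if (!(p$tau_h_cap >= p$tau_h0)) {
    stop("`tau_h_cap` must be >= tau_h0 (caps cannot sit below the initial ",
         "thresholds)", call. = FALSE)
  }
  if (!(p$b0 / p$c_ref < p$tau_h0)) {
    stop("healthy tissue must start normoxic: H(b0) = b0/c_ref must be ",
         "< tau_h0", call. = FALSE)
  }
  if (p$kappa_wm < 1) stop("`kappa_wm` must be >= 1", call. = FALSE)
  if (p$lethal_width <= 0) stop("`lethal_width` must be > 0", call. = FALSE)
  if (p$necrosis_cutoff <= 0 || p$necrosis_cutoff > 1) {
    stop("`necrosis_cutoff` must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.gbm_params <- function(x, ...) {
  cat("<gbm_params>\n")
  num <- vapply(x, is.numeric, logical(1))
  vals <- unlist(x[num])
  cat(paste0("  ", format(names(vals)), " = ", format(vals, digits = 4),
             collapse = "\n"), "\n")
  cat("  mitosis_form =", x$mitosis_form, "| death_form =", x$death_form, "\n")
  invisible(x)
}

#' Modify a parameter set
#'
#' Convenience wrapper that replaces named fields and re-validates, so
#' variant runs (e.g. a passive-diffusion-only configuration) can be derived
#' from a base set in pipelines.
#'
#' @param p A `gbm_params` object.
#' @param ... Named fields to replace.
#' @return A validated `gbm_params` object.
#' @examples
#' at_only <- update_params(gbm_params(), d0 = 0)
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "gbm_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(repl)] <- repl
  validate_params(p)
  p
}
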