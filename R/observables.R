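#' Mass of a density field
#'
#' Sum of the field over the brain mask times the cell area `h^2`.
#'
#' @param field Density matrix (>= 0).
#' @param domain A `brain_domain`.
#' @return A single number.
#' @export
field_mass <- function(field, domain) {
  stopifnot(all(dim(field) == domain$shape))
  sum(field[domain$mask]) * domain$h^2
}

#' Percent of the brain that is necrotic
#'
#' Share of mask cells in which at least `necrosis_cutoff` (default 90%) of
#' the initial brain density has died; a cell exactly at the cutoff counts
#' as necrotic.
#'
#' @param state A `tissue_state`.
#' @param domain A `brain_domain`.
#' @param params A `gbm_params` object.
#' @return Percentage in `[0, 100]`.
#' @export
percent_necrosis <- function(state, domain, params) {
  100 * sum(necrotic_region(state, domain, params)) / sum(domain$mask)
}

#' Percent of the brain invaded by tumour cells
#'
#' Share of mask cells whose invasive-cell density is at least
#' `invasion_cutoff` (default 1e-4).  The denominator is the whole brain
#' mask, necrotic cells included.
#'
#' @inheritParams percent_necrosis
#' @return Percentage in `[0, 100]`.
#' @export
percent_invasion <- function(state, domain, params) {
  100 * sum(state$I >= params$invasion_cutoff & domain$mask) /
    sum(domain$mask)
}

#' Percent of the brain occupied by proliferative cells
#'
#' Same construction as [percent_invasion()] but for the proliferative
#' field (used by the sensitivity sweeps).
#'
#' @inheritParams percent_necrosis
#' @return Percentage in `[0, 100]`.
#' @export
percent_proliferation <- function(state, domain, params) {
  100 * sum(state$P >= params$invasion_cutoff & domain$mask) /
    sum(domain$mask)
}

#' One-dimensional cross-section of the cell-type fields
#'
#' Density profiles of P, I, B and N along a grid row or column, in long
#' (tidy) form for direct plotting.
#'
#' @param state A `tissue_state`.
#' @param axis `"row"` (profile along a fixed row) or `"col"`.
#' @param index Row or column index of the section.
#' @return A tibble with columns `position`, `field`, `density`.
#' @export
cross_section <- function(state, axis = c("row", "col"), index) {
  axis <- match.arg(axis)
  pick <- function(m) if (axis == "row") m[index, ] else m[, index]
  n <- length(pick(state$P))
  tidyr::pivot_longer(
    tibble::tibble(position = seq_len(n),
                   P = pick(state$P), I = pick(state$I),
                   B = pick(state$B), N = pick(state$N)),
    cols = c("P", "I", "B", "N"),
    names_to = "field", values_to = "density"
  )
}

#' Radii of the multilayer tumour structure
#'
#' Characterises the classical concentric organisation -- necrotic core,
#' proliferative rim, invasive margin -- by three radii measured from the
#' seed (or a supplied centre): the maximal radius of any necrotic cell,
#' and the radii at which the azimuthally averaged P and I densities peak.
#' A developed tumour satisfies
#' `r_necrosis < r_P_peak < r_I_peak`.
#'
#' @param state A `tissue_state`.
#' @param domain A `brain_domain`.
#' @param params A `gbm_params` object.
#' @param center `c(row, col)`; defaults to the seed stored in the state.
#' @return A list with `r_necrosis`, `r_P_peak`, `r_I_peak` (in length
#'   units).
#' @export
layer_radii <- function(state, domain, params, center = NULL) {
  if (sum(state$P) <= 0) {
    stop("undefined structure: no proliferative tumour present",
         call. = FALSE)
  }
  if (is.null(center)) center <- attr(state, "seed")
  if (is.null(center)) stop("no seed stored in state; supply `center`",
                            call. = FALSE)
  nr <- nrow(state$P); nc <- ncol(state$P)
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r <- sqrt((row - center[1])^2 + (col - center[2])^2) * domain$h
  necro <- necrotic_region(state, domain, params)
  r_nec <- if (any(necro)) max(r[necro]) else 0
  ring <- round(r / (domain$h / 2))  # half-cell annuli resolve the rim order
  peak_radius <- function(field) {
    avg <- tapply(field[domain$mask], ring[domain$mask], mean)
    as.numeric(names(avg)[which.max(avg)]) * domain$h / 2
  }
  list(r_necrosis = r_nec,
       r_P_peak = peak_radius(state$P),
       r_I_peak = peak_radius(state$I))
}

#' Virtual-MRI label map
#'
#' Classifies every brain cell into the radiological compartments a
#' clinical MRI would show: `necrotic_core` where brain death reaches the
#' necrosis cutoff, `enhancing_rim` where the proliferative density is at
#' least `p_enh` (the contrast-enhancing mass), `flair_margin` where the
#' invasive density reaches the invasion cutoff without qualifying as rim
#' or core (the nonenhancing FLAIR abnormality), and `normal` otherwise.
#' Labels are mutually exclusive and exhaustive on the mask; cells outside
#' the mask are labelled `outside`.
#'
#' @inheritParams percent_necrosis
#' @return A character matrix of labels.
#' @export
virtual_mri <- function(state, domain, params) {
  lab <- matrix("outside", nrow(state$P), ncol(state$P))
  lab[domain$mask] <- "normal"
  core <- necrotic_region(state, domain, params)
  rim <- domain$mask & !core & state$P >= params$p_enh * params$c_ref
  margin <- domain$mask & !core & !rim &
    state$I >= params$invasion_cutoff
  lab[margin] <- "flair_margin"
  lab[rim] <- "enhancing_rim"
  lab[core] <- "necrotic_core"
  lab
}
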