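#' Parameter-pair sensitivity sweep
#'
#' Runs the simulator over a grid of values for a pair of model parameters
#' and records the sweep metrics -- Percent Proliferation, Percent Necrosis
#' and Percent Invasion -- at a fixed horizon.  Rows are deterministic;
#' a run that fails is kept with `error = TRUE` rather than dropped.
#'
#' @param domain A `brain_domain`.
#' @param base_params Base `gbm_params`; each grid point replaces the two
#'   swept fields.
#' @param pair Character vector of two `gbm_params` field names, e.g.
#'   `c("gamma", "d0")`.
#' @param grids List of two numeric vectors of values (crossed).  Defaults
#'   to `x0.25, x1, x4` of each base value (a zero base value sweeps
#'   `0, 0.5, 1`).
#' @param horizon_steps Steps per run (default 3000).
#' @param schedule Treatment schedule (default full model).
#' @param record_every Observable stride for the runs.
#' @return A tibble with one row per grid point: the two parameter values,
#'   `pct_proliferation`, `pct_necrosis`, `pct_invasion`, `P_mass`,
#'   `I_mass`, and `error`.
#' @export
parameter_sweep <- function(domain, base_params, pair,
                            grids = NULL, horizon_steps = 3000,
                            schedule = make_schedule("full"),
                            record_every = 1000) {
  stopifnot(length(pair) == 2)
  valid <- names(base_params)[vapply(base_params, is.numeric, logical(1))]
  bad <- setdiff(pair, valid)
  if (length(bad) > 0) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(grids)) {
    grids <- lapply(pair, function(nm) {
      v <- base_params[[nm]]
      if (v > 0) v * c(0.25, 1, 4) else c(0, 0.5, 1)
    })
  }
  stopifnot(length(grids) == 2, all(lengths(grids) >= 1))
  pts <- tidyr::expand_grid(a = grids[[1]], b = grids[[2]])
  names(pts) <- pair
  res <- purrr::pmap(pts, function(...) {
    vals <- list(...)
    out <- tryCatch({
      p <- do.call(update_params, c(list(base_params), vals))
      sim <- run_simulation(domain, p, schedule, horizon_steps,
                            record_every = record_every)
      last <- sim$series[nrow(sim$series), ]
      tibble::tibble(
        pct_proliferation = last$pct_proliferation,
        pct_necrosis = last$pct_necrosis,
        pct_invasion = last$pct_invasion,
        P_mass = last$P_mass, I_mass = last$I_mass,
        error = FALSE, message = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(
        pct_proliferation = NA_real_, pct_necrosis = NA_real_,
        pct_invasion = NA_real_, P_mass = NA_real_, I_mass = NA_real_,
        error = TRUE, message = conditionMessage(e)
      )
    })
    out
  })
  dplyr::bind_cols(pts, dplyr::bind_rows(res))
}

#' Rank correlation between necrosis and invasion across a sweep
#'
#' Spearman correlation (ties mid-ranked) between the Percent Necrosis and
#' Percent Invasion columns of a sweep table.  A positive value reproduces
#' the predicted association between the areas of necrosis and brain
#' invasion.
#'
#' @param table A tibble from [parameter_sweep()] (or any data frame with
#'   `pct_necrosis` and `pct_invasion` columns).
#' @return The Spearman correlation coefficient.
#' @export
necrosis_invasion_association <- function(table) {
  ok <- stats::complete.cases(table[, c("pct_necrosis", "pct_invasion")])
  if (sum(ok) < 3) {
    stop("need at least 3 rows with finite metrics", call. = FALSE)
  }
  stats::cor(table$pct_necrosis[ok], table$pct_invasion[ok],
             method = "spearman")
}
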