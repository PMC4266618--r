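#' Bidimensional lesion area
#'
#' Lesion area estimated radiologically as the product of the two largest
#' perpendicular diameters (mm), the standard bidimensional measure used on
#' contrast-enhanced and FLAIR images.
#'
#' @param d1,d2 Perpendicular diameters in mm (vectorised).
#' @return Area in mm^2.
#' @examples
#' bidimensional_area(30, 40)  # 1200
#' @export
bidimensional_area <- function(d1, d2) {
  if (any(d1 < 0 | d2 < 0)) stop("diameters must be >= 0", call. = FALSE)
  d1 * d2
}

#' FLAIR-minus-tumour area
#'
#' The nonenhancing invaded margin is quantified as the FLAIR-abnormality
#' area minus the enhancing-tumour area.  Negative differences (measurement
#' noise) are clipped at zero with a warning.
#'
#' @param flair_area,tumor_area Areas in mm^2 (vectorised).
#' @return Difference in mm^2, clipped at 0.
#' @export
flair_minus_tumor <- function(flair_area, tumor_area) {
  if (any(flair_area < 0 | tumor_area < 0)) {
    stop("areas must be >= 0", call. = FALSE)
  }
  d <- flair_area - tumor_area
  if (any(d < 0)) {
    warning(sum(d < 0), " FLAIR area(s) smaller than the tumour area; ",
            "clipped at 0", call. = FALSE)
    d <- pmax(d, 0)
  }
  d
}

#' Least-absolute-residuals polynomial fit
#'
#' Robust polynomial regression minimising the sum of absolute residuals,
#' computed by iteratively reweighted least squares with weights
#' `1 / max(|r|, delta)`.  Far less sensitive to gross outliers than
#' ordinary least squares; on outlier-free data the two agree.
#'
#' @param x,y Numeric vectors.
#' @param degree Polynomial degree (default 1, a robust line).
#' @param delta Residual floor in the weights (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence threshold on the coefficient change
#'   (default 1e-9).
#' @return An object of class `lar_fit`: `coefficients` (intercept first),
#'   `fitted`, `residuals`, `r_squared`, `iterations`, `converged`, plus
#'   the data.
#' @examples
#' f <- lar_polyfit(1:10, 2 * (1:10) + 1)
#' coef(f)
#' @export
lar_polyfit <- function(x, y, degree = 1, delta = 1e-6,
                        max_iter = 100, tol = 1e-9) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n <= degree + 1) {
    stop("underdetermined fit: need more than degree + 1 points",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  if (degree >= 1) {
    X <- cbind(X, stats::poly(x, degree = degree, raw = TRUE))
    colnames(X)[-1] <- paste0("x^", seq_len(degree))
  }
  beta <- stats::lm.fit(X, y)$coefficients  # OLS start
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    r <- y - drop(X %*% beta)
    w <- 1 / pmax(abs(r), delta)
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged) {
    warning("least-absolute-residuals fit did not converge in ", max_iter,
            " iterations; returning the last iterate", call. = FALSE)
  }
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(coefficients = beta, fitted = fitted, residuals = resid,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         iterations = it, converged = converged, degree = degree,
         x = x, y = y),
    class = "lar_fit"
  )
}

#' @export
coef.lar_fit <- function(object, ...) object$coefficients

#' @export
print.lar_fit <- function(x, ...) {
  cat("<lar_fit> degree", x$degree, "least-absolute-residuals fit\n")
  print(round(x$coefficients, 6))
  cat("R-squared:", format(x$r_squared, digits = 4),
      "| iterations:", x$iterations, "\n")
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function from times and event
#' flags, as used for progression-free survival.  Censored subjects leave
#' the risk set without producing a drop; subjects censored at an event
#' time are still counted in that time's risk set.
#'
#' @param times Positive event/censoring times.
#' @param events Logical or 0/1 event indicators (1 = progressed).
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `survival`
#'   (one row per distinct event or censoring time).
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    survival = fit$surv
  )
}

#' Log-rank test comparing two survival curves
#'
#' Standard one-degree-of-freedom log-rank statistic built from the
#' observed and expected event counts with hypergeometric variance, with
#' the p-value from the chi-square distribution.
#'
#' @param time_a,event_a Times and event flags of group A.
#' @param time_b,event_b Times and event flags of group B.
#' @return An object of class `gbm_logrank`: `statistic` (chi-square),
#'   `p_value`, `observed` and `expected` per group.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) > 0, length(time_b) > 0)
  if (sum(event_a) + sum(event_b) == 0) {
    stop("log-rank statistic undefined: no events in either group",
         call. = FALSE)
  }
  time <- c(time_a, time_b)
  event <- as.integer(c(event_a, event_b))
  group <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(
    list(statistic = unname(sd$chisq),
         p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         observed = sd$obs, expected = sd$exp),
    class = "gbm_logrank"
  )
}

#' @export
print.gbm_logrank <- function(x, ...) {
  cat("Log-rank test: chi-square =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Mean age of a subset of patients
#'
#' Arithmetic mean of the ages of the selected cohort rows, reported to one
#' decimal place as in clinical characteristics tables.
#'
#' @param cohort A data frame with an `age` column.
#' @param rows Row indices (default: all rows).
#' @return Mean age in years, rounded to one decimal.
#' @export
table1_group_mean_age <- function(cohort, rows = seq_len(nrow(cohort))) {
  stopifnot("age" %in% names(cohort), length(rows) > 0)
  round(mean(cohort$age[rows]), 1)
}

#' Synthetic clinical cohort
#'
#' Deterministic (given `seed`) generator of a recurrent-GBM-like cohort
#' for exercising the clinical statistics.  Two groups are produced:
#' `necrosis_minus` (no expanding necrosis; longer progression-free
#' survival) and `necrosis_plus`, with exponential PFS times whose means
#' default to 333 and 178 days and roughly 20% random censoring.  Lesion
#' geometry follows a latent tumour-size factor so that the necrosis area
#' and the (FLAIR - tumour) area are positively associated, with occasional
#' heavy-tailed outliers as seen in measured diameters.
#'
#' @param seed Integer seed.
#' @param n Number of patients (>= 6; default 26).
#' @param mean_pfs_minus,mean_pfs_plus Mean PFS (days) of the two groups.
#' @param censor_prob Probability a subject is censored (default 0.2).
#' @param outlier_prob Probability a lesion measurement is replaced by a
#'   heavy-tailed outlier (default 0.1).
#' @return A `ClinicalCohort`-style tibble: `id`, `group`, `age`, tumour /
#'   necrosis / FLAIR diameters (mm), `pfs_time` (days), `event`.
#' @export
synth_cohort <- function(seed, n = 26,
                         mean_pfs_minus = 333, mean_pfs_plus = 178,
                         censor_prob = 0.2, outlier_prob = 0.1) {
  stopifnot(n >= 6)
  withr::with_seed(as.integer(seed), {
    group <- rep(c("necrosis_minus", "necrosis_plus"), length.out = n)
    size <- stats::rlnorm(n, meanlog = log(35), sdlog = 0.35)  # tumour scale, mm
    ecc <- stats::runif(n, 0.6, 1)
    tumor_d1 <- size
    tumor_d2 <- size * ecc
    # necrosis occupies a size-linked fraction of the lesion
    nec_frac <- clamp01(0.35 + 0.25 * scale(log(size))[, 1] * 0.3 +
                          stats::rnorm(n, 0, 0.08))
    necrosis_d1 <- tumor_d1 * nec_frac
    necrosis_d2 <- tumor_d2 * nec_frac
    # FLAIR halo grows with tumour size -> positive necrosis vs
    # (FLAIR - tumour) association through the shared latent size
    halo <- 1 + 0.55 * size / 35 + stats::rnorm(n, 0, 0.12)
    halo <- pmax(halo, 1)
    flair_d1 <- tumor_d1 * halo
    flair_d2 <- tumor_d2 * halo
    out <- stats::runif(n) < outlier_prob
    flair_d1[out] <- flair_d1[out] * stats::runif(sum(out), 1.8, 3)
    mean_pfs <- ifelse(group == "necrosis_minus", mean_pfs_minus,
                       mean_pfs_plus)
    pfs <- stats::rexp(n, rate = 1 / mean_pfs)
    pfs <- pmax(round(pfs), 1)
    event <- stats::runif(n) >= censor_prob
    age <- round(stats::rnorm(n, mean = 52, sd = 11))
    tibble::tibble(
      id = seq_len(n), group = group, age = age,
      tumor_d1 = tumor_d1, tumor_d2 = tumor_d2,
      necrosis_d1 = necrosis_d1, necrosis_d2 = necrosis_d2,
      flair_d1 = flair_d1, flair_d2 = flair_d2,
      pfs_time = pfs, event = event
    )
  })
}
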