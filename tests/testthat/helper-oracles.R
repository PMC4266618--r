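# Fixtures and independent scalar oracles used across the test files.
# The oracles deliberately use plain per-cell loops and share no code with
# the vectorised implementations they check.

make_state <- function(P, I = 0 * P, B = 0 * P, N = 0 * P,
                       tau_h = 0.7, tau_l = 0.85, t = 0) {
  if (length(tau_h) == 1) tau_h <- matrix(tau_h, nrow(P), ncol(P))
  if (length(tau_l) == 1) tau_l <- matrix(tau_l, nrow(P), ncol(P))
  structure(list(P = P, I = I, B = B, N = N,
                 tau_h = tau_h, tau_l = tau_l, t = t),
            class = "tissue_state")
}

open_domain <- function(nr, nc = nr, h = 1) {
  brain_domain(matrix(TRUE, nr, nc), b_init = 0.5, h = h)
}

disc_domain <- function(n, radius = (n - 3) / 2, b0 = 0.5) {
  ctr <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  brain_domain((row - ctr)^2 + (col - ctr)^2 <= radius^2, b_init = b0)
}

# scalar explicit-Euler oracle for the local kinetics in one cell
scalar_reaction_oracle <- function(p_, i_, b_, n_, th, tl, params, dt) {
  C <- p_ + i_ + b_ + n_
  H <- min(max(C / params$c_ref, 0), 1)
  upper <- if (params$mitosis_form == "saturating") 1 else tl
  M <- params$m_max * min(max((upper - H) / (upper - th), 0), 1)
  width <- if (params$death_form == "steep") {
    min(params$lethal_width, 1 - tl + 1e-12)
  } else 1 - tl
  mu <- params$mu_max * min(max((H - tl) / width, 0), 1)
  s_pi <- params$beta_pi * min(max((H - th) / (1 - th), 0), 1)
  s_ip <- params$beta_ip * min(max((tl - H) / (tl - th), 0), 1)
  out_p <- (s_pi + mu) * dt
  out_i <- (s_ip + mu) * dt
  sp <- if (out_p > 1) 1 / out_p else 1
  si <- if (out_i > 1) 1 / out_i else 1
  ob <- min(mu * dt, 1)
  c(P = p_ + M * p_ * dt - (s_pi + mu) * dt * sp * p_ + s_ip * dt * si * i_,
    I = i_ + s_pi * dt * sp * p_ - (s_ip + mu) * dt * si * i_,
    B = b_ - ob * b_,
    N = n_ + mu * dt * sp * p_ + mu * dt * si * i_ + ob * b_)
}

# loop-based flux-form diffusion oracle (zero-flux outside `open`)
scalar_diffusion_oracle <- function(I, D, open, dt, h) {
  nr <- nrow(I); nc <- ncol(I)
  out <- I
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!open[r, cc]) next
    acc <- 0
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!open[r2, c2]) next
      acc <- acc + 0.5 * (D[r, cc] + D[r2, c2]) *
        (I[r2, c2] - I[r, cc]) * dt / h^2
    }
    out[r, cc] <- I[r, cc] + acc
  }
  out
}

# loop-based donor-cell upwind advection oracle with velocity gamma*grad(B)
scalar_advection_oracle <- function(I, B, open, gamma, dt, h) {
  nr <- nrow(I); nc <- ncol(I)
  out <- I
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!open[r, cc]) next
    for (d in list(c(1, 0), c(0, 1))) {  # each face once
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 > nr || c2 > nc) next
      if (!open[r2, c2]) next
      v <- gamma * (B[r2, c2] - B[r, cc]) / h
      donor <- if (v > 0) I[r, cc] else I[r2, c2]
      f <- v * donor * dt / h
      out[r, cc] <- out[r, cc] - f
      out[r2, c2] <- out[r2, c2] + f
    }
  }
  out
}

# direct rank-formula Spearman (mid-ranks for ties)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

fast_params <- function(...) {
  gbm_params(...)
}
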