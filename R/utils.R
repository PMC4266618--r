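# internal helpers shared across the solver files

clamp01 <- function(x) pmin(pmax(x, 0), 1)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# shift a matrix by one cell; vacated cells are zero-filled.  "up" returns
# the neighbour below each cell moved into its place (i.e. m[i+1, j]).
shift_up <- function(m) rbind(m[-1L, , drop = FALSE], 0)
shift_down <- function(m) rbind(0, m[-nrow(m), , drop = FALSE])
shift_left <- function(m) cbind(m[, -1L, drop = FALSE], 0)
shift_right <- function(m) cbind(0, m[, -ncol(m), drop = FALSE])

same_shape <- function(...) {
  dims <- lapply(list(...), dim)
  all(vapply(dims[-1], identical, logical(1), dims[[1]]))
}
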