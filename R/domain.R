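#' Construct a brain domain
#'
#' A brain domain is the geometric substrate of a simulation: a boolean
#' mask of cells inside the brain (skin, bone and background are
#' impermeable), a white-matter fraction field in `[0, 1]`, the initial
#' healthy-brain density and the cell edge length.
#'
#' Raster convention: matrices are indexed `[row, col]`, row-major with the
#' origin at the top-left, so cell (1, 1) is the first pixel of an imported
#' image.
#'
#' @param mask Logical matrix; `TRUE` inside the brain.
#' @param wm Numeric matrix of white-matter fractions in `[0, 1]`.
#' @param b_init Initial brain-density matrix, or a single number applied
#'   inside the mask.
#' @param h Cell edge length (arbitrary length unit; default 1).
#' @return A `brain_domain` object.
#' @export
brain_domain <- function(mask, wm = NULL, b_init = 0.5, h = 1) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (is.null(wm)) wm <- matrix(0, nrow(mask), ncol(mask))
  stopifnot(is.matrix(wm), all(dim(wm) == dim(mask)))
  if (any(wm < 0 | wm > 1)) {
    stop("white-matter fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(b_init) == 1L) {
    b <- matrix(0, nrow(mask), ncol(mask))
    b[mask] <- b_init
    b_init <- b
  }
  stopifnot(all(dim(b_init) == dim(mask)))
  wm[!mask] <- 0
  b_init[!mask] <- 0
  if (h <= 0) stop("cell edge length `h` must be > 0", call. = FALSE)
  structure(
    list(mask = mask, wm = wm, b_init = b_init, h = h, shape = dim(mask)),
    class = "brain_domain"
  )
}

#' @export
print.brain_domain <- function(x, ...) {
  cat("<brain_domain> ", x$shape[1], "x", x$shape[2],
      " | brain cells: ", sum(x$mask),
      " (", round(100 * mean(x$mask), 1), "% of grid)",
      " | white matter: ", round(100 * sum(x$wm > 0) / max(sum(x$mask), 1), 1),
      "% of brain | h = ", x$h, "\n", sep = "")
  invisible(x)
}

#' Synthetic brain phantom
#'
#' Deterministic (given `seed`) stand-in for a virtual-MRI brain slice: an
#' elliptical brain bounded by an impermeable rim, containing 2-4 curved
#' white-matter tracks (sinusoidal bands with `wm = 1`).  The brain occupies
#' between 30% and 70% of the grid.
#'
#' @param shape Integer vector of grid dimensions (default `c(127, 127)`).
#' @param seed Integer seed controlling track geometry.
#' @param b0 Initial brain density inside the mask.
#' @param h Cell edge length.
#' @return A `brain_domain`.
#' @examples
#' dom <- synthetic_brain(c(64, 64), seed = 1)
#' mean(dom$mask)
#' @export
synthetic_brain <- function(shape = c(127, 127), seed = 0, b0 = 0.5, h = 1) {
  stopifnot(length(shape) == 2, all(shape >= 32))
  nr <- shape[1]; nc <- shape[2]
  withr::with_seed(as.integer(seed), {
    row <- matrix(seq_len(nr), nr, nc)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    cy <- (nr + 1) / 2
    cx <- (nc + 1) / 2
    # semi-axes chosen so the ellipse area is ~55% of the grid, inside the
    # guaranteed [0.3, 0.7] band even after rim erosion
    ax <- 0.44 * nc
    ay <- 0.40 * nr
    mask <- ((col - cx) / ax)^2 + ((row - cy) / ay)^2 <= 1
    wm <- matrix(0, nr, nc)
    n_tracks <- sample(2:4, 1)
    for (k in seq_len(n_tracks)) {
      offset <- stats::runif(1, -0.25, 0.25) * nr
      amp <- stats::runif(1, 0.05, 0.2) * nr
      phase <- stats::runif(1, 0, 2 * pi)
      freq <- sample(1:2, 1)
      width <- stats::runif(1, 1, 2.2)
      centre <- cy + offset + amp * sin(freq * 2 * pi * col / nc + phase)
      band <- abs(row - centre) <= width
      wm[band & mask] <- 1
    }
    brain_domain(mask = mask, wm = wm, b_init = b0, h = h)
  })
}

#' Import a labelled brain-slice raster
#'
#' Builds a domain from a labelled image: a CSV grid of integer labels, an
#' ASCII PGM (`P2`) file, a PNG (grey levels 0-255), or a label matrix
#' passed directly.  `label_map` assigns each label a tissue class:
#' `"outside"` (background/skin/bone), `"grey"` (wm 0) or `"white"` (wm 1);
#' numeric values in `[0, 1]` are accepted as white-matter fractions.
#'
#' @param raster File path or integer matrix of labels.
#' @param label_map Named list or vector mapping label values (as names) to
#'   tissue classes, e.g. `c("0" = "outside", "1" = "grey", "2" = "white")`.
#' @param b0 Initial brain density inside the mask.
#' @param h Cell edge length.
#' @return A `brain_domain`.
#' @export
load_brain_slice <- function(raster, label_map, b0 = 0.5, h = 1) {
  labels <- if (is.matrix(raster)) raster else read_label_raster(raster)
  seen <- sort(unique(as.vector(labels)))
  known <- suppressWarnings(as.numeric(names(label_map)))
  missing <- setdiff(seen, known)
  if (length(missing) > 0) {
    stop("raster contains label(s) not covered by label_map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class_of <- function(v) label_map[[match(v, known)]]
  mask <- matrix(FALSE, nrow(labels), ncol(labels))
  wm <- matrix(0, nrow(labels), ncol(labels))
  for (v in seen) {
    cls <- class_of(v)
    sel <- labels == v
    if (identical(cls, "outside")) next
    mask[sel] <- TRUE
    wm[sel] <- if (identical(cls, "grey")) 0
               else if (identical(cls, "white")) 1
               else if (is.numeric(cls) && cls >= 0 && cls <= 1) cls
               else stop("label_map entry for label ", v,
                         " must be 'outside', 'grey', 'white' or a fraction",
                         call. = FALSE)
  }
  if (!any(mask)) stop("no brain tissue: every raster label maps outside",
                       call. = FALSE)
  brain_domain(mask = mask, wm = wm, b_init = b0, h = h)
}

read_label_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else if (ext == "pgm") {
    read_pgm_ascii(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG rasters requires the `png` package", call. = FALSE)
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 255)
  } else {
    stop("unsupported raster format: .", ext,
         " (use CSV, ASCII PGM or PNG)", call. = FALSE)
  }
}

# minimal ASCII ("P2") PGM reader; comments ('#') allowed after the magic
read_pgm_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII (P2) PGM is supported", call. = FALSE)
  nums <- as.numeric(tok[-1])
  nc <- nums[1]; nr <- nums[2]
  vals <- nums[-(1:3)]  # drop width, height, maxval
  if (length(vals) != nr * nc) stop("corrupt PGM: pixel count mismatch",
                                    call. = FALSE)
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Export / import a brain domain as CSV grids
#'
#' Writes `<stem>_mask.csv`, `<stem>_wm.csv`, `<stem>_binit.csv` and a
#' one-line `<stem>_meta.csv` holding the cell edge length.  Re-importing
#' reproduces mask and white matter exactly.
#'
#' @param domain A `brain_domain`.
#' @param stem File-path stem for the four CSV files.
#' @return `write_domain()`: the stem, invisibly.  `read_domain()`: a
#'   `brain_domain`.
#' @export
write_domain <- function(domain, stem) {
  utils::write.table(domain$mask * 1L, paste0(stem, "_mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(domain$wm, paste0(stem, "_wm.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(domain$b_init, paste0(stem, "_binit.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(h = domain$h), paste0(stem, "_meta.csv"),
                     sep = ",", row.names = FALSE)
  invisible(stem)
}

#' @rdname write_domain
#' @export
read_domain <- function(stem) {
  mask <- as.matrix(utils::read.csv(paste0(stem, "_mask.csv"),
                                    header = FALSE)) == 1
  wm <- as.matrix(utils::read.csv(paste0(stem, "_wm.csv"), header = FALSE))
  b <- as.matrix(utils::read.csv(paste0(stem, "_binit.csv"), header = FALSE))
  meta <- utils::read.csv(paste0(stem, "_meta.csv"))
  dimnames(mask) <- dimnames(wm) <- dimnames(b) <- NULL
  brain_domain(mask = mask, wm = wm, b_init = b, h = meta$h)
}

#' Seed a tumour into a brain domain
#'
#' Returns the initial tissue state: healthy brain at `b_init` everywhere
#' inside the mask, no necrosis, thresholds at `(tau_h0, tau_l0)`, and a
#' small concentration of proliferative (`p_seed`) and invasive (`i_seed`)
#' cells inserted into a single cell.
#'
#' @param domain A `brain_domain`.
#' @param params A `gbm_params` object.
#' @param location Integer `c(row, col)` of the seeded cell; defaults to the
#'   brain cell closest to the domain centre.
#' @return A `tissue_state`: matrices `P`, `I`, `B`, `N`, `tau_h`, `tau_l`,
#'   elapsed time `t`, and the seed location as attribute `"seed"`.
#' @export
seed_tumor <- function(domain, params = gbm_params(), location = NULL) {
  stopifnot(inherits(domain, "brain_domain"))
  if (is.null(location)) {
    ctr <- (dim(domain$mask) + 1) / 2
    inside <- which(domain$mask, arr.ind = TRUE)
    d2 <- (inside[, 1] - ctr[1])^2 + (inside[, 2] - ctr[2])^2
    location <- unname(inside[which.min(d2), ])
  }
  location <- as.integer(location)
  if (!domain$mask[location[1], location[2]]) {
    stop("seed location (", location[1], ", ", location[2],
         ") is outside the brain mask", call. = FALSE)
  }
  zero <- matrix(0, nrow(domain$mask), ncol(domain$mask))
  P <- zero; I <- zero; N <- zero
  P[location[1], location[2]] <- params$p_seed
  I[location[1], location[2]] <- params$i_seed
  state <- structure(
    list(P = P, I = I, B = domain$b_init, N = N,
         tau_h = matrix(params$tau_h0, nrow(zero), ncol(zero)),
         tau_l = matrix(params$tau_l0, nrow(zero), ncol(zero)),
         t = 0),
    class = "tissue_state"
  )
  attr(state, "seed") <- location
  state
}

#' @export
print.tissue_state <- function(x, ...) {
  cat("<tissue_state> ", nrow(x$P), "x", ncol(x$P), " at t = ",
      format(x$t, digits = 6),
      " | P mass ", format(sum(x$P), digits = 4),
      " | I mass ", format(sum(x$I), digits = 4),
      " | N mass ", format(sum(x$N), digits = 4), "\n", sep = "")
  invisible(x)
}
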