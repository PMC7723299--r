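# Internal N-d array helpers shared by the label transforms and the
# watershed post-processing. Arrays follow R's column-major layout with
# axis order (row, col) in 2D and (row, col, plane) in 3D.

as_label_array <- function(x) {
  if (is.null(dim(x))) stop("label image must be a matrix or array")
  if (any(x < 0)) stop("label image values must be >= 0")
  storage.mode(x) <- "integer"
  x
}

label_ids <- function(labels) {
  ids <- sort(unique(as.integer(labels)))
  ids[ids > 0L]
}

#' Exact Euclidean distance transform
#'
#' Distance of every `TRUE` pixel to the nearest `FALSE` pixel, computed
#' with the exact separable lower-envelope algorithm in any number of
#' dimensions. Pixels outside the array do not exist: a foreground region
#' touching the frame edge takes its distance from in-frame background only.
#'
#' @param fg logical matrix/array, `TRUE` = foreground.
#' @return numeric array of the same shape with Euclidean distances
#'   (0 on background).
#' @export
distance_transform <- function(fg) {
  d <- dim(fg)
  if (is.null(d)) stop("input must have dimensions")
  if (!all(fg)) {
    out <- sqrt(cpp_sqedt(as.logical(fg), as.integer(d)))
  } else {
    out <- rep(Inf, length(fg))
  }
  dim(out) <- d
  out
}

#' Label connected components
#'
#' @param fg logical matrix/array.
#' @param connectivity `"full"` (8 in 2D / 26 in 3D) or `"face"`
#'   (4 in 2D / 6 in 3D).
#' @return integer array of component labels, 0 on background.
#' @export
label_components <- function(fg, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  d <- dim(fg)
  out <- cpp_label_components(as.logical(fg), as.integer(d),
                              connectivity == "full")
  dim(out) <- d
  out
}

# Structuring-element offsets: rows are integer offsets. "disk" keeps
# offsets with Euclidean norm <= radius, "box" the full Chebyshev cube.
se_offsets <- function(radius, ndim, shape = c("disk", "box")) {
  shape <- match.arg(shape)
  r <- as.integer(radius)
  if (r < 0) stop("radius must be >= 0")
  grids <- rep(list(seq(-r, r)), ndim)
  offs <- as.matrix(expand.grid(grids))
  colnames(offs) <- NULL
  if (shape == "disk" && r > 0) {
    offs <- offs[sqrt(rowSums(offs^2)) <= r + 1e-9, , drop = FALSE]
  }
  offs
}

# out[i] = x[i + off] where in range, `fill` elsewhere.
shift_array <- function(x, off, fill) {
  d <- dim(x)
  k <- length(d)
  src <- vector("list", k)
  dst <- vector("list", k)
  for (a in seq_len(k)) {
    o <- off[a]
    if (abs(o) >= d[a]) return(array(fill, d))
    if (o >= 0) {
      dst[[a]] <- seq_len(d[a] - o)
      src[[a]] <- seq_len(d[a] - o) + o
    } else {
      dst[[a]] <- seq_len(d[a] + o) - o
      src[[a]] <- seq_len(d[a] + o)
    }
  }
  out <- array(fill, d)
  out_idx <- do.call(`[<-`, c(list(out), dst,
                              list(value = do.call(`[`, c(list(x), src)))))
  out_idx
}

# Grayscale dilation/erosion by max/min over structuring-element offsets;
# out-of-frame contributions are ignored (shift fill of -Inf / +Inf).
gray_dilate <- function(x, offsets) {
  out <- array(-Inf, dim(x))
  for (i in seq_len(nrow(offsets))) {
    out <- pmax(out, shift_array(x, offsets[i, ], -Inf))
  }
  dim(out) <- dim(x)
  out
}

gray_erode <- function(x, offsets) {
  out <- array(Inf, dim(x))
  for (i in seq_len(nrow(offsets))) {
    out <- pmin(out, shift_array(x, offsets[i, ], Inf))
  }
  dim(out) <- dim(x)
  out
}

gray_close <- function(x, offsets) {
  neg <- -offsets
  gray_erode(gray_dilate(x, offsets), neg)
}

binary_erode <- function(mask, offsets) {
  gray_erode(mask * 1, offsets) > 0.5
}

binary_dilate <- function(mask, offsets) {
  gray_dilate(mask * 1, offsets) > 0.5
}

# Separable Gaussian smoothing with reflect padding, per-axis sigma.
gaussian_smooth <- function(x, sigma) {
  d <- dim(x)
  k <- length(d)
  sigma <- rep_len(sigma, k)
  for (a in seq_len(k)) {
    if (sigma[a] <= 0) next
    x <- conv1d_axis(x, a, gaussian_kernel(sigma[a]))
  }
  x
}

gaussian_kernel <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(round(truncate * sigma)))
  w <- dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

# Convolve along one axis with reflect ("symmetric") padding.
conv1d_axis <- function(x, axis, w) {
  d <- dim(x)
  k <- length(d)
  perm <- c(axis, seq_len(k)[-axis])
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  n <- nrow(m)
  r <- (length(w) - 1L) %/% 2L
  pre <- pmin(r, n)          # reflect indices (edge mirrored without repeat
  top <- m[rev(seq_len(pre)), , drop = FALSE]     # of border pixel), scipy
  bot <- m[n - seq_len(pre) + 1L, , drop = FALSE] # "reflect"/symmetric mode
  if (pre < r) { # tiny arrays: extend by cycling reflections
    while (nrow(top) < r) top <- rbind(m[seq_len(min(n, r - nrow(top))), , drop = FALSE], top)
    while (nrow(bot) < r) bot <- rbind(bot, m[rev(seq_len(min(n, r - nrow(bot)))), , drop = FALSE])
    top <- top[seq(nrow(top) - r + 1L, nrow(top)), , drop = FALSE]
    bot <- bot[seq_len(r), , drop = FALSE]
  }
  mp <- rbind(top, m, bot)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(w)) {
    out <- out + w[j] * mp[seq_len(n) + j - 1L, , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}

# Evaluate an expression with a temporary RNG seed, restoring state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
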