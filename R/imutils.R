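# Low-level 3-D image utilities: Gaussian smoothing (FFT, periodic
# boundaries), Otsu thresholding, connected components and binary
# morphology. All operate on plain 3-D arrays.

# Gaussian smoothing with per-axis sigma in voxels, via the separable
# frequency-domain transfer function exp(-2 pi^2 sigma^2 f^2). Periodic
# boundary conditions; adequate for texture synthesis and displacement-field
# regularisation where content stays away from the array edges.
gaussian_smooth3 <- function(arr, sigma_vox) {
  dm <- dim(arr)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  if (all(sigma_vox <= 0)) return(arr)
  H1 <- function(n, s) {
    f <- c(0:floor(n / 2), if (n > 1) seq.int(-ceiling(n / 2) + 1, -1)) / n
    exp(-2 * pi^2 * s^2 * f^2)
  }
  hx <- H1(dm[1], sigma_vox[1])
  hy <- H1(dm[2], sigma_vox[2])
  hz <- H1(dm[3], sigma_vox[3])
  H <- array(outer(outer(hx, hy), hz), dim = dm)
  Re(fft(fft(arr) * H, inverse = TRUE)) / prod(dm)
}

# Otsu's threshold on finite values; returns the threshold maximizing
# between-class variance over a 256-bin histogram.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("otsu_threshold: no finite values")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / (r[2] - r[1]) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * (r[2] - r[1])
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  bc <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

# Shift a logical/numeric 3-D array by one voxel along `axis` in direction
# `dir` (+1/-1), padding with `fill`.
shift3 <- function(arr, axis, dir, fill = FALSE) {
  dm <- dim(arr)
  out <- array(fill, dim = dm)
  n <- dm[axis]
  if (n <= 1) return(out)
  src <- lapply(dm, seq_len)
  dst <- src
  if (dir > 0) {
    src[[axis]] <- 1:(n - 1)
    dst[[axis]] <- 2:n
  } else {
    src[[axis]] <- 2:n
    dst[[axis]] <- 1:(n - 1)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# One 6-connectivity binary dilation step.
dilate1 <- function(m) {
  m | shift3(m, 1, 1) | shift3(m, 1, -1) |
    shift3(m, 2, 1) | shift3(m, 2, -1) |
    shift3(m, 3, 1) | shift3(m, 3, -1)
}

binary_dilate <- function(m, iter = 1L) {
  for (i in seq_len(iter)) m <- dilate1(m)
  m
}

binary_erode <- function(m, iter = 1L) {
  !binary_dilate(!m, iter)
}

binary_close <- function(m, iter = 1L) {
  if (iter < 1) return(m)
  binary_erode(binary_dilate(m, iter), iter)
}

# Fill interior holes: anything not reachable from the array border through
# the background becomes foreground.
fill_holes <- function(m) {
  bg <- !m
  reach <- array(FALSE, dim = dim(m))
  dm <- dim(m)
  reach[c(1, dm[1]), , ] <- bg[c(1, dm[1]), , ]
  reach[, c(1, dm[2]), ] <- reach[, c(1, dm[2]), ] | bg[, c(1, dm[2]), ]
  reach[, , c(1, dm[3])] <- reach[, , c(1, dm[3])] | bg[, , c(1, dm[3])]
  repeat {
    grown <- dilate1(reach) & bg
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  m | (bg & !reach)
}

# Largest 6-connected component of a logical array. Flood-fills by frontier
# dilation; component count on phantom-like images is small.
largest_component <- function(m) {
  remaining <- m
  best <- NULL
  best_n <- 0L
  while (any(remaining)) {
    seed_idx <- which(remaining)[1]
    comp <- array(FALSE, dim = dim(m))
    comp[seed_idx] <- TRUE
    repeat {
      grown <- dilate1(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    n <- sum(comp)
    if (n > best_n) {
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  if (is.null(best)) m else best
}

# Central-difference spatial gradient (per mm) of a 3-D array.
gradient3 <- function(arr, spacing) {
  g <- vector("list", 3)
  for (ax in 1:3) {
    fwd <- shift3(arr, ax, -1, fill = NA)   # value at i+1
    bwd <- shift3(arr, ax, 1, fill = NA)    # value at i-1
    d <- (fwd - bwd) / (2 * spacing[ax])
    # one-sided at the borders
    d[is.na(d)] <- 0
    g[[ax]] <- d
  }
  g
}
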