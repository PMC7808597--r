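# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's fast paths (distance
# transforms, separable box sums) so they can serve as references.

# tiny image/mask builders ---------------------------------------------------

tiny_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  hs_image(values, spacing, origin)
}

tiny_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      role = "other") {
  hs_mask(values, spacing, origin, role = role)
}

random_mask <- function(dims, p = 0.2, spacing = c(1, 1, 1), nonempty = TRUE) {
  repeat {
    v <- array(as.numeric(stats::runif(prod(dims)) < p), dim = dims)
    if (!nonempty || sum(v) > 0)
      return(tiny_mask(v, spacing = spacing))
  }
}

# boundary voxels by explicit neighbour scan ---------------------------------

oracle_surface_idx <- function(mask) {
  d <- dim(mask$values)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask$values[i, j, k] == 0) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    surf <- FALSE
    for (q in nb) {
      if (any(q < 1) || any(q > d)) { surf <- TRUE; break }
      if (mask$values[q[1], q[2], q[3]] == 0) { surf <- TRUE; break }
    }
    if (surf) out <- rbind(out, c(i, j, k) - 1)
  }
  out
}

oracle_surface_points <- function(mask) {
  idx <- oracle_surface_idx(mask)
  voxel_to_physical(mask, idx)
}

# exhaustive pairwise surface distances --------------------------------------

oracle_directed <- function(pa, pb) {
  vapply(seq_len(nrow(pa)), function(r) {
    sqrt(min(colSums((t(pb) - pa[r, ])^2)))
  }, numeric(1))
}

oracle_masd <- function(a, b) {
  pa <- oracle_surface_points(a); pb <- oracle_surface_points(b)
  (mean(oracle_directed(pa, pb)) + mean(oracle_directed(pb, pa))) / 2
}

oracle_hd <- function(a, b) {
  pa <- oracle_surface_points(a); pb <- oracle_surface_points(b)
  max(max(oracle_directed(pa, pb)), max(oracle_directed(pb, pa)))
}

# exhaustive patch mean absolute difference ----------------------------------

oracle_patch_mad <- function(av, bv, rvox) {
  d <- dim(av)
  out <- array(0, d)
  ad <- abs(av - bv)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    xs <- max(1, i - rvox[1]):min(d[1], i + rvox[1])
    ys <- max(1, j - rvox[2]):min(d[2], j + rvox[2])
    zs <- max(1, k - rvox[3]):min(d[3], k + rvox[3])
    out[i, j, k] <- mean(ad[xs, ys, zs])
  }
  out
}

# per-voxel majority vote -----------------------------------------------------

oracle_majority <- function(masks) {
  n <- length(masks)
  votes <- Reduce(`+`, lapply(masks, function(m) m$values))
  array(as.numeric(votes > n / 2), dim = dim(votes))
}

# displaced copy of a mask by whole voxels ------------------------------------

shift_mask <- function(mask, shift_vox) {
  d <- dim(mask$values)
  out <- array(0, d)
  src <- mask$values
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    q <- c(i, j, k) - shift_vox
    if (all(q >= 1) && all(q <= d) && src[q[1], q[2], q[3]] > 0)
      out[i, j, k] <- 1
  }
  tiny_mask(out, spacing = mask$spacing, origin = mask$origin,
            role = mask$role)
}

# small, fast phantom for registration-level unit tests ----------------------

small_phantom <- function(seed = 1L, noise_sd = 10) {
  make_phantom(phantom_spec(dims = c(48, 48, 48),
                            spacing = rep(160 / 48, 3),
                            noise_sd = noise_sd, seed = seed))
}

# shared default-size phantom, built once per test run
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom()
    cache
  }
})
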