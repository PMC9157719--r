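# Naive enumeration oracles, written independently of the package kernels:
# plain R loops over voxels and neighbours, used to pin down the texture
# matrices and distance geometry on small random ROIs.

DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

in_bounds <- function(v, dims) all(v >= 1) && all(v <= dims)

naive_glcm <- function(lev, mask, G) {
  dims <- dim(mask)
  counts <- matrix(0, G, G)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    for (k in 1:13) {
      nb <- c(x, y, z) + DIRS13[k, ]
      if (!in_bounds(nb, dims)) next
      if (!mask[nb[1], nb[2], nb[3]]) next
      a <- lev[x, y, z]
      b <- lev[nb[1], nb[2], nb[3]]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts
}

naive_glrlm <- function(lev, mask, G) {
  dims <- dim(mask)
  counts <- matrix(0, G, max(dims))
  for (k in 1:13) {
    d <- DIRS13[k, ]
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      v <- c(x, y, z)
      if (!mask[x, y, z]) next
      prev <- v - d
      if (in_bounds(prev, dims) && mask[prev[1], prev[2], prev[3]] &&
          lev[prev[1], prev[2], prev[3]] == lev[x, y, z]) next
      len <- 1
      nxt <- v + d
      while (in_bounds(nxt, dims) && mask[nxt[1], nxt[2], nxt[3]] &&
             lev[nxt[1], nxt[2], nxt[3]] == lev[x, y, z]) {
        len <- len + 1
        nxt <- nxt + d
      }
      counts[lev[x, y, z], len] <- counts[lev[x, y, z], len] + 1
    }
  }
  counts
}

# flood-fill labelling of 26-connected equal-level zones;
# returns a data frame of (level, size) sorted for comparison
naive_zones <- function(lev, mask) {
  dims <- dim(mask)
  seen <- array(FALSE, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z] || seen[x, y, z]) next
    g <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        nb <- v + offs[r, ]
        if (!in_bounds(nb, dims)) next
        if (seen[nb[1], nb[2], nb[3]] || !mask[nb[1], nb[2], nb[3]]) next
        if (lev[nb[1], nb[2], nb[3]] != g) next
        seen[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1]] <- nb
      }
    }
    zones[[length(zones) + 1]] <- c(level = g, size = size)
  }
  df <- as.data.frame(do.call(rbind, zones))
  df[order(df$level, df$size), ]
}

naive_ngtdm <- function(lev, mask, G) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  n_i <- numeric(G)
  s_i <- numeric(G)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    vals <- c()
    for (r in seq_len(nrow(offs))) {
      nb <- c(x, y, z) + offs[r, ]
      if (!in_bounds(nb, dims)) next
      if (mask[nb[1], nb[2], nb[3]]) vals <- c(vals, lev[nb[1], nb[2], nb[3]])
    }
    if (!length(vals)) next
    g <- lev[x, y, z]
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(vals))
  }
  list(n = n_i, s = s_i)
}

# random ROI on a small grid: integer levels and an irregular mask
rand_roi <- function(dims, G, p_mask = 0.7) {
  lev <- array(sample.int(G, prod(dims), replace = TRUE), dim = dims)
  mask <- array(runif(prod(dims)) < p_mask, dim = dims)
  if (!any(mask)) mask[sample(prod(dims), 1)] <- TRUE
  list(lev = lev, mask = mask)
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
wilcox_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(Wnull - mu) >= abs(W - mu) - 1e-12)
  min(1, p)
}

# Benjamini-Hochberg step-up written from the definition
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# ICC(A,1) via an aov() two-way ANOVA table (independent route to the
# mean squares used by the closed-form implementation)
icc_aov_oracle <- function(test, retest) {
  n <- length(test)
  df <- data.frame(
    y = c(test, retest),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# small synthetic lesion volume used across delineation/feature tests:
# homogeneous ellipsoid, optional noise-free surroundings
ball_volume <- function(radius_vox = 4.2, dims = c(21, 21, 21), suv_in = 8,
                        suv_out = 1, voxel_mm = 4) {
  ctr <- (dims + 1) / 2
  g <- expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3])
  r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  vals <- array(ifelse(r <= radius_vox, suv_in, suv_out), dim = dims)
  suv_volume(vals, voxel_size_mm = voxel_mm)
}

whole_seed <- function(vol, id = "lesion") {
  seed_region(c(1, 1, 1), dim(vol$values), id)
}

# seed box shrunk away from the volume boundary (lesions in these tests
# are centred, and an interior box keeps the SUVpeak sphere in bounds)
interior_seed <- function(vol, margin = 5, id = "lesion") {
  seed_region(rep(1 + margin, 3), dim(vol$values) - margin, id)
}
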