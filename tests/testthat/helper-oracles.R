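# Independent brute-force oracles and phantom builders shared by the tests.
# These deliberately re-derive each quantity with naive loops, not through
# the package's own accumulation code paths.

offsets26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
offsets26 <- offsets26[rowSums(abs(offsets26)) > 0, ]

# Symmetric co-occurrence counts over all 26 ordered neighbour offsets.
or_glcm <- function(levels, mask, G) {
  d <- dim(levels)
  P <- matrix(0, G, G)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    for (o in seq_len(nrow(offsets26))) {
      xx <- x + offsets26[o, 1]; yy <- y + offsets26[o, 2]
      zz <- z + offsets26[o, 3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
        next
      if (!mask[xx, yy, zz]) next
      P[levels[x, y, z], levels[xx, yy, zz]] <-
        P[levels[x, y, z], levels[xx, yy, zz]] + 1
    }
  }
  P
}

dirs13 <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
                c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
                c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))

# Exhaustive run enumeration over the 13 unique directions.
or_glrlm <- function(levels, mask, G) {
  d <- dim(levels)
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (k in seq_len(nrow(dirs13))) {
    dir <- dirs13[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      p <- c(x, y, z)
      if (!mask[x, y, z]) next
      prev <- p - dir
      if (inb(prev) && mask[prev[1], prev[2], prev[3]] &&
          levels[prev[1], prev[2], prev[3]] == levels[x, y, z]) next
      len <- 1
      q <- p + dir
      while (inb(q) && mask[q[1], q[2], q[3]] &&
             levels[q[1], q[2], q[3]] == levels[x, y, z]) {
        len <- len + 1
        q <- q + dir
      }
      runs[[length(runs) + 1]] <- c(levels[x, y, z], len)
    }
  }
  do.call(rbind, runs)
}

# 26-connected equal-level zones by repeated frontier growth.
or_zones <- function(levels, mask) {
  d <- dim(levels)
  seen <- array(FALSE, dim = d)
  zones <- list()
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    lev <- levels[p0[1], p0[2], p0[3]]
    frontier <- matrix(p0, ncol = 3)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0
    while (nrow(frontier) > 0) {
      size <- size + nrow(frontier)
      nxt <- list()
      for (i in seq_len(nrow(frontier))) {
        for (o in seq_len(nrow(offsets26))) {
          q <- frontier[i, ] + offsets26[o, ]
          if (any(q < 1) || any(q > d)) next
          if (seen[q[1], q[2], q[3]]) next
          if (!mask[q[1], q[2], q[3]]) next
          if (levels[q[1], q[2], q[3]] != lev) next
          seen[q[1], q[2], q[3]] <- TRUE
          nxt[[length(nxt) + 1]] <- q
        }
      }
      frontier <- if (length(nxt)) do.call(rbind, nxt) else
        matrix(numeric(0), ncol = 3)
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  do.call(rbind, zones)
}

# Dependence counts (neighbours within alpha) per voxel.
or_gldm <- function(levels, mask, G, alpha) {
  d <- dim(levels)
  P <- matrix(0, G, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    dep <- 0
    for (o in seq_len(nrow(offsets26))) {
      q <- c(x, y, z) + offsets26[o, ]
      if (any(q < 1) || any(q > d)) next
      if (!mask[q[1], q[2], q[3]]) next
      if (abs(levels[q[1], q[2], q[3]] - levels[x, y, z]) <= alpha)
        dep <- dep + 1
    }
    P[levels[x, y, z], dep + 1] <- P[levels[x, y, z], dep + 1] + 1
  }
  P
}

# Digitized sphere mask centred in a cubic lattice.
sphere_mask <- function(n, radius, spacing = c(1, 1, 1)) {
  cen <- (n - 1) / 2 * spacing
  co <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1)))
  co <- sweep(co, 2, spacing, "*")
  r2 <- rowSums(sweep(co, 2, cen, "-")^2)
  binary_mask(array(r2 <= radius^2, dim = c(n, n, n)), spacing = spacing)
}

# Small random levels/mask pair for matrix-family oracles.
random_levels_case <- function(seed, n = 5, G = 4, p_mask = 0.85) {
  withr::with_seed(seed, {
    lev <- array(sample.int(G, n^3, replace = TRUE), dim = c(n, n, n))
    msk <- array(runif(n^3) < p_mask, dim = c(n, n, n))
    if (!any(msk)) msk[1, 1, 1] <- TRUE
    lev[!msk] <- 0L
    list(levels = lev, mask = binary_mask(array(as.double(msk), dim(msk))),
         G = G)
  })
}

# A fast, deliberately small simulation configuration for image tests.
small_sim_config <- function(...) {
  sim_config(dims = c(32L, 32L, 32L), radius_range = c(6, 9), ...)
}
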