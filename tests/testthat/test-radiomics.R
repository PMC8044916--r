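test_that("discretization maps 0..31 to identity-ordered levels", {
  vals <- array(0, c(4, 4, 4))
  vals[1:32] <- 0:31
  vals[33:64] <- 31
  v <- image_volume(vals)
  m <- binary_mask(array(1, c(4, 4, 4)))
  d <- discretize(v, m, feature_params("count", 32))
  expect_equal(d$n_levels, 32L)
  expect_equal(as.numeric(d$levels[1:32]), 1:32)
  expect_false(d$degenerate)
})

test_that("constant regions collapse to a single flagged level", {
  v <- image_volume(array(7, c(3, 3, 3)))
  m <- binary_mask(array(1, c(3, 3, 3)))
  for (p in list(feature_params("count", 8), feature_params("width", 5))) {
    d <- discretize(v, m, p)
    expect_true(d$degenerate)
    expect_equal(d$n_levels, 1L)
    expect_true(all(d$levels == 1L))
  }
})

test_that("fixed-bin-count levels match a direct re-binning oracle", {
  withr::with_seed(61, {
    vals <- array(rnorm(6^3, 10, 4), c(6, 6, 6))
    v <- image_volume(vals)
    msk <- array(runif(6^3) < 0.8, c(6, 6, 6)); msk[1] <- TRUE
    m <- binary_mask(array(as.double(msk), dim(msk)))
    G <- 7L
    d <- discretize(v, m, feature_params("count", G))
    x <- vals[msk]
    width <- (max(x) - min(x)) / G
    oracle <- pmin(G, floor((x - min(x)) / width) + 1)
    expect_equal(as.numeric(d$levels[msk]), as.numeric(oracle))
    # monotone: level order follows value order
    expect_true(all(diff(d$levels[msk][order(x)]) >= 0))
  })
})

test_that("shape features: cube volume, sphere sphericity, count", {
  cube <- binary_mask({
    a <- array(0, c(14, 14, 14)); a[3:12, 3:12, 3:12] <- 1; a
  })
  sf <- shape_features(cube)
  expect_length(sf, 14)
  expect_equal(unname(sf["shape_VoxelVolume"]), 1000)
  sph <- shape_features(sphere_mask(36, 15))
  expect_gte(unname(sph["shape_Sphericity"]), 0.95)
  expect_lte(unname(sph["shape_Sphericity"]), 1.0)
  expect_lt(abs(sph["shape_MeshVolume"] - 4 / 3 * pi * 15^3) /
              (4 / 3 * pi * 15^3), 0.05)
  expect_lt(abs(sph["shape_Maximum3DDiameter"] - 30) / 30, 0.07)
  # shape ignores intensities: identical masks, different images
  expect_identical(shape_features(cube), shape_features(cube))
})

test_that("first-order features obey closed forms on a constant region", {
  a <- array(0, c(4, 4, 4))
  a[1:8] <- 2
  m <- binary_mask(array(rep(c(1, 0), c(8, 56)), c(4, 4, 4)))
  f <- first_order_features(image_volume(a), m)
  expect_length(f, 18)
  expect_equal(unname(f["firstorder_Mean"]), 2)
  expect_equal(unname(f["firstorder_Variance"]), 0)
  expect_equal(unname(f["firstorder_Energy"]), 32)
  expect_equal(unname(f["firstorder_Entropy"]), 0)
  expect_equal(unname(f["firstorder_Uniformity"]), 1)
  expect_equal(unname(f["firstorder_Skewness"]), 0)
})

test_that("first-order features match a formula-by-formula oracle", {
  withr::with_seed(62, {
    vals <- array(rnorm(125, 50, 12), c(5, 5, 5))
    v <- image_volume(vals, spacing = c(1, 1.2, 0.8))
    m <- binary_mask(array(1, c(5, 5, 5)), spacing = c(1, 1.2, 0.8))
    p <- feature_params("count", 16)
    f <- first_order_features(v, m, p)
    x <- as.numeric(vals)
    n <- length(x)
    mu <- sum(x) / n
    m2 <- sum((x - mu)^2) / n
    q <- unname(quantile(x, c(.1, .25, .5, .75, .9)))
    rob <- x[x >= q[1] & x <= q[5]]
    G <- 16
    lev <- pmin(G, floor((x - min(x)) / ((max(x) - min(x)) / G)) + 1)
    pr <- as.numeric(table(factor(lev, 1:G))) / n
    prp <- pr[pr > 0]
    expected <- c(sum(x^2), prod(c(1, 1.2, 0.8)) * sum(x^2),
                  -sum(prp * log2(prp)), min(x), q[1], q[5], max(x), mu,
                  q[3], q[4] - q[2], max(x) - min(x), sum(abs(x - mu)) / n,
                  sum(abs(rob - mean(rob))) / length(rob), sqrt(sum(x^2) / n),
                  (sum((x - mu)^3) / n) / m2^1.5, (sum((x - mu)^4) / n) / m2^2,
                  m2, sum(pr^2))
    expect_equal(unname(f), expected, tolerance = 1e-9)
    expect_gte(unname(f["firstorder_Entropy"]), 0)
  })
})

test_that("GLCM degenerates cleanly on a single-level region", {
  v <- image_volume(array(4, c(3, 3, 3)))
  m <- binary_mask(array(1, c(3, 3, 3)))
  d <- discretize(v, m, feature_params("count", 8))
  g <- glcm_features(d$levels, m, d$n_levels)
  expect_length(g, 24)
  expect_equal(unname(g["glcm_Autocorrelation"]), 1)
  expect_equal(unname(g["glcm_Contrast"]), 0)
  expect_equal(unname(g["glcm_Correlation"]), 1)
  expect_equal(unname(g["glcm_JointEnergy"]), 1)
  expect_true(attr(g, "degenerate"))
})

test_that("GLCM counts match manual pair enumeration on a 2D slab", {
  # 4 x 4 single-slice lattice, levels laid out by hand
  lev <- array(0L, c(4, 4, 1))
  lev[, , 1] <- matrix(c(1, 2, 2, 3,
                         1, 1, 2, 3,
                         3, 2, 1, 1,
                         2, 2, 3, 1), 4, 4, byrow = TRUE)
  m <- binary_mask(array(1, c(4, 4, 1)))
  P <- nactrad:::cpp_glcm(as.integer(lev), m$values > 0.5, dim(lev), 3L)
  O <- or_glcm(lev, array(TRUE, dim(lev)), 3)
  expect_equal(unname(P), unname(O))
  p <- P / sum(P)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  g <- glcm_features(lev, m, 3L)
  ij <- outer(1:3, 1:3)
  expect_equal(unname(g["glcm_Autocorrelation"]), sum(p * ij))
})

test_that("GLCM and GLRLM features match oracles on random lattices", {
  for (seed in c(71, 72, 73)) {
    cs <- random_levels_case(seed)
    msk_log <- cs$mask$values > 0.5
    P <- nactrad:::cpp_glcm(as.integer(cs$levels), msk_log, dim(cs$levels),
                            cs$G)
    expect_equal(unname(P), unname(or_glcm(cs$levels, msk_log, cs$G)))
    R <- nactrad:::cpp_glrlm(as.integer(cs$levels), msk_log, dim(cs$levels),
                             cs$G)
    runs <- or_glrlm(cs$levels, msk_log, cs$G)
    RO <- matrix(0, cs$G, ncol(R))
    for (r in seq_len(nrow(runs)))
      RO[runs[r, 1], runs[r, 2]] <- RO[runs[r, 1], runs[r, 2]] + 1
    expect_equal(unname(R), unname(RO))
  }
})

test_that("GLRLM run structure is exact on constructed lines", {
  # constant line of length L in an L x 1 x 1 lattice: 3 of the 13
  # directions lie in-plane; the x direction yields one run of length L,
  # the other in-bounds directions yield L runs of length 1
  L <- 7L
  lev <- array(1L, c(L, 1, 1))
  m <- array(TRUE, c(L, 1, 1))
  R <- nactrad:::cpp_glrlm(as.integer(lev), m, dim(lev), 1L)
  expect_equal(R[1, L], 1)          # the single x-direction run
  # alternating two-level line: every direction gives runs of length 1
  lev2 <- array(rep(c(1L, 2L), length.out = L), c(L, 1, 1))
  R2 <- nactrad:::cpp_glrlm(as.integer(lev2), m, dim(lev2), 2L)
  expect_true(all(R2[, -1] == 0))
  expect_equal(sum(R2[, 1]), sum(R2))
})

test_that("GLSZM zones partition the mask and match constructions", {
  cs <- random_levels_case(81)
  msk_log <- cs$mask$values > 0.5
  z <- nactrad:::cpp_glszm_zones(as.integer(cs$levels), msk_log,
                                 dim(cs$levels))
  expect_equal(sum(z[, 2]), sum(msk_log))   # partition identity
  zo <- or_zones(cs$levels, msk_log)
  expect_equal(sort(z[, 2]), sort(zo[, 2]))
  # constant region: exactly one zone of size |mask|
  lev1 <- array(1L, c(4, 4, 4))
  z1 <- nactrad:::cpp_glszm_zones(lev1, array(TRUE, c(4, 4, 4)), c(4, 4, 4))
  expect_equal(dim(z1), c(1L, 2L))
  expect_equal(z1[1, 2], 64L)
  # two disjoint equal-level blobs of sizes 5 and 7
  lev2 <- array(0L, c(10, 3, 3))
  msk2 <- array(FALSE, c(10, 3, 3))
  lev2[1:5, 1, 1] <- 2L; msk2[1:5, 1, 1] <- TRUE
  lev2[8:10, 1, 1] <- 2L; lev2[8:10, 2, 1] <- 2L
  msk2[8:10, 1, 1] <- TRUE; msk2[8:10, 2, 1] <- TRUE
  lev2[8, 3, 1] <- 2L; msk2[8, 3, 1] <- TRUE
  z2 <- nactrad:::cpp_glszm_zones(lev2, msk2, dim(lev2))
  expect_equal(sort(z2[, 2]), c(5L, 7L))
})

test_that("GLDM dependence matches oracles and saturates with alpha", {
  cs <- random_levels_case(91)
  msk_log <- cs$mask$values > 0.5
  for (alpha in c(0, 1)) {
    P <- nactrad:::cpp_gldm(as.integer(cs$levels), msk_log, dim(cs$levels),
                            cs$G, alpha)
    expect_equal(unname(P), unname(or_gldm(cs$levels, msk_log, cs$G, alpha)))
  }
  # alpha covering all levels: dependence = in-mask neighbour count
  Pbig <- nactrad:::cpp_gldm(as.integer(cs$levels), msk_log, dim(cs$levels),
                             cs$G, cs$G)
  deps <- rep(seq_len(27) - 1, colSums(Pbig))
  counts <- integer(0)
  d <- dim(cs$levels)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!msk_log[x, y, z]) next
    cnt <- 0
    for (o in seq_len(nrow(offsets26))) {
      q <- c(x, y, z) + offsets26[o, ]
      if (any(q < 1) || any(q > d)) next
      if (msk_log[q[1], q[2], q[3]]) cnt <- cnt + 1
    }
    counts <- c(counts, cnt)
  }
  expect_equal(sort(deps), sort(counts))
})

test_that("GLDM large dependence high gray-level emphasis is hand-checked", {
  # constant 5x5x5 region: single gray level, dependence = neighbour count
  lev <- array(1L, c(5, 5, 5))
  m <- binary_mask(array(1, c(5, 5, 5)))
  g <- gldm_features(lev, m, 1L, alpha = 0)
  expect_length(g, 14)
  # hand evaluation of sum P(i,j) i^2 j^2 / N with j = dependence size
  d <- c(5L, 5L, 5L)
  sizes <- integer(0)
  for (x in 1:5) for (y in 1:5) for (z in 1:5) {
    cnt <- 0
    for (o in seq_len(nrow(offsets26))) {
      q <- c(x, y, z) + offsets26[o, ]
      if (all(q >= 1) && all(q <= 5)) cnt <- cnt + 1
    }
    sizes <- c(sizes, cnt + 1L)
  }
  expect_equal(unname(g["gldm_LargeDependenceHighGrayLevelEmphasis"]),
               mean(sizes^2))
  # interior voxels all have the full 26-neighbour dependence
  expect_equal(sum(sizes == 27), 27)
})

test_that("extract_all returns the frozen 102-feature vector", {
  withr::with_seed(101, {
    n <- 20
    m <- sphere_mask(n, 6)
    vals <- array(rnorm(n^3, 100, 20), c(n, n, n))
    v <- image_volume(vals)
    f <- extract_all_features(v, m)
    expect_length(f, 102)
    expect_identical(names(f), feature_names())
    fam <- table(sub("_.*", "", names(f)))
    expect_equal(as.numeric(fam[c("shape", "firstorder", "glcm", "glrlm",
                                  "glszm", "gldm")]),
                 c(14, 18, 24, 16, 16, 14))
    expect_true(all(is.finite(f)))
    expect_identical(f, extract_all_features(v, m))
  })
})

test_that("texture features are invariant to joint translation", {
  withr::with_seed(102, {
    n <- 24
    base <- array(rnorm(n^3, 80, 15), c(n, n, n))
    msk <- array(0, c(n, n, n)); msk[6:13, 6:13, 6:13] <- 1
    f1 <- extract_all_features(image_volume(base), binary_mask(msk))
    shifted <- array(0, c(n, n, n)); smsk <- array(0, c(n, n, n))
    shifted[4:n, 2:(n - 2), 3:(n - 1)] <- base[1:(n - 3), 1:(n - 3), 1:(n - 3)]
    smsk[4:n, 2:(n - 2), 3:(n - 1)] <- msk[1:(n - 3), 1:(n - 3), 1:(n - 3)]
    f2 <- extract_all_features(image_volume(shifted), binary_mask(smsk))
    nonshape <- setdiff(names(f1), grep("^shape_", names(f1), value = TRUE))
    expect_equal(f1[nonshape], f2[nonshape], tolerance = 1e-9)
  })
})

test_that("constant inputs produce the dictated degenerate features", {
  v <- image_volume(array(5, c(6, 6, 6)))
  m <- sphere_mask(6, 2.2)
  f <- extract_all_features(v, m)
  expect_equal(unname(f["firstorder_Variance"]), 0)
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["firstorder_Entropy"]), 0)
  expect_equal(unname(f["glcm_JointEnergy"]), 1)
  expect_equal(unname(f["glszm_ZonePercentage"]), 1 / sum(m$values))
})
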