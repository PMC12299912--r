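test_that("the operator SVD reproduces the operator", {
  sv <- fx_svd3d()
  op <- fx_op3d()
  rec <- sv$u %*% diag(sv$d) %*% Conj(t(sv$v))
  relerr <- sqrt(sum(Mod(rec - op$matrix)^2)) / sqrt(sum(Mod(op$matrix)^2))
  expect_lt(relerr, 1e-8)
  expect_lte(length(sv$d), min(55L, ncol(op$matrix)))
  expect_true(all(diff(sv$d) <= 0))
  expect_true(all(sv$d >= 0))
  # column orthonormality of the factors
  expect_equal(Conj(t(sv$u)) %*% sv$u, diag(length(sv$d)) + 0i,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(Conj(t(sv$v)) %*% sv$v, diag(length(sv$d)) + 0i,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("duplicated channels leave singular values matching an eigen oracle", {
  # reciprocity-degenerate toy: a 3-antenna system observed with the full
  # 3 x 3 channel list duplicates every off-diagonal row
  op <- fx_toy_op()
  L6 <- op$matrix[c(1, 2, 3, 11, 12, 20), 1:30]   # rows (1,1),(1,2),(1,3),(2,2),(2,3),(3,3)
  L9 <- L6[c(1, 2, 3, 2, 4, 5, 3, 5, 6), ]        # full 3x3 row-major listing
  d <- svd(L9)$d
  # rank cannot exceed 6: three trailing singular values vanish
  expect_lt(d[7] / d[1], 1e-12)
  # brute-force eigen-decomposition of L L^H gives the squared spectrum
  ev <- sort(Re(eigen(L9 %*% Conj(t(L9)), symmetric = TRUE,
                      only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(d^2, pmax(ev, 0), tolerance = 1e-10)
})

test_that("full-truncation TSVD equals the minimum-norm least-squares solution", {
  # well-conditioned 3-antenna toy: random complex operator on a coarse grid
  g <- imaging_grid(spacing = 40, z = 100)
  N <- nrow(g$centers)
  set.seed(17)
  L <- matrix(complex(real = rnorm(6 * N), imaginary = rnorm(6 * N)), 6, N)
  op <- structure(list(matrix = L, grid = g, k_b = 1 + 0i, c0 = 1,
                       frequency = 1e9), class = "born_operator")
  sv <- decompose(op)
  dS <- complex(real = rnorm(6), imaginary = rnorm(6))
  m <- reconstruct(sv, dS, nT = length(sv$d))
  # independent oracle: normal equations of the fat system, x = L^H (L L^H)^{-1} y
  x <- Conj(t(L)) %*% solve(L %*% Conj(t(L)), dS)
  expect_equal(m$values, drop(x), tolerance = 1e-6)
})

test_that("reconstruction is linear and validates its truncation index", {
  sv <- fx_svd3d()
  z <- reconstruct(sv, complex(55), nT = 50)
  expect_true(all(z$values == 0 + 0i))
  expect_error(reconstruct(sv, complex(55), nT = 0), "between 1 and")
  expect_error(reconstruct(sv, complex(55), nT = 56), "between 1 and")
  expect_error(reconstruct(sv, complex(10), nT = 5), "channels")
})

test_that("noiseless reconstructions localize in-plane strokes within 10 mm", {
  sv <- fx_svd3d()
  op <- fx_op3d()
  cases <- list(list("iStroke", c(20, 30, 100), 40),
                list("hStroke", c(10, 10, 100), 20))
  for (cs in cases) {
    dS <- fx_ds(cs[[1]], cs[[2]], cs[[3]])
    img <- blur_map(reconstruct(sv, dS, nT = 50))
    loc <- localize(img)
    expect_true(loc$detected)
    err <- sqrt(sum((loc$coords[1:2] - cs[[2]][1:2])^2))
    expect_lte(err, 10)
  }
})

test_that("magnitude image is the modulus and is phase invariant", {
  grid <- fx_grid2d()
  v <- complex(real = stats::rnorm(nrow(grid$centers)),
               imaginary = stats::rnorm(nrow(grid$centers)))
  m <- contrast_map(v, grid)
  expect_equal(magnitude_image(m)$values, Mod(v))
  rot <- contrast_map(v * exp(0.77i), grid)
  expect_equal(magnitude_image(rot)$values, magnitude_image(m)$values,
               tolerance = 1e-12)
  z <- contrast_map(complex(nrow(grid$centers)), grid)
  expect_true(all(magnitude_image(z)$values == 0))
  # direct modulus on a hand-checked toy triple
  tri <- c(3 + 4i, -1 + 0i, 0 - 2i)
  expect_identical(Mod(tri), c(5, 1, 2))
})

test_that("the 3x3 box blur averages with reflect padding", {
  const <- matrix(2.5, 7, 6)
  expect_equal(box_blur(const), const)
  spike <- matrix(0, 7, 7); spike[4, 4] <- 9
  b <- box_blur(spike)
  expect_equal(b[3:5, 3:5], matrix(1, 3, 3))
  expect_true(all(b[-(3:5), ] == 0) && all(b[, -(3:5)] == 0))
  # mass preservation for compactly supported interior input
  img <- matrix(0, 9, 9); img[4:6, 4:6] <- matrix(runif(9), 3, 3)
  expect_equal(sum(box_blur(img)), sum(img), tolerance = 1e-12)
  expect_error(box_blur(matrix(1, 2, 5)), "at least 3 x 3")
})

test_that("localization is deterministic with documented tie-breaks", {
  grid <- fx_grid2d()
  v <- numeric(nrow(grid$centers))
  v[100] <- 1
  loc <- localize(contrast_map(v, grid, kind = "magnitude"))
  expect_equal(loc$coords, as.numeric(grid$centers[100, ]))
  # symmetric two-peak tie: the lower voxel index wins
  v[200] <- 1
  loc2 <- localize(contrast_map(v, grid, kind = "magnitude"))
  expect_equal(loc2$coords, as.numeric(grid$centers[100, ]))
  # all-zero image: flagged, no coordinate
  loc3 <- localize(contrast_map(numeric(nrow(grid$centers)), grid,
                                kind = "magnitude"))
  expect_false(loc3$detected)
  expect_null(loc3$coords)
})

test_that("peak contrast tracks stroke size and depth", {
  sv <- fx_svd3d()
  peak <- function(lab, ctr, d)
    localize(blur_map(reconstruct(sv, fx_ds(lab, ctr, d), nT = 50)))$value
  p20 <- peak("iStroke", c(20, 30, 100), 20)
  p40 <- peak("iStroke", c(20, 30, 100), 40)
  expect_gt(p40, p20)
  # deeper stroke reconstructs weaker
  expect_lt(peak("iStroke", c(10, 10, 100), 20), p20)
  # out-of-plane stroke reconstructs weaker than in-plane
  expect_lt(peak("iStroke", c(20, 30, 70), 40), p40)
})

test_that("single-ring reconstructions are mirror symmetric about the ring", {
  # antennas all at z = 100: operator columns for (x, y, 100 - t) and
  # (x, y, 100 + t) are identical, so the inversion cannot tell them apart
  sv <- fx_svd3d()
  m <- magnitude_image(reconstruct(sv, fx_ds("iStroke", c(20, 30, 70), 40),
                                   nT = 50))
  g <- m$grid
  lo <- m$values[abs(g$centers[, 3] - 70) < 1e-9]
  hi <- m$values[abs(g$centers[, 3] - 130) < 1e-9]
  expect_equal(lo, hi, tolerance = 1e-8)
})

test_that("the truncation sweep shows the TSVD residual/norm trade-off", {
  sv <- fx_svd3d()
  dS <- fx_ds("hStroke", c(20, 30, 100), 30)
  # noisy data: perturb with a fixed draw
  set.seed(99)
  std <- 0.05 * sqrt(mean(Mod(dS)^2))
  noisy <- dS + complex(real = rnorm(55, 0, std / sqrt(2)),
                        imaginary = rnorm(55, 0, std / sqrt(2)))
  tab <- truncation_sweep(sv, noisy, nT_list = c(1, 5, 10, 20, 35, 50, 55))
  expect_true(all(diff(tab$residual) <= 1e-12))
  expect_true(all(diff(tab$solution_norm) >= -1e-12))
  # brute-force recomputation from the SVD factors for three indices
  for (nT in c(5, 20, 50)) {
    coef <- drop(Conj(t(sv$u[, 1:nT])) %*% noisy) / sv$d[1:nT]
    x <- drop(sv$v[, 1:nT] %*% coef)
    expect_equal(tab$residual[tab$nT == nT],
                 sqrt(sum(Mod(fx_op3d()$matrix %*% x - noisy)^2)),
                 tolerance = 1e-10)
    expect_equal(tab$solution_norm[tab$nT == nT], sqrt(sum(Mod(x)^2)),
                 tolerance = 1e-10)
  }
})
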