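test_that("background wavenumber matches the closed-form square root", {
  # vacuum: 2 pi f / c oracle
  expect_equal(background_wavenumber(medium(1, 0), 1e9), 20.958 + 0i,
               tolerance = 1e-3)
  # head medium: frozen from k0 * sqrt(41.40 - 18.694i), principal branch
  kb <- background_wavenumber(head_media()$head, 1e9)
  expect_equal(kb, complex(real = 138.0914, imaginary = -29.7321),
               tolerance = 1e-5)
  # branch condition for arbitrary lossy media
  for (s in c(0, 0.1, 1, 3, 10)) {
    k <- background_wavenumber(medium(30, s), 1e9)
    expect_gt(Re(k), 0)
    expect_lte(Im(k), 0)
  }
})

test_that("the point-source field obeys 1/R amplitude and lossy decay", {
  k_real <- background_wavenumber(medium(4, 0), 1e9)
  a <- c(0, 0, 0)
  g1 <- antenna_field(a, c(50, 0, 0), k_real)
  g2 <- antenna_field(a, c(100, 0, 0), k_real)
  expect_equal(Mod(g1) / Mod(g2), 2, tolerance = 1e-12)

  kb <- background_wavenumber(head_media()$head, 1e9)
  rr <- seq(20, 150, by = 10)
  gmag <- vapply(rr, function(r) Mod(antenna_field(a, c(r, 0, 0), kb)),
                 numeric(1))
  expect_true(all(diff(gmag) < 0))
  # hand evaluation at R = 0.05 m in the head medium (frozen oracle value)
  expect_equal(antenna_field(a, c(50, 0, 0), kb),
               complex(real = 0.292634, imaginary = -0.209526),
               tolerance = 1e-5)
  expect_error(antenna_field(a, a, kb), "singular")
})

test_that("operator entries equal the Green's-function product formula", {
  op <- fx_toy_op()
  grid <- op$grid
  expect_identical(dim(op$matrix), c(55L, nrow(grid$centers)))
  kb <- op$k_b
  arr <- default_array()
  ch <- channel_pairs()
  dV <- grid$voxel_volume * 1e-9
  for (row in c(1L, 17L, 55L)) for (v in c(1L, nrow(grid$centers) %/% 2L)) {
    m <- ch[row, 1]; n <- ch[row, 2]
    want <- op$c0 * kb^2 * dV *
      antenna_field(arr$positions[m, ], grid$centers[v, ], kb) *
      antenna_field(arr$positions[n, ], grid$centers[v, ], kb)
    expect_equal(op$matrix[row, v], want, tolerance = 1e-12)
  }
})

test_that("operator rows are reciprocal and scale with the calibration", {
  grid <- fx_grid2d()
  arr <- default_array()
  op1 <- assemble_operator(arr, grid, c0 = 1)
  op2 <- assemble_operator(arr, grid, c0 = 2)
  expect_equal(op2$matrix, 2 * op1$matrix, tolerance = 1e-14)
  # reciprocity by construction: the (m,n) row is symmetric in m and n,
  # checked through the synthesized S-matrix being exactly symmetric
  dS <- fx_ds("hStroke", c(20, 30, 100), 30)
  s <- synthesize_smatrix(default_background_smatrix(), dS,
                          noise_level = 0.05, seed = 11)
  expect_identical(s$entries, t(s$entries))
})

test_that("near-antenna voxels dominate channels involving that antenna", {
  op <- fx_op3d()
  grid <- op$grid
  arr <- default_array()
  ctr <- which.min(rowSums(grid$centers[, 1:2]^2) +
                     (grid$centers[, 3] - 100)^2)
  # voxel ~10 mm inward of antenna 1
  a1 <- arr$positions[1, ]
  tgt <- c(a1[1:2] * (1 - 12 / sqrt(sum(a1[1:2]^2))), 100)
  near <- which.min(colSums((t(grid$centers) - tgt)^2))
  ch <- channel_pairs()
  rows <- which(ch[, 1] == 1L | ch[, 2] == 1L)
  expect_true(all(Mod(op$matrix[rows, ctr]) < Mod(op$matrix[rows, near])))
})

test_that("forward scattering is linear and matches a brute-force sum", {
  op <- fx_op3d()
  grid <- op$grid
  zmap <- true_contrast(stroke_scenario("noStroke"), grid)
  expect_identical(forward_dS(op, zmap), complex(55))

  sc <- stroke_scenario("iStroke", center = c(20, 30, 100), diameter = 20)
  cm <- true_contrast(sc, grid)
  dS <- forward_dS(op, cm)
  cm2 <- contrast_map(2 * cm$values, grid)
  expect_equal(forward_dS(op, cm2), 2 * dS, tolerance = 1e-14)

  # independent brute force: per-voxel Green's-function products summed
  # directly, bypassing the assembled operator matrix
  kb <- op$k_b
  arr <- default_array()
  idx <- which(Mod(cm$values) > 0)
  ch <- channel_pairs()
  dV <- grid$voxel_volume * 1e-9
  brute <- complex(55)
  for (r in 1:55) {
    gm <- vapply(idx, function(v)
      antenna_field(arr$positions[ch[r, 1], ], grid$centers[v, ], kb),
      complex(1))
    gn <- vapply(idx, function(v)
      antenna_field(arr$positions[ch[r, 2], ], grid$centers[v, ], kb),
      complex(1))
    brute[r] <- sum(kb^2 * dV * gm * gn * cm$values[idx])
  }
  expect_equal(dS, brute, tolerance = 1e-10)
})

test_that("differential signal grows with stroke diameter and proximity", {
  nrm <- function(v) sqrt(sum(Mod(v)^2))
  n20 <- nrm(fx_ds("iStroke", c(20, 30, 100), 20))
  n30 <- nrm(fx_ds("iStroke", c(20, 30, 100), 30))
  n40 <- nrm(fx_ds("iStroke", c(20, 30, 100), 40))
  expect_lt(n20, n30)
  expect_lt(n30, n40)
  # deeper (closer to center) stroke scatters less into the array
  expect_lt(nrm(fx_ds("iStroke", c(10, 10, 100), 20)), n20)
  # out-of-plane stroke scatters less than the same stroke in-plane
  expect_lt(nrm(fx_ds("hStroke", c(20, 30, 70), 40)),
            nrm(fx_ds("hStroke", c(20, 30, 100), 40)))
})

test_that("stroke types point into opposite complex half-planes", {
  di <- fx_ds("iStroke", c(20, 30, 100), 30)
  dh <- fx_ds("hStroke", c(20, 30, 100), 30)
  j <- which.max(Mod(di))
  # angle between the dominant-channel phasors exceeds 90 degrees
  expect_lt(Re(di[j] * Conj(dh[j])), 0)
})

test_that("synthesized S-matrices are reproducible with calibrated noise", {
  bg <- default_background_smatrix()
  # zero noise, zero signal: exact identity
  s0 <- synthesize_smatrix(bg, complex(55), noise_level = 0)
  expect_identical(s0$entries, bg$entries)

  dS <- fx_ds("hStroke", c(0, 40, 100), 30)
  s1 <- synthesize_smatrix(bg, dS, noise_level = 0.02, seed = 42)
  s2 <- synthesize_smatrix(bg, dS, noise_level = 0.02, seed = 42)
  expect_identical(s1$entries, s2$entries)
  s3 <- synthesize_smatrix(bg, dS, noise_level = 0.02, seed = 43)
  expect_false(identical(s1$entries, s3$entries))

  # Monte-Carlo noise calibration: per-entry complex std within 5%
  std_req <- 0.02 * sqrt(mean(Mod(dS)^2))
  set.seed(7)
  devs <- replicate(200, {
    s <- synthesize_smatrix(bg, dS, noise_level = 0.02)
    pack_channels(s) - pack_channels(bg) - dS
  })
  expect_equal(sqrt(mean(Mod(devs)^2)), std_req, tolerance = 0.05)
})
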