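test_that("edge-stopping map is 1 on flat regions and dips on edges", {
  cst <- matrix(0.5, 30, 30)
  expect_equal(edge_stop_map(cst), matrix(1, 30, 30))

  step <- matrix(0.2, 40, 40); step[, 21:40] <- 0.8
  g <- edge_stop_map(step, edge_sigma = 1.5)
  # minimum attained on the edge line (columns 20/21), in every row
  min_cols <- apply(g[5:36, ], 1L, which.min)
  expect_true(all(min_cols %in% 20:21))
  # strictly decreasing in gradient magnitude: scale the contrast up
  g2 <- edge_stop_map(0.2 + 2 * (step - 0.2), edge_sigma = 1.5)
  expect_lt(min(g2), min(g))
})

test_that("local means recover the two tones of a split image and agree
           with hand enumeration at radius 1", {
  n <- 40
  img <- matrix(0.3, n, n); img[, 21:n] <- 0.9
  phi <- matrix(rep(seq_len(n) - 20.5, each = n), n)   # inside = left half
  lm <- local_means(img, level_set(phi), local_radius = 5)
  band <- abs(phi) < 3
  expect_equal(lm$u[band], rep(0.3, sum(band)), tolerance = 1e-12)
  expect_equal(lm$v[band], rep(0.9, sum(band)), tolerance = 1e-12)

  # uniform image: u = v everywhere
  uni <- matrix(0.42, 15, 15)
  lmu <- local_means(uni, level_set(phi[1:15, 1:15]), 3)
  expect_equal(lmu$u, lmu$v, tolerance = 1e-12)

  # radius 1: plus-shaped neighbourhood of <= 5 pixels, hand enumerated
  img2 <- matrix(0.2, 7, 7); img2[4, 4] <- 1
  phi2 <- matrix(1, 7, 7); phi2[4, 4] <- -1   # single interior pixel
  lm2 <- local_means(img2, level_set(phi2), 1)
  expect_equal(lm2$u[4, 4], 1)                       # only itself inside
  expect_equal(lm2$v[4, 4], mean(rep(0.2, 4)))       # its 4 neighbours
  expect_equal(lm2$u[4, 3], 1)                       # ball contains (4,4)
  expect_equal(lm2$v[4, 3], mean(c(0.2, 0.2, 0.2, 0.2)))
})

test_that("curvature matches closed forms on circles, lines and ellipses", {
  phi <- exact_circle_sdf(101, 20)
  k <- curvature(phi)
  zero_band <- abs(phi) <= 0.5
  expect_true(all(abs(k[zero_band] - 0.05) <= 0.05 * 0.05))

  straight <- matrix(rep(seq_len(60) - 30.5, each = 60), 60)
  expect_lt(max(abs(curvature(straight)[10:50, 10:50])), 1e-3)

  # ellipse level function: curvature extremes at the vertices
  a <- 30; b <- 18; n <- 101
  f <- outer(seq_len(n) - 51, seq_len(n) - 51,
             function(y, x) sqrt((y / a)^2 + (x / b)^2)) - 1
  kf <- curvature(f)
  on_ell <- abs(f) < 0.005
  pts <- which(on_ell, arr.ind = TRUE)
  kv <- kf[on_ell]
  # closed-form ellipse curvature at co-vertex (y=+-a): a/b^2; vertex: b/a^2
  co_vertex <- pts[which.max(abs(pts[, 1] - 51)), ]
  vertex <- pts[which.max(abs(pts[, 2] - 51)), ]
  expect_equal(kf[co_vertex[1], co_vertex[2]], a / b^2, tolerance = 0.1)
  expect_equal(kf[vertex[1], vertex[2]], b / a^2, tolerance = 0.1)
  expect_equal(max(kv), a / b^2, tolerance = 0.1)
  expect_equal(min(kv), b / a^2, tolerance = 0.1)
})

test_that("area-change rule stops exactly when the difference drops below
           the threshold", {
  areas <- c(10000, 10210, 10214)
  # replay the checks as evolve would: halt at the third check
  halted_at <- NA_integer_
  for (i in seq_along(areas))
    if (area_converged(areas[seq_len(i)], area_tol = 10)) {
      halted_at <- i; break
    }
  expect_equal(halted_at, 3L)
  expect_false(area_converged(c(10000, 10210), 10))
  expect_true(area_converged(c(10214, 10210), 10))   # |diff| = 4 < 10
})

test_that("evolution respects max_iters = 0 and is deterministic", {
  ph <- unit_phantom(seed = 7L)
  px <- preprocess_slice(ph$volume$voxels[, , 1])$image
  phi0 <- sdf_from_mask(circle_mask(192, 30))
  out0 <- evolve(px, phi0, snake_params(max_iters = 0L))
  expect_identical(out0$ls$phi, phi0$phi)
  expect_equal(out0$trace$stop_reason, "max_iters")
  expect_equal(out0$trace$n_iters, 0L)

  p <- snake_params(max_iters = 30L)
  r1 <- evolve(px, phi0, p)
  r2 <- evolve(px, phi0, p)
  expect_identical(r1$ls$phi, r2$ls$phi)
  expect_identical(r1$trace$areas, r2$trace$areas)
})

test_that("pure balloon inflation grows the contour monotonically", {
  uni <- matrix(0.5, 128, 128)
  phi0 <- sdf_from_mask(circle_mask(128, 20))
  out <- evolve(uni, phi0, snake_params(balloon_weight = 0.5,
                                        curvature_weight = 0,
                                        max_iters = 60L,
                                        area_tol = 1e-9))
  expect_true(all(diff(out$trace$areas) > 0))
})

test_that("pure curvature flow shrinks a circle at the curve-shortening
           rate", {
  uni <- matrix(0.5, 128, 128)
  # exact signed distance: curvature estimates are clean from the start
  phi0 <- level_set(exact_circle_sdf(128, 35))
  dt <- 0.25
  out <- evolve(uni, phi0, snake_params(balloon_weight = 0,
                                        curvature_weight = 1,
                                        step_size = dt,
                                        max_iters = 200L,
                                        check_interval = 20L,
                                        area_tol = 1e-9))
  ar <- out$trace$areas
  # mean dA/dt over the run: -2*pi in the curve-shortening limit (area
  # counting quantizes individual checks, so the mean is the estimator)
  rate <- (ar[length(ar)] - ar[1]) / ((length(ar) - 1) * 20 * dt)
  expect_lt(abs(rate - (-2 * pi)), 0.15 * 2 * pi)
})

test_that("contour locks onto a strong dark ring (muscle-wall analogue)", {
  n <- 160; ctr <- (n + 1) / 2
  r <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
             function(y, x) sqrt(y^2 + x^2))
  img <- matrix(0.8, n, n)
  img[r >= 45 & r <= 49] <- 0.15      # dark ring
  phi0 <- sdf_from_mask(r <= 25)
  out <- evolve(img, phi0, snake_params())
  expect_equal(out$trace$stop_reason, "area_converged")
  # contour (inside pixels touching outside) within 2 px of the ring for
  # >= 95% of boundary points
  inside <- out$ls$phi < 0
  bnd <- inside & !(inside[c(1, 1:(n - 1)), ] & inside[c(2:n, n), ] &
                    inside[, c(1, 1:(n - 1))] & inside[, c(2:n, n)])
  pts <- which(bnd, arr.ind = TRUE)
  rad <- sqrt((pts[, 1] - ctr)^2 + (pts[, 2] - ctr)^2)
  expect_gte(mean(rad >= 43 & rad <= 51), 0.95)
})

test_that("contour collapse and border contact are reported as errors", {
  uni <- matrix(0.5, 96, 96)
  tiny <- sdf_from_mask(circle_mask(96, 3))
  expect_error(
    evolve(uni, tiny, snake_params(balloon_weight = 0,
                                   curvature_weight = 2,
                                   max_iters = 400L, area_tol = 1e-9)),
    "collapsed")
  big <- sdf_from_mask(circle_mask(96, 40))
  expect_error(
    evolve(uni, big, snake_params(balloon_weight = 1,
                                  curvature_weight = 0,
                                  max_iters = 400L, area_tol = 1e-9)),
    "containment")
})

test_that("snake parameter validation rejects degenerate settings", {
  expect_error(snake_params(area_tol = 0), "positive")
  expect_error(snake_params(local_radius = 0), ">= 1")
  expect_error(snake_params(balloon_weight = -1), "non-negative")
})
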