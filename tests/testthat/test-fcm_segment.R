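test_that("fcm separates well-separated groups almost hard", {
  set.seed(51)
  x <- c(rnorm(40, 0.2, 0.005), rnorm(40, 0.9, 0.005))
  fit <- fcm(x, 2)
  own <- ifelse(x < 0.5, fit$memberships[, 1], fit$memberships[, 2])
  expect_true(all(own >= 0.99))
  expect_lt(abs(fit$centroids[1] - mean(x[x < 0.5])) / 0.2, 0.01)
  expect_lt(abs(fit$centroids[2] - mean(x[x > 0.5])) / 0.9, 0.01)
})

test_that("fcm degenerates to the data mean with one class and validates
           input", {
  x <- runif(30)
  fit <- fcm(x, 1)
  expect_equal(fit$centroids, mean(x))
  expect_true(all(fit$memberships == 1))

  expect_error(fcm(c(1, 1, 1, 2), 3), "distinct")
  expect_error(fcm(runif(10), 2, fuzzifier_m = 1), "> 1")
})

test_that("fcm memberships sum to one, objective never increases, and the
           fit matches the textbook oracle", {
  set.seed(52)
  x <- runif(50)
  for (k in c(3L, 5L)) {
    fit <- fcm(x, k, tol = 1e-10, max_iter = 2000)
    expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
    expect_true(all(diff(fit$objective) <= 1e-12))
    orc <- fcm_oracle(x, k, m = 2, tol = 1e-10)
    expect_equal(fit$centroids, orc$centroids, tolerance = 1e-6)
    expect_lt(max(abs(fit$memberships - orc$memberships)), 1e-6)
  }
})

test_that("fcm agrees with the reference implementation in e1071", {
  skip_if_not_installed("e1071")
  set.seed(53)
  x <- c(rnorm(30, 0.3, 0.05), rnorm(30, 0.7, 0.05))
  fit <- fcm(x, 3, tol = 1e-10, max_iter = 2000)
  ref <- e1071::cmeans(matrix(x), centers = matrix(fit$centroids), m = 2,
                       iter.max = 2000)
  expect_equal(sort(as.numeric(ref$centers)), fit$centroids,
               tolerance = 1e-6)
})

test_that("fcm is reproducible and equivariant under voxel permutation", {
  set.seed(54)
  x <- runif(80)
  f1 <- fcm(x, 3, seed = 9L)
  f2 <- fcm(x, 3, seed = 9L)
  expect_identical(f1$memberships, f2$memberships)

  perm <- sample(length(x))
  fp <- fcm(x[perm], 3, seed = 9L)
  expect_equal(fp$memberships, f1$memberships[perm, ], tolerance = 1e-12)
  expect_equal(fp$centroids, f1$centroids, tolerance = 1e-12)
})

test_that("hardening takes the maximum membership and breaks ties toward
           the brighter class", {
  fit <- structure(list(memberships = rbind(c(0.7, 0.3), c(0.5, 0.5),
                                            c(0.2, 0.8)),
                        centroids = c(0.2, 0.8), objective = 0,
                        n_iters = 1L, fuzzifier_m = 2),
                   class = "fcm_fit")
  expect_equal(harden(fit), c(1L, 2L, 2L))
})

test_that("region merging follows the intensity-gap + adjacency rule", {
  # three vertical bands: means 0.9 | 0.85 | 0.2, bands 1-2 adjacent
  px <- cbind(matrix(0.9, 6, 2), matrix(0.85, 6, 2), matrix(0.2, 6, 2))
  cm <- cbind(matrix(3L, 6, 2), matrix(2L, 6, 2), matrix(1L, 6, 2))
  merged <- merge_regions(cm, px, intensity_gap = 0.1)
  expect_true(all(merged[, 1:4]))
  expect_false(any(merged[, 5:6]))

  # all classes within the gap but one not adjacent -> excluded
  px2 <- cbind(matrix(0.9, 6, 2), matrix(0.86, 6, 2), matrix(0.88, 6, 2))
  cm2 <- cbind(matrix(3L, 6, 2), matrix(1L, 6, 2), matrix(2L, 6, 2))
  merged2 <- merge_regions(cm2, px2, intensity_gap = 0.1)
  expect_true(all(merged2[, 1:4]))     # class 1 touches the anchor
  expect_false(any(merged2[, 5:6]))    # class 2 within gap but detached
  # with adjacency off it joins
  merged3 <- merge_regions(cm2, px2, intensity_gap = 0.1,
                           require_adjacency = FALSE)
  expect_true(all(merged3))
})

test_that("merged fat mask stays inside the partition support and VAT
           recovery on the phantom clears Dice 0.85", {
  ph <- unit_phantom(seed = 8L)
  px <- ph$volume$voxels[, , 1]
  tr <- ph$labels$labels[, , 1]
  vat_side <- tr %in% c(2L, 4L)
  fit <- fcm(px[vat_side], 5)
  cm <- matrix(NA_integer_, nrow(px), ncol(px))
  cm[vat_side] <- harden(fit)
  mask <- merge_regions(cm, px, 0.15)
  expect_true(all(vat_side[mask]))     # mask within clustered support
  expect_gte(dice(mask, tr == 2L), 0.85)
})

test_that("fcm centroids recover the phantom tissue means within the
           noise scale when the field is homogeneous", {
  ph <- unit_phantom(seed = 9L, bias_amplitude = 0)
  px <- ph$volume$voxels[, , 1]
  tr <- ph$labels$labels[, , 1]
  f5 <- fcm(px[tr %in% c(2L, 4L)], 5)
  expect_lt(min(abs(f5$centroids - 0.85)), 0.03)   # VAT
  expect_lt(min(abs(f5$centroids - 0.35)), 0.03)   # organ
  f3 <- fcm(px[tr %in% c(1L, 3L)], 3)
  expect_lt(min(abs(f3$centroids - 0.90)), 0.03)   # SAT
})

test_that("skin/wall stripping removes the documented bands and nothing
           else", {
  ph <- unit_phantom(seed = 10L, noise_sigma = 0, bias_amplitude = 0)
  tr <- ph$labels$labels[, , 1]
  body <- tr > 0
  # fat mask straight from truth: SAT ring plus the skin and wall bands,
  # emulating FCM output that could not separate them
  d_in <- as.matrix(EBImage::distmap(matrix(as.numeric(body), nrow(body))))
  sat_plus <- tr == 1L | (body & d_in <= 2)                 # skin leak
  wall_ls <- sdf_from_mask(body & d_in > 11)                # contour at wall
  sat_plus <- sat_plus | (body & abs(wall_ls$phi) < 2)      # wall leak

  # zero depths: identity
  expect_identical(strip_skin_wall(sat_plus, body, wall_ls, 0, 0), sat_plus)

  stripped <- strip_skin_wall(sat_plus, body, wall_ls,
                              skin_depth = 2, wall_depth = 2)
  residual <- sum(stripped & tr == 3L) / sum(stripped)
  expect_lt(residual, 0.01)

  expect_warning(out <- strip_skin_wall(matrix(FALSE, 192, 192), body,
                                        wall_ls, 2, 2), "empty")
  expect_false(any(out))
})

test_that("the intensity guard keeps fat-bright voxels inside the wall
           band", {
  ph <- unit_phantom(seed = 10L, noise_sigma = 0, bias_amplitude = 0)
  tr <- ph$labels$labels[, , 1]
  body <- tr > 0
  px <- ph$volume$voxels[, , 1]
  d_in <- as.matrix(EBImage::distmap(matrix(as.numeric(body), nrow(body))))
  # contour sitting at the wall/SAT interface: band overlaps true SAT
  wall_ls <- sdf_from_mask(body & d_in > 8)
  sat_mask <- tr == 1L
  blind <- strip_skin_wall(sat_mask, body, wall_ls, 0, 2)
  guarded <- strip_skin_wall(sat_mask, body, wall_ls, 0, 2,
                             pixels = px, fat_floor = 0.65)
  expect_lt(sum(blind), sum(sat_mask))       # geometric band eats SAT
  expect_equal(guarded, sat_mask)            # guard retains bright voxels
})
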