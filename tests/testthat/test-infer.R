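test_that("patch enumeration matches the per-axis start oracle", {
  # grid 64, patch 32, overlap 0.5: starts 0, 16, 32 per axis -> 27 patches
  specs <- enumerate_patches(c(64, 64, 64), c(32, 32, 32), 0.5)
  starts <- unique(t(vapply(specs, `[[`, integer(3), "origin")))
  expect_length(specs, 27)
  expect_setequal(unique(starts[, 1]), c(0L, 16L, 32L))

  # exhaustive per-axis oracle for assorted sizes
  axis_oracle <- function(n, p, ov) {
    step <- max(1, ceiling(p * (1 - ov)))
    s <- unique(c(seq(0, n - p, by = step),
                  if (tail(seq(0, n - p, by = step), 1) != n - p) n - p))
    sort(s)
  }
  for (case in list(c(48, 32), c(33, 16), c(10, 10), c(20, 8))) {
    n <- case[1]; p <- case[2]
    got <- enumerate_patches(c(n, 8, 8), c(p, 8, 8), 0.5)
    xs <- sort(unique(vapply(got, function(s) s$origin[1], integer(1))))
    expect_equal(xs, as.integer(axis_oracle(n, p, 0.5)))
  }

  # overlap 0 tiles the grid as a partition
  t0 <- enumerate_patches(c(64, 64, 64), c(32, 32, 32), 0)
  expect_length(t0, 8)
  xs <- sort(unique(vapply(t0, function(s) s$origin[1], integer(1))))
  expect_equal(xs, c(0L, 32L))
})

test_that("roi filtering keeps exactly the intersecting patches", {
  roi <- array(0L, dim = c(64, 64, 64)); roi[1, 1, 1] <- 1L
  kept <- enumerate_patches(c(64, 64, 64), c(32, 32, 32), 0.5,
                            roi = labelmap(roi))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$origin, c(0L, 0L, 0L))
  empty <- labelmap(array(0L, dim = c(64, 64, 64)))
  expect_error(enumerate_patches(c(64, 64, 64), c(32, 32, 32), 0.5,
                                 roi = empty), "empty")
})

test_that("the Gaussian kernel is centred, symmetric, positive, and flattens as sigma grows", {
  k <- gaussian_kernel(c(8, 8, 4), sigma_scale = 1 / 8)
  expect_equal(max(k), 1)
  expect_true(all(k > 0))
  # maximum at the centre (even sizes peak on the central voxel pair)
  peaks <- which(k == max(k), arr.ind = TRUE)
  expect_true(all(peaks[, 1] %in% 4:5))
  expect_true(all(peaks[, 2] %in% 4:5))
  expect_true(all(peaks[, 3] %in% 2:3))
  # mirror symmetry through the centre
  expect_equal(k, k[8:1, , ], tolerance = 1e-12)
  expect_equal(k, k[, 8:1, ], tolerance = 1e-12)
  expect_equal(k, k[, , 4:1], tolerance = 1e-12)
  flat <- gaussian_kernel(c(8, 8, 8), sigma_scale = 100)
  expect_true(all(abs(flat - 1) < 1e-3))
})

toy_case <- function(seed = 1, shape = c(48, 48, 32)) {
  make_case(phantom_params(shape = shape, seed = seed), "t")$mid
}

test_that("a constant-logit predictor yields a uniform label where covered", {
  case <- toy_case()
  const <- function(x) {
    d <- dim(x)[1:3]
    out <- array(0, dim = c(d, 3))
    out[, , , 2] <- 5  # favour class label 1 everywhere
    out
  }
  pred <- sliding_window_predict(const, case, channel_recipe(),
                                 patch = c(16, 16, 16), overlap = 0.5)
  expect_true(all(pred$labels == 1L))
  masked <- sliding_window_predict(const, case, channel_recipe(),
                                   patch = c(16, 16, 16), overlap = 0.5,
                                   roi = case$prior_mask)
  pr <- sliding_window_probs(const, case, channel_recipe(),
                             patch = c(16, 16, 16), overlap = 0.5,
                             roi = case$prior_mask)
  expect_true(all(masked$labels[pr$covered] == 1L))
  expect_true(all(masked$labels[!pr$covered] == 0L))
})

test_that("unmasked plans cover every voxel and blended probabilities sum to one", {
  set.seed(2)
  case <- toy_case(seed = 2)
  net <- build_network(net_config(n_stages = 2, base_channels = 2))
  pr <- sliding_window_probs(net, case, channel_recipe(),
                             patch = c(16, 16, 16), overlap = 0.5)
  expect_true(all(pr$covered))
  sums <- pr$prob[, , , 1] + pr$prob[, , , 2] + pr$prob[, , , 3]
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("masked and unmasked inference agree exactly on roi voxels", {
  # agreement is guaranteed wherever the covering-patch sets coincide --
  # in particular on every roi voxel, since any patch covering an roi
  # voxel intersects the roi and is therefore retained by the masked plan
  set.seed(3)
  case <- toy_case(seed = 3)
  net <- build_network(net_config(n_stages = 2, base_channels = 2))
  full <- sliding_window_predict(net, case, channel_recipe(),
                                 patch = c(16, 16, 16), overlap = 0.5)
  masked <- sliding_window_predict(net, case, channel_recipe(),
                                   patch = c(16, 16, 16), overlap = 0.5,
                                   roi = case$prior_mask)
  pr <- sliding_window_probs(net, case, channel_recipe(),
                             patch = c(16, 16, 16), overlap = 0.5,
                             roi = case$prior_mask)
  roi_vox <- case$prior_mask$labels > 0L
  expect_identical(masked$labels[roi_vox], full$labels[roi_vox])
  expect_true(all(masked$labels[!pr$covered] == 0L))

  # an roi covering the whole grid reproduces the unmasked result exactly
  whole <- labelmap(array(1L, dim = dim(case$image$data)), case$image$spacing)
  same <- sliding_window_predict(net, case, channel_recipe(),
                                 patch = c(16, 16, 16), overlap = 0.5,
                                 roi = whole)
  expect_identical(same$labels, full$labels)
})

test_that("an empty roi falls back to unmasked inference with a warning", {
  set.seed(4)
  case <- toy_case(seed = 4)
  net <- build_network(net_config(n_stages = 2, base_channels = 2))
  empty <- labelmap(array(0L, dim = dim(case$image$data)), case$image$spacing)
  expect_warning(
    pred <- sliding_window_predict(net, case, channel_recipe(),
                                   patch = c(16, 16, 16), roi = empty),
    "unmasked")
  full <- sliding_window_predict(net, case, channel_recipe(),
                                 patch = c(16, 16, 16))
  expect_identical(pred$labels, full$labels)
})

test_that("volumes smaller than the patch are padded and cropped back", {
  case <- make_case(phantom_params(shape = c(24, 24, 12), seed = 6,
                                   gtvp_radius_range = c(4, 5),
                                   gtvn_radius_range = c(2, 3)), "small")$mid
  const <- function(x) {
    d <- dim(x)[1:3]
    out <- array(0, dim = c(d, 3)); out[, , , 3] <- 1
    out
  }
  pred <- sliding_window_predict(const, case, channel_recipe(),
                                 patch = c(32, 32, 32))
  expect_equal(dim(pred$labels), c(24, 24, 12))
  expect_true(all(pred$labels == 2L))
})

test_that("channel-count mismatches between recipe and network are refused", {
  set.seed(5)
  case <- toy_case(seed = 5)
  net <- build_network(net_config(n_stages = 2, base_channels = 2,
                                  in_channels = 3))
  expect_error(sliding_window_predict(net, case, channel_recipe(),
                                      patch = c(16, 16, 16)), "channels")
})

test_that("inference is equivariant under volume flips of an equivariant predictor", {
  # hand-built voxelwise predictor (logits depend only on local intensity),
  # exactly flip-equivariant; the sliding-window machinery must preserve that
  case <- toy_case(seed = 7)
  vox <- function(x) {
    d <- dim(x)[1:3]
    out <- array(0, dim = c(d, 3))
    out[, , , 2] <- x[, , , 1]         # bright voxels -> GTVp
    out[, , , 1] <- 1 - x[, , , 1]
    out
  }
  pred <- sliding_window_predict(vox, case, channel_recipe(),
                                 patch = c(16, 16, 16), overlap = 0.5)
  flipped_case <- case
  flipped_case$image$data <- case$image$data[dim(case$image$data)[1]:1, , ]
  flipped_case$reference$labels <-
    case$reference$labels[dim(case$reference$labels)[1]:1, , ]
  pred_f <- sliding_window_predict(vox, flipped_case, channel_recipe(),
                                   patch = c(16, 16, 16), overlap = 0.5)
  expect_identical(pred_f$labels[dim(pred_f$labels)[1]:1, , ], pred$labels)
})

test_that("disjoint-component counting flags islands outside a prior", {
  pred <- array(0L, dim = c(16, 16, 8))
  pred[2:4, 2:4, 2:4] <- 1L        # inside prior
  pred[10:12, 10:12, 2:4] <- 2L    # island
  pred[14, 14, 7] <- 1L            # second island
  prior <- array(0L, dim = c(16, 16, 8))
  prior[1:5, 1:5, 1:5] <- 1L
  cc <- count_disjoint_components(labelmap(pred), labelmap(prior))
  expect_equal(cc$n_components, 3L)
  expect_equal(cc$n_islands, 2L)
  expect_setequal(cc$island_sizes, c(27L, 1L))
  none <- count_disjoint_components(labelmap(array(0L, dim = c(16, 16, 8))),
                                    labelmap(prior))
  expect_equal(none$n_components, 0L)
  expect_equal(none$n_islands, 0L)
})
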