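test_that("network output shapes follow the configuration contract", {
  set.seed(1)
  cfg <- net_config(n_stages = 3, base_channels = 8, in_channels = 1)
  net <- build_network(cfg)
  x <- array(rnorm(32^3), dim = c(32, 32, 32, 1))
  out <- net_forward(net, x)
  expect_length(out$logits, cfg$ds_levels)
  expect_equal(dim(out$logits[[1]]), c(32, 32, 32, 3))
  expect_equal(dim(out$logits[[2]]), c(16, 16, 16, 3))

  cfg3 <- net_config(n_stages = 2, base_channels = 4, in_channels = 3)
  net3 <- build_network(cfg3)
  x3 <- array(rnorm(8^3 * 3), dim = c(8, 8, 8, 3))
  expect_equal(dim(net_forward(net3, x3)$logits[[1]]), c(8, 8, 8, 3))
  expect_error(net_forward(net3, x), "channels")
})

test_that("patch sizes must be divisible by the downsampling factor", {
  set.seed(1)
  net <- build_network(net_config(n_stages = 3, base_channels = 4))
  x <- array(rnorm(30 * 32 * 32), dim = c(30, 32, 32, 1))
  expect_error(net_forward(net, x), "axis x")
})

test_that("parameter count matches the layer-by-layer closed form", {
  set.seed(1)
  net <- build_network(net_config(n_stages = 2, base_channels = 4,
                                  in_channels = 1, n_classes = 3, kernel = 3))
  # enumerated by hand for channels (4, 8):
  conv <- function(k, cin, cout) k^3 * cin * cout + cout
  norm <- function(ch) 2 * ch
  expected <-
    conv(3, 1, 4) + norm(4) + conv(3, 4, 4) + norm(4) + conv(1, 1, 4) + # enc1 + proj
    conv(3, 4, 8) + norm(8) +                                           # down2
    conv(3, 8, 8) + norm(8) + conv(3, 8, 8) + norm(8) +                 # enc2
    2^3 * 8 * 4 +                                                       # up1
    conv(3, 8, 4) + norm(4) + conv(3, 4, 4) + norm(4) + conv(1, 8, 4) + # dec1 + proj
    conv(1, 4, 3)                                                       # head
  expect_equal(n_parameters(net), expected)
})

test_that("composite loss matches a brute-force evaluation of its formula", {
  set.seed(3)
  d <- c(4, 4, 4)
  logits <- array(rnorm(prod(d) * 3), dim = c(d, 3))
  target <- array(sample(0:2, prod(d), TRUE), dim = d)
  w <- loss_weights(dice_weight = 1, ce_weight = 1, n_levels = 1)
  got <- composite_loss(list(logits), target, w)

  # independent oracle, written directly from the definition
  n <- prod(d)
  lm <- matrix(logits, nrow = n)
  pm <- exp(lm - apply(lm, 1, max))
  pm <- pm / rowSums(pm)
  eps <- 1e-5
  dice <- vapply(2:3, function(c) {
    g <- as.numeric(as.vector(target) == c - 1)
    2 * sum(pm[, c] * g) / (sum(pm[, c]) + sum(g) + eps)
  }, 0)
  ce <- -mean(log(pm[cbind(seq_len(n), as.vector(target) + 1L)]))
  expect_equal(got, (1 - mean(dice)) + ce, tolerance = 1e-10)

  # uniform logits: softmax is exactly 1/3 everywhere
  u <- composite_loss(list(array(0, dim = c(d, 3))), target, w)
  pu <- 1 / 3
  dice_u <- vapply(2:3, function(c) {
    g <- sum(target == c - 1)
    2 * pu * g / (pu * n + g + eps)
  }, 0)
  expect_equal(u, (1 - mean(dice_u)) + log(3), tolerance = 1e-10)
})

test_that("confident correct logits drive the loss to its analytic minimum", {
  d <- c(4, 4, 4)
  target <- array(sample(0:2, prod(d), TRUE), dim = d)
  logits <- array(0, dim = c(d, 3))
  for (c in 1:3) logits[, , , c] <- 50 * (target == c - 1)
  w <- loss_weights(n_levels = 1)
  val <- composite_loss(list(logits), target, w)
  # CE -> 0; soft Dice -> 1 - eps-correction, so loss -> ~0
  expect_lt(val, 1e-3)
})

test_that("deep-supervision weights reduce and normalize as documented", {
  set.seed(4)
  d <- c(8, 8, 8)
  logits <- array(rnorm(prod(d) * 3), dim = c(d, 3))
  target <- array(sample(0:2, prod(d), TRUE), dim = d)
  single <- composite_loss(list(logits), target, loss_weights(n_levels = 1))
  also_single <- composite_loss(list(logits), target,
                                loss_weights(ds_weights = 1))
  expect_equal(single, also_single)
  w2 <- loss_weights(n_levels = 2)
  expect_equal(sum(w2$ds_weights), 1)
  expect_equal(w2$ds_weights, c(2 / 3, 1 / 3))
})

test_that("the loss is equivariant under swapping the two foreground classes", {
  set.seed(5)
  d <- c(4, 4, 4)
  logits <- array(rnorm(prod(d) * 3), dim = c(d, 3))
  target <- array(sample(0:2, prod(d), TRUE), dim = d)
  w <- loss_weights(n_levels = 1)
  swapped_logits <- logits[, , , c(1, 3, 2)]
  swapped_target <- target
  swapped_target[target == 1] <- 2L
  swapped_target[target == 2] <- 1L
  expect_equal(composite_loss(list(logits), target, w),
               composite_loss(list(swapped_logits), swapped_target, w),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through the whole network", {
  set.seed(6)
  cfg <- net_config(n_stages = 2, base_channels = 2, in_channels = 2,
                    ds_levels = 1)
  net <- build_network(cfg)
  x <- array(rnorm(4^3 * 2), dim = c(4, 4, 4, 2))
  tg <- array(sample(0:2, 64, TRUE), dim = c(4, 4, 4))
  w <- loss_weights(n_levels = 1)
  fwd <- net_forward(net, x, want_cache = TRUE)
  lg <- stagedseg:::composite_loss_grad(list(fwd$logits), list(tg), w)
  grads <- net_backward(net, fwd$cache, lg$grads[[1]])
  loss_of <- function(n) composite_loss(net_forward(n, x)$logits, tg, w)
  set.seed(7)
  for (blk in names(net$params)) {
    for (leaf in names(net$params[[blk]])) {
      p <- net$params[[blk]][[leaf]]
      g <- grads[[blk]][[leaf]]
      if (is.list(p)) {
        for (sub in names(p)) {
          i <- sample.int(length(p[[sub]]), 1)
          np <- nm <- net
          np$params[[blk]][[leaf]][[sub]][i] <- p[[sub]][i] + 1e-5
          nm$params[[blk]][[leaf]][[sub]][i] <- p[[sub]][i] - 1e-5
          num <- (loss_of(np) - loss_of(nm)) / 2e-5
          expect_equal(g[[sub]][i], num, tolerance = 1e-4)
        }
      } else {
        i <- sample.int(length(p), 1)
        np <- nm <- net
        np$params[[blk]][[leaf]][i] <- p[i] + 1e-5
        nm$params[[blk]][[leaf]][i] <- p[i] - 1e-5
        num <- (loss_of(np) - loss_of(nm)) / 2e-5
        expect_equal(g[i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("gradient flows to every parameter group on a random batch", {
  set.seed(8)
  cfg <- net_config(n_stages = 3, base_channels = 2, in_channels = 1)
  net <- build_network(cfg)
  x <- array(rnorm(16^3), dim = c(16, 16, 16, 1))
  tg <- array(sample(0:2, 16^3, TRUE), dim = c(16, 16, 16))
  fwd <- net_forward(net, x, want_cache = TRUE)
  lg <- stagedseg:::composite_loss_grad(list(fwd$logits), list(tg),
                                        loss_weights(n_levels = cfg$ds_levels))
  grads <- net_backward(net, fwd$cache, lg$grads[[1]])
  norms <- rapply(grads, function(g) sqrt(sum(g^2)), how = "unlist")
  expect_true(all(norms > 0))
})

test_that("checkpoints round-trip weights and refuse nothing silently", {
  set.seed(9)
  net <- build_network(net_config(n_stages = 2, base_channels = 2))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, f, recipe = channel_recipe(TRUE, TRUE),
                  extra = list(best_epoch = 3L))
  ck <- load_checkpoint(f)
  expect_equal(ck$net$params, net$params)
  expect_equal(ck$recipe$n_channels, 3L)
  expect_equal(ck$extra$best_epoch, 3L)
})

test_that("convolution kernels agree with a brute-force oracle on random shapes", {
  conv_ref <- function(x, w, b, stride, pad) {
    d <- dim(x); k <- dim(w)[1]; Cin <- dim(w)[4]; Cout <- dim(w)[5]
    od <- (d[1:3] + 2 * pad - k) %/% stride + 1
    y <- array(0, dim = c(od, Cout))
    for (co in 1:Cout) for (oz in 1:od[3]) for (oy in 1:od[2]) for (ox in 1:od[1]) {
      acc <- b[co]
      for (ci in 1:Cin) for (kz in 1:k) for (ky in 1:k) for (kx in 1:k) {
        ix <- (ox - 1) * stride + kx - pad
        iy <- (oy - 1) * stride + ky - pad
        iz <- (oz - 1) * stride + kz - pad
        if (ix >= 1 && ix <= d[1] && iy >= 1 && iy <= d[2] &&
            iz >= 1 && iz <= d[3])
          acc <- acc + x[ix, iy, iz, ci] * w[kx, ky, kz, ci, co]
      }
      y[ox, oy, oz, co] <- acc
    }
    y
  }
  set.seed(10)
  for (trial in 1:5) {
    d <- sample(3:8, 3, TRUE)
    Cin <- sample(1:3, 1); Cout <- sample(1:3, 1)
    k <- sample(c(1, 3), 1); stride <- sample(1:2, 1)
    pad <- (k - 1) / 2
    x <- array(rnorm(prod(d) * Cin), dim = c(d, Cin))
    w <- array(rnorm(k^3 * Cin * Cout), dim = c(k, k, k, Cin, Cout))
    b <- rnorm(Cout)
    got <- stagedseg:::.conv3d_fw(x, w, b, as.integer(stride), as.integer(pad))
    expect_equal(got, conv_ref(x, w, b, stride, pad), tolerance = 1e-12)
  }
})
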