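# Lightweight 3D residual encoder-decoder with deep supervision.
#
# Topology (n_stages = S, channels ch[s] = base * growth^(s-1)):
#   encoder: stage 1 = residual block at full resolution;
#            stage s>1 = strided 3x3x3 conv (stride 2) + IN + lReLU, then a
#            residual block. A residual block is two conv(3)-IN-lReLU units
#            with an identity skip (1x1x1 projection when channels change).
#   decoder: per level, 2x2x2 transposed conv (stride 2), concatenation
#            with the encoder skip, then a residual block.
#   heads:   1x1x1 conv to n_classes logits at the ds_levels finest decoder
#            levels (finest first).
# Parameters live in a flat named list; forward caches enable the explicit
# backward pass.

#' Network configuration
#'
#' @param n_stages number of resolution levels (>= 2); desk-scale default 3.
#' @param base_channels channels at the finest level.
#' @param channel_growth per-stage channel multiplier.
#' @param in_channels input channels (1-3 depending on the channel recipe).
#' @param n_classes output classes (background, GTVp, GTVn).
#' @param kernel convolution kernel edge length (cubic).
#' @param ds_levels number of deep-supervision outputs (finest first);
#'   must be <= n_stages - 1.
#' @return a `net_config` object.
#' @export
net_config <- function(n_stages = 3L, base_channels = 8L, channel_growth = 2,
                       in_channels = 1L, n_classes = 3L, kernel = 3L,
                       ds_levels = n_stages - 1L) {
  stopifnot(n_stages >= 2, base_channels >= 1, channel_growth > 0,
            in_channels >= 1, n_classes >= 2, kernel %% 2 == 1)
  if (ds_levels < 1 || ds_levels > n_stages - 1)
    stopf("net_config: ds_levels must lie in [1, n_stages - 1]")
  ch <- as.integer(round(base_channels * channel_growth^(0:(n_stages - 1))))
  structure(list(n_stages = as.integer(n_stages),
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 kernel = as.integer(kernel),
                 ds_levels = as.integer(ds_levels),
                 channels = ch),
            class = "net_config")
}

he_init <- function(dims, fan_in) {
  gain <- sqrt(2 / (1 + LRELU_SLOPE^2))
  array(rnorm(prod(dims), sd = gain / sqrt(fan_in)), dim = dims)
}

init_conv <- function(k, cin, cout) {
  list(w = he_init(c(k, k, k, cin, cout), k^3 * cin), b = numeric(cout))
}

init_in <- function(ch) list(g = rep(1, ch), b = numeric(ch))

init_resblock <- function(k, cin, cout) {
  blk <- list(conv1 = init_conv(k, cin, cout), in1 = init_in(cout),
              conv2 = init_conv(k, cout, cout), in2 = init_in(cout))
  if (cin != cout) blk$proj <- init_conv(1L, cin, cout)
  blk
}

#' Build a randomly initialized network
#'
#' Weight initialization draws from the current R RNG stream (seed it for
#' reproducible builds). Convolutions use He-style initialization matched to
#' the leaky-ReLU nonlinearity.
#'
#' @param cfg a [net_config()].
#' @return a `network` object: `cfg` plus a nested parameter list.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  S <- cfg$n_stages; ch <- cfg$channels; k <- cfg$kernel
  params <- list()
  params$enc1 <- init_resblock(k, cfg$in_channels, ch[1])
  for (s in 2:S) {
    params[[paste0("down", s)]] <- list(conv = init_conv(k, ch[s - 1], ch[s]),
                                        norm = init_in(ch[s]))
    params[[paste0("enc", s)]] <- init_resblock(k, ch[s], ch[s])
  }
  for (s in (S - 1):1) {
    params[[paste0("up", s)]] <-
      list(w = he_init(c(2, 2, 2, ch[s + 1], ch[s]), 8 * ch[s + 1]))
    params[[paste0("dec", s)]] <- init_resblock(k, 2L * ch[s], ch[s])
  }
  for (l in seq_len(cfg$ds_levels))
    params[[paste0("head", l)]] <- init_conv(1L, ch[l], cfg$n_classes)
  structure(list(cfg = cfg, params = params), class = "network")
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("<network %d stages, channels %s, in=%d, %d classes, %d ds levels, %d parameters>\n",
              x$cfg$n_stages, paste(x$cfg$channels, collapse = "/"),
              x$cfg$in_channels, x$cfg$n_classes, x$cfg$ds_levels,
              n_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param net a `network`.
#' @return integer count.
#' @export
n_parameters <- function(net) {
  length(unlist(net$params, use.names = FALSE))
}

check_patch_divisible <- function(cfg, dims) {
  f <- 2L^(cfg$n_stages - 1L)
  bad <- which(dims %% f != 0)
  if (length(bad))
    stopf("patch size %s not divisible by %d along axis %s (n_stages = %d)",
          paste(dims, collapse = "x"), f, paste(c("x", "y", "z")[bad], collapse = ","),
          cfg$n_stages)
}

conv_fw <- function(x, prm, stride = 1L, pad = NULL) {
  k <- dim(prm$w)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  .conv3d_fw(x, prm$w, prm$b, as.integer(stride), as.integer(pad))
}

conv_bw <- function(x, prm, gy, stride = 1L, pad = NULL) {
  k <- dim(prm$w)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  .conv3d_bw(x, prm$w, gy, as.integer(stride), as.integer(pad))
}

resblock_fw <- function(x, prm) {
  c1 <- conv_fw(x, prm$conv1)
  n1 <- in_fw(c1, prm$in1$g, prm$in1$b, act = TRUE)
  a1 <- n1$y
  c2 <- conv_fw(a1, prm$conv2)
  n2 <- in_fw(c2, prm$in2$g, prm$in2$b)
  skip <- if (!is.null(prm$proj)) conv_fw(x, prm$proj) else x
  pre <- n2$y + skip
  y <- lrelu_fw(pre)
  list(y = y, cache = list(x = x, n1 = n1$cache, a1 = a1,
                           n2 = n2$cache, pre = pre))
}

# Returns gx plus a gradient list mirroring the block's parameter layout.
resblock_bw <- function(gy, prm, cache) {
  gpre <- lrelu_bw(cache$pre, gy)
  b2 <- in_bw(gpre, prm$in2$g, cache$n2)
  cb2 <- conv_bw(cache$a1, prm$conv2, b2$gx)
  b1 <- in_bw(cb2$gx, prm$in1$g, cache$n1)
  cb1 <- conv_bw(cache$x, prm$conv1, b1$gx)
  grads <- list(conv1 = list(w = cb1$gw, b = cb1$gb),
                in1 = list(g = b1$dgamma, b = b1$dbeta),
                conv2 = list(w = cb2$gw, b = cb2$gb),
                in2 = list(g = b2$dgamma, b = b2$dbeta))
  if (!is.null(prm$proj)) {
    pb <- conv_bw(cache$x, prm$proj, gpre)
    grads$proj <- list(w = pb$gw, b = pb$gb)
    gx <- cb1$gx + pb$gx
  } else {
    gx <- cb1$gx + gpre
  }
  list(gx = gx, grads = grads)
}

down_fw <- function(x, prm) {
  c1 <- conv_fw(x, prm$conv, stride = 2L)
  n1 <- in_fw(c1, prm$norm$g, prm$norm$b, act = TRUE)
  list(y = n1$y, cache = list(x = x, n1 = n1$cache))
}

down_bw <- function(gy, prm, cache) {
  b1 <- in_bw(gy, prm$norm$g, cache$n1)
  cb <- conv_bw(cache$x, prm$conv, b1$gx, stride = 2L)
  list(gx = cb$gx,
       grads = list(conv = list(w = cb$gw, b = cb$gb),
                    norm = list(g = b1$dgamma, b = b1$dbeta)))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

#' Network forward pass
#'
#' @param net a `network` from [build_network()].
#' @param x input stack, array `(D, H, W, in_channels)`; each spatial dim
#'   must be divisible by `2^(n_stages - 1)`.
#' @param want_cache keep activations for a subsequent [net_backward()].
#' @return a list with `logits` (list of arrays, finest supervision level
#'   first; the finest has shape `(D, H, W, n_classes)`) and, when
#'   requested, `cache`.
#' @export
net_forward <- function(net, x, want_cache = FALSE) {
  cfg <- net$cfg; prm <- net$params
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[4] != cfg$in_channels)
    stopf("net_forward: input has %d channels, network expects %d",
          d[4], cfg$in_channels)
  check_patch_divisible(cfg, d[1:3])
  S <- cfg$n_stages
  enc <- vector("list", S); enc_cache <- vector("list", S)
  down_cache <- vector("list", S)
  r <- resblock_fw(x, prm$enc1); enc[[1]] <- r$y; enc_cache[[1]] <- r$cache
  for (s in 2:S) {
    dn <- down_fw(enc[[s - 1]], prm[[paste0("down", s)]])
    down_cache[[s]] <- dn$cache
    r <- resblock_fw(dn$y, prm[[paste0("enc", s)]])
    enc[[s]] <- r$y; enc_cache[[s]] <- r$cache
  }
  dec <- vector("list", S - 1); dec_cache <- vector("list", S - 1)
  up_in <- vector("list", S - 1)
  feat <- enc[[S]]
  for (s in (S - 1):1) {
    up_in[[s]] <- feat
    u <- .convt3d_fw(feat, prm[[paste0("up", s)]]$w)
    cat_ <- concat_channels(u, enc[[s]])
    r <- resblock_fw(cat_, prm[[paste0("dec", s)]])
    dec[[s]] <- r$y; dec_cache[[s]] <- r$cache
    feat <- dec[[s]]
  }
  logits <- lapply(seq_len(cfg$ds_levels), function(l)
    conv_fw(dec[[l]], prm[[paste0("head", l)]]))
  out <- list(logits = logits)
  if (want_cache)
    out$cache <- list(enc_cache = enc_cache, down_cache = down_cache,
                      dec_cache = dec_cache, dec = dec, up_in = up_in)
  out
}

#' Network backward pass
#'
#' @param net a `network`.
#' @param cache the cache returned by [net_forward()] with `want_cache = TRUE`.
#' @param glogits list of gradients w.r.t. each supervision level's logits
#'   (finest first; shorter lists leave deeper heads untouched).
#' @return nested gradient list mirroring `net$params`.
#' @export
net_backward <- function(net, cache, glogits) {
  cfg <- net$cfg; prm <- net$params
  S <- cfg$n_stages
  grads <- list()
  gdec <- vector("list", S - 1)
  for (l in seq_along(glogits)) {
    hb <- conv_bw(cache$dec[[l]], prm[[paste0("head", l)]], glogits[[l]])
    grads[[paste0("head", l)]] <- list(w = hb$gw, b = hb$gb)
    gdec[[l]] <- hb$gx
  }
  genc <- vector("list", S)
  gfeat_next <- NULL  # gradient flowing into dec[[s+1]] / enc[[S]]
  for (s in seq_len(S - 1)) {
    g <- gdec[[s]] %||% array(0, dim = dim(cache$dec[[s]]))
    if (s > 1 && !is.null(gfeat_next)) g <- g + gfeat_next
    rb <- resblock_bw(g, prm[[paste0("dec", s)]], cache$dec_cache[[s]])
    grads[[paste0("dec", s)]] <- rb$grads
    ch_u <- cfg$channels[s]
    gcat <- rb$gx
    d4 <- dim(gcat)[4]
    gu <- gcat[, , , seq_len(ch_u), drop = FALSE]
    gskip <- gcat[, , , (ch_u + 1L):d4, drop = FALSE]
    genc[[s]] <- gskip
    ub <- .convt3d_bw(cache$up_in[[s]], prm[[paste0("up", s)]]$w, gu)
    grads[[paste0("up", s)]] <- list(w = ub$gw)
    gfeat_next <- ub$gx
  }
  gs <- gfeat_next  # gradient on enc[[S]]
  for (s in S:2) {
    if (s < S && !is.null(genc[[s]])) gs <- gs + genc[[s]]
    rb <- resblock_bw(gs, prm[[paste0("enc", s)]], cache$enc_cache[[s]])
    grads[[paste0("enc", s)]] <- rb$grads
    db <- down_bw(rb$gx, prm[[paste0("down", s)]], cache$down_cache[[s]])
    grads[[paste0("down", s)]] <- db$grads
    gs <- db$gx
  }
  gs <- gs + (genc[[1]] %||% 0)
  rb <- resblock_bw(gs, prm$enc1, cache$enc_cache[[1]])
  grads$enc1 <- rb$grads
  grads
}

#' Save a network checkpoint
#'
#' Stores weights, the network configuration, and the channel recipe the
#' model was trained with, so inference can refuse mismatched recipes.
#'
#' @param net a `network`.
#' @param path output file (RDS).
#' @param recipe optional [channel_recipe()] recorded alongside.
#' @param extra optional named list of additional metadata.
#' @export
save_checkpoint <- function(net, path, recipe = NULL, extra = list()) {
  saveRDS(list(cfg = net$cfg, params = net$params, recipe = recipe,
               extra = extra), path)
  invisible(path)
}

#' Load a network checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a list with `net` (a `network`), `recipe`, and `extra`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  list(net = structure(list(cfg = ck$cfg, params = ck$params),
                       class = "network"),
       recipe = ck$recipe, extra = ck$extra)
}
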