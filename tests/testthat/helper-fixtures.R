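# Shared fixtures: small phantoms and hand-built grids, generated in code.

tiny_params <- function(seed = 1L, n_gtvn = 1L, ...) {
  phantom_params(shape = c(32L, 32L, 16L), spacing = c(1, 1, 1.5),
                 n_gtvn = n_gtvn, gtvp_radius_range = c(4, 6),
                 gtvn_radius_range = c(2.5, 3.5), seed = seed, ...)
}

# chi-square test of origin uniformity over an nbin^3 histogram, with cell
# probabilities matching the uneven integer split of each axis range
origin_chisq_ok <- function(origins, valid, nbin = 4L, alpha = 0.01) {
  n <- nrow(origins)
  axis_counts <- lapply(valid, function(v)
    tabulate(floor((0:(v - 1)) / v * nbin) + 1L, nbins = nbin))
  bins <- sapply(1:3, function(a) floor(origins[, a] / valid[a] * nbin))
  cell <- bins[, 1] + nbin * bins[, 2] + nbin^2 * bins[, 3]
  obs <- tabulate(cell + 1L, nbins = nbin^3)
  p <- as.vector(outer(outer(axis_counts[[1]], axis_counts[[2]]),
                       axis_counts[[3]])) / prod(valid)
  expected <- n * p
  chi <- sum((obs - expected)^2 / expected)
  chi < qchisq(1 - alpha, df = nbin^3 - 1)
}

desk_params <- function(seed = 1L, ...) phantom_params(seed = seed, ...)

# a deterministic labelled 4^3 pair with known overlap counts
handmade_pair <- function() {
  p <- array(0L, dim = c(4, 4, 4))
  r <- array(0L, dim = c(4, 4, 4))
  p[1:3, 1, 1] <- 1L          # |P| = 3
  r[2:4, 1, 1] <- 1L          # |R| = 3, overlap {2,3} -> 2
  list(pred = labelmap(p), ref = labelmap(r))
}

random_labelmap <- function(shape, p_fg = 0.3) {
  labelmap(array(sample(0:2, prod(shape), TRUE,
                        prob = c(1 - p_fg, p_fg / 2, p_fg / 2)),
                 dim = shape))
}

# independent brute-force Dice on voxel index sets
dice_oracle <- function(pred, ref, label) {
  ip <- which(pred$labels == label)
  ir <- which(ref$labels == label)
  if (length(ip) + length(ir) == 0) return(1)
  2 * length(intersect(ip, ir)) / (length(ip) + length(ir))
}

aggdice_oracle <- function(pairs, label) {
  inter <- tot <- 0
  for (pr in pairs) {
    ip <- which(pr$pred$labels == label)
    ir <- which(pr$ref$labels == label)
    inter <- inter + length(intersect(ip, ir))
    tot <- tot + length(ip) + length(ir)
  }
  if (tot == 0) return(1)
  2 * inter / tot
}

# exact two-sided signed-rank p by enumeration of all sign assignments
wilcoxon_oracle <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v - mu) - 1e-9)
}
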