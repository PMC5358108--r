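# Independent brute-force oracles and shared fixtures.

# Exact Euclidean distance to the nearest background pixel, by exhaustive
# search over all pixel pairs. O(n^2) -- small masks only.
edt_brute <- function(mask) {
  bg <- which(mask == 0, arr.ind = TRUE)
  fg <- which(mask != 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (j in seq_len(nrow(fg))) {
    out[fg[j, 1], fg[j, 2]] <-
      sqrt(min((fg[j, 1] - bg[, 1])^2 + (fg[j, 2] - bg[, 2])^2))
  }
  out
}

# Per-band channel means by direct per-pixel grouping on floor(d / w).
band_means_brute <- function(channel, dmap, w) {
  inside <- dmap > 0
  band <- floor(dmap[inside] / w)
  tapply(channel[inside], band, mean)
}

# Mann-Whitney U and exact two-tailed p by full enumeration of all
# choose(n1 + n2, n1) group assignments (two-tailed by symmetric distance
# of U from its null mean).
mw_brute <- function(a, b) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_obs <- u_stat(a, b)
  mu <- n1 * n2 / 2
  us <- apply(utils::combn(n1 + n2, n1), 2, function(ii)
    u_stat(pooled[ii], pooled[-ii]))
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p = p)
}

# Reduced-size generator configuration for fast unit tests; acceptance
# tests use the full default configuration.
small_config <- function(...) {
  args <- utils::modifyList(
    list(image_size = 160, aggregate_radius = 50,
         n_cells = c(CFP = 15, GFP_RFP = 15, RFP = 8, CFP_RFP = 15),
         cell_radius = 4),
    list(...))
  do.call(synth_config, args)
}

iou <- function(a, b) sum(a != 0 & b != 0) / sum(a != 0 | b != 0)

disk_mask <- function(n, radius, ctr = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  ((rows - ctr)^2 + (cols - ctr)^2 <= radius^2) * 1
}
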