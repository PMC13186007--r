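# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately re-derive everything from first
# principles (explicit ranking, explicit formulas, per-pixel counting)
# and never call the code paths they verify.

# Kruskal-Wallis H with tie correction, from explicit midranks
brute_kruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  list(H = h / correction, df = length(groups) - 1L)
}

# Dunn pairwise z statistics from explicit pooled midranks
brute_dunn_z <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(x)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2L)
  apply(pairs, 2L, function(ij) {
    (rbar[ij[1]] - rbar[ij[2]]) /
      sqrt(s2 * (1 / n[ij[1]] + 1 / n[ij[2]]))
  })
}

# per-column pixel counting of a layer label mask: thickness of each
# label (um) in a given column, and the ORr implied by the pixel counts
pixel_count_orr <- function(mask, col, px_per_um) {
  v <- mask[, col]
  counts <- vapply(1:7, function(k) sum(v == k), numeric(1))
  outer_px <- sum(counts[4:7])      # OPL, ONL, IS, OS
  total_px <- sum(counts)
  c(outer_um = outer_px / px_per_um, total_um = total_px / px_per_um,
    orr = if (total_px > 0) outer_px / total_px else NA_real_)
}

# build a small spike table for one stimulating electrode from
# per-channel (position, counts) rows
make_spike_table <- function(channels, currents) {
  do.call(rbind, lapply(channels, function(ch) {
    data.frame(stim_electrode = 1L, channel = ch$channel,
               hemisphere = ch$hemisphere %||% "ipsi",
               x_mm = ch$x, y_mm = ch$y %||% 0,
               current_uA = currents, spikes = ch$counts)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw a disk image fixture: matrix with hard or anti-aliased disks
disk_image <- function(H, W, centers, r_px, value = 0.9) {
  img <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    rr <- seq_len(H); cc <- seq_len(W)
    d <- sqrt(outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+"))
    img <- pmax(img, pmin(pmax(r_px + 0.5 - d, 0), 1) * value)
  }
  img
}
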