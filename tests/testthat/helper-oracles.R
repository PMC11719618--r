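# Independent brute-force oracles. Each is deliberately written from first
# principles (scalar loops, exhaustive scans, full enumeration) and shares no
# code path with the package implementation it checks.

# Ground-truth oracle: per-pixel point-in-disc / point-in-rectangle tests,
# plus border flood fill to identify enclosed voids. Small images only.
slow_colony_truth <- function(spec) {
  W <- spec$image_width; H <- spec$image_height
  cx <- spec$center[1]; cy <- spec$center[2]
  disc <- matrix(FALSE, W, H); un <- matrix(FALSE, W, H)
  fil <- spec$filaments
  for (ix in seq_len(W)) {
    for (iy in seq_len(H)) {
      px <- ix - 1; py <- iy - 1
      in_disc <- (px - cx)^2 + (py - cy)^2 <= spec$inner_radius^2
      in_any <- in_disc
      for (k in seq_len(nrow(fil))) {
        if (fil$length[k] <= 0) next
        a <- fil$angle[k]; w <- fil$width[k]
        ov <- max(2, w / 2)
        tt <- (px - cx) * cos(a) + (py - cy) * sin(a)
        ss <- -(px - cx) * sin(a) + (py - cy) * cos(a)
        if (tt >= spec$inner_radius - ov &&
            tt <= spec$inner_radius + fil$length[k] &&
            abs(ss) <= w / 2) in_any <- TRUE
      }
      disc[ix, iy] <- in_disc; un[ix, iy] <- in_any
    }
  }
  # flood fill background from the border (4-connectivity); anything
  # unreached and not foreground is an enclosed void
  outside <- matrix(FALSE, W, H)
  queue <- list()
  push <- function(x, y) {
    if (x >= 1 && x <= W && y >= 1 && y <= H && !outside[x, y] && !un[x, y]) {
      outside[x, y] <<- TRUE
      queue[[length(queue) + 1]] <<- c(x, y)
    }
  }
  for (x in seq_len(W)) { push(x, 1); push(x, H) }
  for (y in seq_len(H)) { push(1, y); push(W, y) }
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    push(p[1] - 1, p[2]); push(p[1] + 1, p[2])
    push(p[1], p[2] - 1); push(p[1], p[2] + 1)
  }
  a_outer <- sum(!outside)      # foreground plus enclosed voids
  a_inner <- sum(disc)
  list(a_inner_true = a_inner, a_outer_true = a_outer,
       f_true = (a_outer - a_inner) / a_inner)
}

# Exhaustive-scan Otsu: the between-class variance of a candidate
# threshold, and its maximum over all 256 thresholds. Bimodal images have
# a plateau of equally optimal thresholds, so checks compare achieved
# objectives rather than threshold values.
otsu_objective <- function(g, t) {
  v <- round(as.numeric(g))
  lo <- v[v <= t]; hi <- v[v > t]
  if (!length(lo) || !length(hi)) return(0)
  w0 <- length(lo) / length(v)
  w0 * (1 - w0) * (mean(lo) - mean(hi))^2
}

otsu_oracle_max <- function(g) {
  max(vapply(0:255, function(t) otsu_objective(g, t), numeric(1)))
}

# Direct spatial-domain convolution with edge replication.
conv_oracle <- function(g, kern) {
  W <- nrow(g); H <- ncol(g); k <- nrow(kern); half <- (k - 1) / 2
  out <- matrix(0, W, H)
  for (x in seq_len(W)) for (y in seq_len(H)) {
    acc <- 0
    for (dx in -half:half) for (dy in -half:half) {
      sx <- min(max(x + dx, 1), W); sy <- min(max(y + dy, 1), H)
      acc <- acc + g[sx, sy] * kern[dx + half + 1, dy + half + 1]
    }
    out[x, y] <- acc
  }
  out
}

# Kruskal-Wallis H from first principles: mid-ranks computed by counting
# (1 + #smaller + (#equal - 1)/2), then the defining formula.
kw_h_oracle <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- vapply(pooled, function(v)
    1 + sum(pooled < v) + (sum(pooled == v) - 1) / 2, numeric(1))
  idx <- rep(seq_along(groups), lengths(groups))
  h0 <- 0
  for (i in seq_along(groups))
    h0 <- h0 + lengths(groups)[i] * (mean(r[idx == i]) - (N + 1) / 2)^2
  h0 <- h0 * 12 / (N * (N + 1))
  ties <- table(pooled)
  h0 / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exact permutation p-value by enumerating all N! orderings of the pooled
# values (feasible for N <= 8) and assigning the first n1 to group 1, etc.
kw_perm_oracle <- function(groups) {
  pooled <- unlist(groups)
  n <- lengths(groups)
  N <- length(pooled)
  h_obs <- kw_h_oracle(groups)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  all_p <- perms(seq_len(N))
  ge <- 0
  for (p in all_p) {
    gl <- split(pooled[p], rep(seq_along(n), n))
    if (kw_h_oracle(gl) >= h_obs - 1e-9) ge <- ge + 1
  }
  ge / length(all_p)
}

# Shoelace area of a polygon, written directly from the cross-product sum.
shoelace_oracle <- function(poly) {
  n <- nrow(poly); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  abs(s) / 2
}

# A standard noiseless test colony: disc plus a few spokes.
demo_spec <- function(noise_sd = 0, seed = NULL, n_spokes = 6,
                      spoke_len = 30, spoke_w = 7, r = 45,
                      W = 220, H = 220) {
  colony_spec(W, H, inner_radius = r,
              filaments = radial_filaments(n_spokes, spoke_len, spoke_w),
              noise_sd = noise_sd, seed = seed)
}
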