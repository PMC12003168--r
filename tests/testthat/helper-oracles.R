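# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force search, direct formula evaluation,
# and a from-scratch Hungarian assignment.

# ---- optimal 1:1 assignment (Hungarian, O(n^3) potentials version) -------
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- rep(0, n + 1); v <- rep(0, m + 1)
  p <- rep(0L, m + 1); way <- rep(0L, m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- -1L
      for (j in seq_len(m)) if (!used[j + 1]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]; p[j0 + 1] <- p[j1 + 1]; j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

# Match truth nuclei to segmented labels: optimal assignment on centroid
# distances; a pair counts as matched when the label centroid lies within
# the truth radius. Returns c(matched, n_truth, n_labels).
match_to_truth <- function(tab, truth) {
  nt <- nrow(truth); nl <- nrow(tab)
  if (nl == 0L) return(c(matched = 0L, n_truth = nt, n_labels = 0L))
  BIG <- 1e6
  d <- outer(seq_len(nt), seq_len(nl), function(i, j)
    sqrt((truth$x_um[i] - tab$centroid_x_um[j])^2 +
           (truth$y_um[i] - tab$centroid_y_um[j])^2))
  cost <- ifelse(d <= truth$radius_um, d, BIG)
  # pad with dummy columns so every truth row can stay unmatched
  cost <- cbind(cost, matrix(BIG, nt, nt))
  a <- hungarian_assign(cost)
  matched <- sum(a <= nl & cost[cbind(seq_len(nt), a)] < BIG)
  c(matched = matched, n_truth = nt, n_labels = nl)
}

# ---- exhaustive Otsu: maximize between-class variance over bin edges -----
otsu_brute <- function(values, n_bins = 256L) {
  lo <- min(values); hi <- max(values)
  w <- (hi - lo) / n_bins
  best <- -Inf; best_t <- NA_real_
  for (k in seq_len(n_bins - 1L)) {
    t <- lo + k * w
    a <- values[values <= t]; b <- values[values > t]
    if (length(a) == 0L || length(b) == 0L) next
    w0 <- length(a) / length(values)
    bcv <- w0 * (1 - w0) * (mean(a) - mean(b))^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# binned-mean variant matching the 256-bin histogram discretisation
otsu_brute_binned <- function(values, n_bins = 256L) {
  lo <- min(values); hi <- max(values)
  w <- (hi - lo) / n_bins
  bin <- pmin(floor((values - lo) / w) + 1L, n_bins)
  mids <- lo + (bin - 0.5) * w
  best <- -Inf; best_t <- NA_real_
  for (k in seq_len(n_bins - 1L)) {
    t <- lo + k * w
    a <- mids[bin <= k]; b <- mids[bin > k]
    if (length(a) == 0L || length(b) == 0L) next
    w0 <- length(a) / length(values)
    bcv <- w0 * (1 - w0) * (mean(a) - mean(b))^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# ---- Kruskal-Wallis H from raw ranks (with tie correction) ---------------
kruskal_H_brute <- function(values, group) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, group, function(v) length(v) * (mean(v) - (N + 1) / 2)^2))
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# ---- Holm step-down from the definition ----------------------------------
holm_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * (m - seq_len(m) + 1))
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# ---- grayscale opening with a ball element, direct double loop -----------
gray_open_brute <- function(img, r_px) {
  k <- floor(r_px)
  offs <- expand.grid(dx = -k:k, dy = -k:k)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r_px^2, ]
  offs$h <- sqrt(r_px^2 - offs$dx^2 - offs$dy^2)
  nr <- nrow(img); nc <- ncol(img)
  clamp <- function(v, n) pmin(pmax(v, 1L), n)
  er <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    er[i, j] <- min(img[cbind(clamp(i + offs$dx, nr),
                              clamp(j + offs$dy, nc))] - offs$h)
  op <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    op[i, j] <- max(er[cbind(clamp(i - offs$dx, nr),
                             clamp(j - offs$dy, nc))] + offs$h)
  op
}

# ---- KL divergence, direct -----------------------------------------------
kl_brute <- function(p, q) {
  s <- 0
  for (c in seq_along(p)) if (p[c] > 0) s <- s + p[c] * log(p[c] / q[c])
  unname(s)
}

# 2D ring embedding with alternating labels: every cell's k nearest
# neighbours (k/2 per side, k divisible by 4) split the two labels exactly
# in half, so neighbourhood and global distributions coincide
interleaved_ring <- function(n = 120) {
  theta <- 2 * pi * seq_len(n) / n
  list(embedding = cbind(cos(theta), sin(theta)) * 50,
       labels = rep(c("A", "B"), n / 2))
}

# run the full scene -> nuclei -> matching chain used by several suites
segment_and_match <- function(seed, params = sim_params(rng_seed = seed)) {
  sc <- generate_scene(params)
  lm <- segment_nuclei(sc$channels$nuclei)
  match_to_truth(object_table(lm), sc$truth_nuclei)
}
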