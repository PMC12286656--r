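# Internal helpers shared across modules.

# Deterministic substream seeds: one master integer seed, fixed small offsets
# per named stream, folded into [0, 2^31-2]. Documented contract: identical
# (config, seed) pairs yield bit-identical generator output.
.STREAMS <- c(events = 1L, rates = 2L, lfp = 3L, eye = 4L, latent = 5L,
              nmf = 6L, perm = 7L, boot = 8L, misc = 9L)

substreamSeed <- function(seed, stream) {
  stopifnot(stream %in% names(.STREAMS))
  as.integer((as.numeric(seed) * 7919 + 104729 * .STREAMS[[stream]]) %%
               2147483646)
}

# Half-open window [start, stop) indices on a time axis.
windowIdx <- function(time_s, start, stop) {
  which(time_s >= start & time_s < stop)
}

# First index at or after each target time on a sorted time axis.
.binAt <- function(t, targets) findInterval(targets - 1e-9, t) + 1L

# Analytic signal via FFT (Hilbert transform embedding). The transform is
# evaluated at a highly composite length (mirror-extended) so the FFT
# never hits a slow prime-length path; the result is truncated back.
analyticSignal <- function(x) {
  n0 <- length(x)
  m <- stats::nextn(n0, c(2, 3, 5))
  if (m > n0) {
    pad <- rev(x)[seq_len(m - n0)]
    return(.analyticCore(c(x, pad))[seq_len(n0)])
  }
  .analyticCore(x)
}

.analyticCore <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Zero-phase fifth-order Butterworth band-pass (forward-backward).
bandpassFiltfilt <- function(x, low, high, fs, order = 5) {
  if (low <= 0 || high >= fs / 2 || low >= high)
    stop("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# Connected components of supra-threshold cells on a (time x freq) grid,
# 4-connectivity, computed by union-find over the cell index list.
# cells: integer matrix with columns (row, col). Returns integer component
# labels, one per cell.
connectedComponents4 <- function(cells) {
  n <- nrow(cells)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- cells[, 1] + 1e6 * cells[, 2]
  idx <- seq_len(n)
  # neighbours: same col, row +/- 1; same row, col +/- 1
  for (dd in list(c(1, 0), c(0, 1))) {
    nk <- (cells[, 1] + dd[1]) + 1e6 * (cells[, 2] + dd[2])
    m <- match(nk, key)
    hit <- which(!is.na(m))
    for (a in hit) {
      ra <- find(idx[a]); rb <- find(m[a])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(idx, find, integer(1))
  match(roots, unique(roots))
}

# Best one-to-one matching of columns of A to columns of B by cosine
# similarity, exhaustive over permutations (intended for small k <= 7).
# Returns list(perm, cosines): B[, perm[j]] is matched to A[, j].
matchColumnsByCosine <- function(A, B) {
  k <- ncol(A)
  stopifnot(ncol(B) == k, k <= 7)
  cs <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  C <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) C[i, j] <- cs(A[, i], B[, j])
  perms <- permn(seq_len(k))
  best <- NULL; bestv <- -Inf
  for (p in perms) {
    v <- sum(C[cbind(seq_len(k), p)])
    if (v > bestv) { bestv <- v; best <- p }
  }
  list(perm = best, cosines = C[cbind(seq_len(k), best)])
}

permn <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permn(v[-i]), function(p) c(v[i], p)))
  out
}

# Mean of x over the half-open window [w[1], w[2]) of a time axis.
windowMean <- function(x, time_s, w) {
  idx <- windowIdx(time_s, w[1], w[2])
  if (length(idx) == 0) stop("window [", w[1], ",", w[2], ") is empty")
  mean(x[idx])
}
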