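# Shared fixture builders. Everything is generated in code, seeded.

# small noisy session for population-level tests
smallSession <- function(seed = 1, n_pre = 4, n_post = 4, n_units = 40,
                         noise_sd = 0.5, bin_width = 0.01, ...) {
  tru <- groundTruth(seed = seed, n_units = n_units, ...)
  sch <- makeEventSchedule(n_pre, n_post, seed = seed)
  pop <- simulatePopulation(sch, tru, bin_width = bin_width,
                            noise_sd = noise_sd)
  list(truth = tru, schedule = sch, population = pop)
}

# planted sign-split factor matrices with disjoint supports
plantedFactorMatrix <- function(seed = 1, n_ch = 24, p = 300, k = 3,
                                noise_sd = 0) {
  set.seed(seed)
  # distinct supports: each factor owns a block of channels and a block
  # of time-frequency cells
  Wp <- matrix(0, n_ch, k); Wn <- matrix(0, n_ch, k)
  cblk <- floor(n_ch / k)
  for (j in seq_len(k)) {
    rows <- ((j - 1) * cblk + 1):(j * cblk)
    Wp[rows, j] <- runif(cblk, 0.2, 1)
    Wn[rev(rows), j] <- runif(cblk, 0.2, 1)
  }
  Hp <- matrix(0, k, p); Hn <- matrix(0, k, p)
  blk <- floor(p / (2 * k))
  for (j in seq_len(k)) {
    Hp[j, ((j - 1) * blk + 1):(j * blk)] <- runif(blk, 0.5, 1)
    Hn[j, (k * blk + (j - 1) * blk + 1):(k * blk + j * blk)] <-
      runif(blk, 0.5, 1)
  }
  # scale each rank-1 component to unit Frobenius norm so every planted
  # factor contributes equal variance
  for (j in seq_len(k)) {
    sp <- sqrt(sum(Wp[, j]^2) * sum(Hp[j, ]^2))
    Wp[, j] <- Wp[, j] / sqrt(sp); Hp[j, ] <- Hp[j, ] / sqrt(sp)
    sn <- sqrt(sum(Wn[, j]^2) * sum(Hn[j, ]^2))
    Wn[, j] <- Wn[, j] / sqrt(sn); Hn[j, ] <- Hn[j, ] / sqrt(sn)
  }
  M <- Wp %*% Hp - Wn %*% Hn
  if (noise_sd > 0) M <- M + matrix(rnorm(n_ch * p, 0, noise_sd), n_ch)
  list(M = M, Wp = Wp, Hp = Hp, Wn = Wn, Hn = Hn)
}

# synthetic peri-event tensors carrying a planted factor structure whose
# loadings may differ by condition
plantedTensors <- function(seed = 1, n_ch = 12, n_ev_per_cond = 8,
                           conds = c("pre", "drug", "post"),
                           drop = c(pre = 1, drug = 1, post = 1),
                           noise_sd = 0.05) {
  set.seed(seed)
  nt <- 20; nf <- 10
  time_s <- seq(0, by = 0.05, length.out = nt)
  freq_hz <- seq(5, 95, length.out = nf)
  template <- outer(exp(-((seq_len(nt) - 6)^2) / 18),
                    exp(-((seq_len(nf) - 3)^2) / 4))
  load <- runif(n_ch, 0.3, 1)
  cond_v <- rep(conds, each = n_ev_per_cond)
  tensors <- lapply(seq_len(n_ch), function(ch) {
    v <- array(rnorm(length(cond_v) * nt * nf, 0, noise_sd),
               c(length(cond_v), nt, nf))
    for (e in seq_along(cond_v))
      v[e, , ] <- v[e, , ] + drop[[cond_v[e]]] * load[ch] * template
    affectdyn:::periEventTensor(v, time_s, freq_hz,
                                channel = sprintf("ch%02d", ch),
                                condition = cond_v)
  })
  names(tensors) <- sprintf("ch%02d", seq_len(n_ch))
  list(tensors = tensors, loadings = load, template = template)
}

# deterministic eye-trace-like object
flatTrace <- function(value = 1, fs = 100, t0 = -1, t1 = 2) {
  t <- seq(t0, t1, by = 1 / fs)
  list(time_s = t, closure = rep(value, length(t)), trial = 0L,
       condition = "pre", fs = fs, puff_onsets = 0)
}
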