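# Sign-split NMF of peri-puff z-scored spectrograms across channels, with
# held-out factor-count selection and condition-wise loading comparison.

# flatten the window-restricted (time x freq) average of selected events
.flatAverage <- function(tensor, window, event_idx) {
  ti <- windowIdx(tensor@time_s, window[1], window[2])
  if (length(ti) == 0) stop("factor window is empty on the tensor time axis")
  m <- apply(tensor@values[event_idx, ti, , drop = FALSE], c(2, 3), mean)
  as.vector(m)
}

#' Build train/test response matrices for factorization
#'
#' Per channel, averages the double z-scored peri-puff tensor over the
#' train set (every other eligible trial; the test set is the remaining
#' trials) within the given post-onset window, flattens (time x freq), and
#' stacks channels into a channels x (time * frequency) matrix.
#'
#' @param tensors named list of \code{\linkS4class{PeriEventTensor}}, one
#'   per channel, sharing axes and event order
#' @param window half-open window (seconds from onset) entering the
#'   factorization
#' @param train_conditions condition labels eligible for the split; NULL
#'   for all (the convention is to train on the non-infusion conditions)
#' @return list with \code{train}, \code{test} matrices, \code{channels},
#'   \code{time_s}, \code{freq_hz}, \code{split} (train/test event
#'   indices and the window)
#' @export
buildResponseMatrix <- function(tensors, window = c(0, 1.4),
                                train_conditions = NULL) {
  stopifnot(length(tensors) >= 1)
  tz <- tensors[[1]]
  elig <- if (is.null(train_conditions)) seq_along(tz@condition)
          else which(tz@condition %in% train_conditions)
  if (length(elig) < 2) stop("need at least 2 eligible trials to split")
  train_idx <- elig[seq(1, length(elig), by = 2)]
  test_idx <- setdiff(elig, train_idx)
  ti <- windowIdx(tz@time_s, window[1], window[2])
  ch <- names(tensors)
  if (is.null(ch)) ch <- sprintf("ch%02d", seq_along(tensors))
  train <- do.call(rbind, lapply(tensors, .flatAverage, window = window,
                                 event_idx = train_idx))
  test <- do.call(rbind, lapply(tensors, .flatAverage, window = window,
                                event_idx = test_idx))
  rownames(train) <- rownames(test) <- ch
  list(train = train, test = test, channels = ch,
       time_s = tz@time_s[ti], freq_hz = tz@freq_hz,
       split = list(train = train_idx, test = test_idx, window = window))
}

# non-negative double SVD initialization (zeros filled with the matrix
# mean so HALS cannot stall on exact zeros); seed only perturbs ties
.nndsvdInit <- function(A, k, seed = 1) {
  sv <- svd(A, nu = k, nv = k)
  W <- matrix(0, nrow(A), k); H <- matrix(0, k, ncol(A))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npu <- sqrt(sum(up^2)); nnu <- sqrt(sum(un^2))
    npv <- sqrt(sum(vp^2)); nnv <- sqrt(sum(vn^2))
    if (npu * npv >= nnu * nnv && npu * npv > 0) {
      s <- sqrt(sv$d[j] * npu * npv)
      W[, j] <- s * up / npu; H[j, ] <- s * vp / npv
    } else if (nnu * nnv > 0) {
      s <- sqrt(sv$d[j] * nnu * nnv)
      W[, j] <- s * un / nnu; H[j, ] <- s * vn / nnv
    }
  }
  eps <- mean(A) * 1e-4
  set.seed(seed)
  W[W == 0] <- eps * runif(sum(W == 0))
  H[H == 0] <- eps * runif(sum(H == 0))
  list(W = W, H = H)
}

# HALS updates to a local Frobenius minimum
.halsNmf <- function(A, k, seed = 1, maxit = 4000, tol = 1e-16) {
  init <- .nndsvdInit(A, k, seed)
  W <- init$W; H <- init$H
  nrmA <- sum(A^2)
  err_prev <- Inf
  for (it in seq_len(maxit)) {
    # update H rows
    WtW <- crossprod(W); WtA <- crossprod(W, A)
    for (j in seq_len(k)) {
      if (WtW[j, j] <= 0) next
      H[j, ] <- pmax(0, H[j, ] + (WtA[j, ] - WtW[j, ] %*% H) / WtW[j, j])
    }
    # update W columns
    HHt <- tcrossprod(H); AHt <- tcrossprod(A, H)
    for (j in seq_len(k)) {
      if (HHt[j, j] <= 0) next
      W[, j] <- pmax(0, W[, j] + (AHt[, j] - W %*% HHt[, j]) / HHt[j, j])
    }
    err <- sum((A - W %*% H)^2) / max(nrmA, .Machine$double.eps)
    if (abs(err_prev - err) < tol) break
    err_prev <- err
  }
  list(W = W, H = H, rel_err = err)
}

#' Fit the sign-split NMF
#'
#' The response matrix is split into its positive part and the absolute
#' value of its negative part; each non-negative matrix is factored
#' separately (NNDSVD initialization, HALS updates to a local Frobenius
#' minimum; the seed only perturbs degenerate ties). The signed
#' reconstruction is \code{Wpos Hpos - Wneg Hneg}.
#'
#' @param rm response-matrix list from \code{\link{buildResponseMatrix}},
#'   or a bare matrix
#' @param k_pos,k_neg factor counts per sign (>= 1)
#' @param seed integer seed
#' @return a \code{\linkS4class{FactorSet}}
#' @export
fitSignSplitNmf <- function(rm, k_pos = 3, k_neg = 3, seed = 1L) {
  if (is.matrix(rm))
    rm <- list(train = rm, channels = rownames(rm),
               time_s = numeric(0), freq_hz = numeric(0), split = list())
  stopifnot(k_pos >= 1, k_neg >= 1)
  A <- rm$train
  fitOne <- function(M, k) {
    if (all(M == 0)) {
      warning("all-zero sign component; its factors are empty")
      return(list(W = matrix(0, nrow(M), k), H = matrix(0, k, ncol(M))))
    }
    .halsNmf(M, k, seed = seed)
  }
  pos <- fitOne(pmax(A, 0), k_pos)
  neg <- fitOne(pmax(-A, 0), k_neg)
  ch <- rm$channels
  if (is.null(ch)) ch <- sprintf("ch%02d", seq_len(nrow(A)))
  new("FactorSet", Wpos = pos$W, Wneg = neg$W, Hpos = pos$H, Hneg = neg$H,
      time_s = rm$time_s, freq_hz = rm$freq_hz, channels = ch,
      split = rm$split)
}

# non-negative least squares loadings of rows of M against fixed templates
.nnlsLoadings <- function(M, H) {
  k <- nrow(H)
  C <- t(H)
  W <- matrix(0, nrow(M), k)
  if (all(H == 0)) return(W)
  for (i in seq_len(nrow(M))) W[i, ] <- lsqnonneg(C, M[i, ])$x
  W
}

#' Held-out explained variance of a factor set
#'
#' Loadings are refit on the held-out matrix by non-negative least squares
#' against the fixed templates; EV is
#' \code{1 - ||test - What H||^2 / ||test - mean(test)||^2} on the signed
#' matrix.
#'
#' @param fs a \code{\linkS4class{FactorSet}}
#' @param test held-out channels x (time*frequency) matrix
#' @return scalar explained variance
#' @export
heldOutEV <- function(fs, test) {
  Wp <- .nnlsLoadings(pmax(test, 0), fs@Hpos)
  Wn <- .nnlsLoadings(pmax(-test, 0), fs@Hneg)
  recon <- Wp %*% fs@Hpos - Wn %*% fs@Hneg
  1 - sum((test - recon)^2) / sum((test - mean(test))^2)
}

#' Factor-count selection by held-out explained variance
#'
#' Fits the sign-split NMF for each total factor count in \code{k_grid}
#' (split equally between signs), computes held-out EV with test loadings
#' refit against fixed templates, and chooses the elbow as the point of
#' maximum discrete curvature (second difference) of the EV curve; ties go
#' to the smaller k. A k of 0 scores EV 0.
#'
#' @param rm response matrices from \code{\link{buildResponseMatrix}}
#' @param k_grid ascending even total factor counts (0 allowed)
#' @param seed integer seed
#' @return list with \code{k_grid}, \code{ev}, \code{chosen_k}
#' @export
selectFactorCount <- function(rm, k_grid = c(0, 2, 4, 6, 8, 10), seed = 1L) {
  stopifnot(!is.unsorted(k_grid), all(k_grid %% 2 == 0))
  ev <- vapply(k_grid, function(k) {
    if (k == 0) return(0)
    fs <- fitSignSplitNmf(rm, k_pos = k / 2, k_neg = k / 2, seed = seed)
    heldOutEV(fs, rm$test)
  }, numeric(1))
  m <- length(k_grid)
  if (m >= 3) {
    curv <- 2 * ev[2:(m - 1)] - ev[1:(m - 2)] - ev[3:m]
    chosen <- k_grid[1 + which.max(curv)]   # ties: which.max takes first
  } else chosen <- k_grid[which.max(ev)]
  list(k_grid = k_grid, ev = ev, chosen_k = chosen)
}

#' Condition-wise loading comparison
#'
#' Computes per-condition loadings on held-out trials against the fixed
#' templates, excludes channels whose average baseline-condition loading on
#' a factor is below \code{loading_floor}, and tests the contrast
#' (infusion minus the mean of the baseline conditions) per factor: a
#' paired t-test across surviving channels, or a hierarchical bootstrap
#' (resampling participants, then channels) when participant labels are
#' given.
#'
#' @param fs a \code{\linkS4class{FactorSet}}
#' @param tensors the per-channel tensors the factors were built from
#' @param infusion condition label of the infusion session
#' @param baseline_conditions labels averaged as the baseline reference
#' @param loading_floor exclusion threshold on the average baseline loading
#' @param participants optional per-channel participant labels
#' @param n_boot bootstrap resamples when \code{participants} is given
#' @param seed seed for the bootstrap
#' @return data.frame, one row per factor: \code{factor}, \code{sign},
#'   \code{n_channels}, \code{contrast}, \code{p}
#' @export
compareLoadings <- function(fs, tensors, infusion = "drug",
                            baseline_conditions = c("pre", "post"),
                            loading_floor = 0.1, participants = NULL,
                            n_boot = 1000, seed = 1L) {
  window <- fs@split$window
  test_idx <- fs@split$test
  conds <- unique(tensors[[1]]@condition)
  baseline_conditions <- intersect(baseline_conditions, conds)
  if (length(baseline_conditions) == 0) stop("no baseline conditions present")
  if (!infusion %in% conds) stop("infusion condition absent from tensors")

  condLoad <- function(cn) {
    idx <- which(tensors[[1]]@condition == cn)
    idx_t <- intersect(idx, test_idx)
    if (length(idx_t) == 0) idx_t <- idx   # condition absent from the split
    M <- do.call(rbind, lapply(tensors, .flatAverage, window = window,
                               event_idx = idx_t))
    cbind(.nnlsLoadings(pmax(M, 0), fs@Hpos),
          .nnlsLoadings(pmax(-M, 0), fs@Hneg))
  }
  L <- lapply(setNames(nm = c(baseline_conditions, infusion)), condLoad)
  k_pos <- nrow(fs@Hpos); k_tot <- k_pos + nrow(fs@Hneg)
  base <- Reduce("+", L[baseline_conditions]) / length(baseline_conditions)

  rows <- vector("list", k_tot)
  for (j in seq_len(k_tot)) {
    keep <- which(base[, j] >= loading_floor)
    sgn <- if (j <= k_pos) "positive" else "negative"
    if (length(keep) == 0) {
      rows[[j]] <- data.frame(factor = j, sign = sgn, n_channels = 0,
                              contrast = NA_real_, p = NA_real_)
      next
    }
    contrast <- L[[infusion]][keep, j] - base[keep, j]
    if (!is.null(participants) && length(keep) >= 2) {
      pp <- participants[keep]
      set.seed(substreamSeed(seed, "boot"))
      bm <- replicate(n_boot, {
        ps <- sample(unique(pp), replace = TRUE)
        idx <- unlist(lapply(ps, function(p) {
          ci <- which(pp == p); sample(ci, replace = TRUE)
        }))
        mean(contrast[idx])
      })
      p <- 2 * min(mean(bm <= 0), mean(bm >= 0))
      p <- min(1, max(p, 1 / n_boot))
    } else if (length(keep) >= 2 && sd(contrast) > 0) {
      p <- t.test(contrast)$p.value
    } else p <- NA_real_
    rows[[j]] <- data.frame(factor = j, sign = sgn,
                            n_channels = length(keep),
                            contrast = mean(contrast), p = p)
  }
  out <- do.call(rbind, rows)
  if (all(out$n_channels == 0))
    warning("loading floor excluded every channel on every factor")
  out
}
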