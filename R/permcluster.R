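# Paired cluster-based permutation testing of condition differences in
# peri-event time-frequency tensors, with BH-FDR across regions.

# clusters of supra-threshold cells with one sign, 4-connectivity;
# returns list of (cells matrix, mass)
.signedClusters <- function(tmap, tcrit) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- which(sgn * tmap > tcrit, arr.ind = TRUE)
    if (nrow(mask) == 0) next
    lab <- connectedComponents4(mask)
    for (l in unique(lab)) {
      cells <- mask[lab == l, , drop = FALSE]
      out[[length(out) + 1]] <-
        list(cells = cells, mass = sum(tmap[cells]), sign = sgn)
    }
  }
  out
}

#' Paired cluster-based permutation test
#'
#' One-sample t-test per (time, frequency) cell on paired per-event
#' differences; cells exceeding the two-sided forming threshold are grouped
#' by 4-connectivity within sign; the cluster statistic is the mass (sum of
#' t). The null distribution of the maximum absolute cluster mass is built
#' by random sign flips of whole events, and each observed cluster gets
#' \code{p = (1 + #null >= observed) / (1 + n_perm)}.
#'
#' @param diff_tensor events x time x frequency array of paired differences
#'   (paired by position in the puff sequence)
#' @param forming_alpha two-sided cluster-forming alpha on the cell t-values
#' @param n_perm number of sign-flip permutations (>= 100)
#' @param seed integer seed
#' @param region label carried into the result
#' @return list of class \code{ClusterResult}: \code{t_map},
#'   \code{clusters} (each with cells, mass, sign, p), \code{min_p},
#'   \code{region}, \code{n_events}
#' @export
pairedClusterTest <- function(diff_tensor, forming_alpha = 0.01,
                              n_perm = 1000, seed = 1L, region = "region") {
  if (n_perm < 100) stop("n_perm < 100 gives unstable p-values; refused")
  d <- dim(diff_tensor)
  stopifnot(length(d) == 3, d[1] >= 2)
  n <- d[1]
  X <- matrix(diff_tensor, n)            # events x cells
  tcrit <- qt(1 - forming_alpha / 2, df = n - 1)

  tFromSums <- function(s, SS) {
    m <- s / n
    v <- pmax((SS - n * m^2) / (n - 1), 0)
    ifelse(v > 0, m / sqrt(v / n), 0)
  }
  SS <- colSums(X^2)
  tobs <- tFromSums(colSums(X), SS)
  tmap <- matrix(tobs, d[2], d[3])
  clusters <- .signedClusters(tmap, tcrit)

  if (length(clusters)) {
    set.seed(substreamSeed(seed, "perm"))
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Tperm <- tFromSums(flips %*% X, rep(1, n_perm) %o% SS)
    null_max <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      tp <- matrix(Tperm[p, ], d[2], d[3])
      cl <- .signedClusters(tp, tcrit)
      null_max[p] <- if (length(cl))
        max(vapply(cl, function(x) abs(x$mass), numeric(1))) else 0
    }
    for (i in seq_along(clusters))
      clusters[[i]]$p <- (1 + sum(null_max >= abs(clusters[[i]]$mass))) /
        (1 + n_perm)
  }
  min_p <- if (length(clusters))
    min(vapply(clusters, function(x) x$p, numeric(1))) else 1
  structure(list(t_map = tmap, clusters = clusters, min_p = min_p,
                 region = region, n_events = n,
                 forming_alpha = forming_alpha),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult [%s]: %d events, %d clusters, min p = %.4g\n",
              x$region, x$n_events, length(x$clusters), x$min_p))
  invisible(x)
}

#' Benjamini-Hochberg correction across regions
#'
#' Applies BH to each region's most significant cluster p-value; regions
#' with corrected p below \code{q} are flagged, and within flagged regions
#' every cluster with raw p below \code{raw_alpha} is reported.
#'
#' @param results list of \code{ClusterResult}
#' @param q FDR threshold on the corrected minimum p
#' @param raw_alpha raw-p threshold for reporting clusters within flagged
#'   regions
#' @return data.frame: \code{region}, \code{min_p}, \code{p_corrected},
#'   \code{significant}, \code{n_reported_clusters}
#' @export
fdrAcrossRegions <- function(results, q = 0.01, raw_alpha = 0.01) {
  if (length(results) == 0)
    return(data.frame(region = character(0), min_p = numeric(0),
                      p_corrected = numeric(0), significant = logical(0),
                      n_reported_clusters = integer(0)))
  min_p <- vapply(results, function(r) r$min_p, numeric(1))
  region <- vapply(results, function(r) r$region, character(1))
  p_adj <- p.adjust(min_p, method = "BH")
  sig <- p_adj < q
  n_rep <- vapply(seq_along(results), function(i) {
    if (!sig[i]) return(0L)
    sum(vapply(results[[i]]$clusters, function(cl) cl$p < raw_alpha,
               logical(1)))
  }, integer(1))
  data.frame(region = region, min_p = min_p, p_corrected = p_adj,
             significant = sig, n_reported_clusters = n_rep)
}
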