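#' Fuzzy c-means clustering of lifespan trajectories
#'
#' Standard fuzzy c-means with Euclidean distance: centers are
#' membership^fuzzifier-weighted means, memberships are inverse-distance
#' ratios with exponent 2/(fuzzifier - 1). Iteration stops when the
#' objective improves by less than `tol` or after `max_iter` iterations.
#' A point coinciding with a center gets its membership concentrated on
#' the coincident center(s), split equally if several coincide
#' (documented tie rule). Clusters are canonically
#' ordered by decreasing winner-take-all size (ties by first occurrence),
#' so cluster 1 is always the largest.
#'
#' @param x Numeric matrix, rows = items (parcel trajectories).
#' @param n_clusters Number of clusters, >= 2 and <= nrow(x).
#' @param fuzzifier Fuzzy partition exponent (> 1; default 5).
#' @param max_iter Maximum iterations (default 10000).
#' @param tol Minimum objective improvement (default 1e-5).
#' @param seed Optional integer seed for the random membership init.
#' @return An object of class `fcm_membership`: list(u, labels, tie,
#'   centers, objective_trace, n_iter, converged).
#' @export
fuzzy_cmeans <- function(x, n_clusters, fuzzifier = 5, max_iter = 10000,
                         tol = 1e-5, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_clusters < 2) stop("n_clusters must be >= 2", call. = FALSE)
  if (n < n_clusters) stop("need at least n_clusters rows", call. = FALSE)
  if (fuzzifier <= 1) stop("fuzzifier must be > 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(runif(n * n_clusters), nrow = n)
  u <- u / rowSums(u)
  expo <- -1 / (fuzzifier - 1)          # applied to squared distances
  trace <- numeric(0)
  j_prev <- Inf
  converged <- FALSE
  iter <- 0L
  centers <- NULL
  repeat {
    iter <- iter + 1L
    w <- u^fuzzifier
    centers <- (t(w) %*% x) / colSums(w)
    d2 <- outer(rowSums(x^2), rep(1, n_clusters)) -
      2 * x %*% t(centers) + outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    j_now <- sum(w * d2)
    trace <- c(trace, j_now)
    if (abs(j_prev - j_now) < tol || iter >= max_iter) {
      converged <- abs(j_prev - j_now) < tol
      break
    }
    j_prev <- j_now
    zero <- d2 < .Machine$double.eps
    t_ <- d2^expo
    u <- t_ / rowSums(t_)
    hit <- which(rowSums(zero) > 0)
    for (i in hit) {
      u[i, ] <- 0
      u[i, zero[i, ]] <- 1 / sum(zero[i, ])
    }
  }
  # canonical ordering: largest winner-take-all cluster first
  lab0 <- max.col(u, ties.method = "first")
  sizes <- tabulate(lab0, nbins = n_clusters)
  ord <- order(-sizes, seq_len(n_clusters))
  u <- u[, ord, drop = FALSE]
  centers <- centers[ord, , drop = FALSE]
  wta <- winner_take_all(u)
  structure(list(u = u, labels = wta$labels, tie = wta$tie,
                 centers = centers, objective_trace = trace,
                 n_iter = iter, converged = converged),
            class = "fcm_membership")
}

#' Winner-take-all labels from a fuzzy membership matrix
#'
#' Argmax per row; exact ties resolve to the lowest cluster index and are
#' flagged.
#'
#' @param u Membership matrix (rows sum to 1).
#' @return list(labels = integer vector, tie = logical vector).
#' @export
winner_take_all <- function(u) {
  u <- as.matrix(u)
  labels <- max.col(u, ties.method = "first")
  rowmax <- u[cbind(seq_len(nrow(u)), labels)]
  tie <- rowSums(abs(u - rowmax) < .Machine$double.eps * 4) > 1
  list(labels = labels, tie = tie)
}

#' Select the cluster count by mean silhouette
#'
#' Runs fuzzy c-means for each candidate count, converts memberships to
#' winner-take-all labels, and scores the partition by mean Euclidean
#' silhouette width. A candidate that collapses to a single non-empty
#' cluster scores -1. The chosen count is the argmax.
#'
#' @param x Trajectory matrix.
#' @param candidates Candidate cluster counts (default 2:15).
#' @param fuzzifier,max_iter,tol As in [fuzzy_cmeans()].
#' @param seed Base seed; candidate k uses `seed + k`.
#' @return list(candidate_n, silhouette, chosen_n, memberships).
#' @export
silhouette_select <- function(x, candidates = 2:15, fuzzifier = 5,
                              max_iter = 10000, tol = 1e-5, seed = 1L) {
  x <- as.matrix(x)
  candidates <- candidates[candidates <= nrow(x)]
  if (!length(candidates)) stop("no feasible candidate counts", call. = FALSE)
  dx <- stats::dist(x)
  fits <- list()
  scores <- vapply(candidates, function(k) {
    fit <- fuzzy_cmeans(x, k, fuzzifier = fuzzifier, max_iter = max_iter,
                        tol = tol, seed = seed + k)
    fits[[as.character(k)]] <<- fit
    if (length(unique(fit$labels)) < 2) return(-1)
    mean(cluster::silhouette(fit$labels, dx)[, "sil_width"])
  }, numeric(1))
  chosen <- candidates[which.max(scores)]
  list(candidate_n = candidates, silhouette = scores, chosen_n = chosen,
       memberships = fits)
}

#' RSN-cluster correspondence index
#'
#' For each network r and cluster c, sums the product of the parcels' RSN
#' probability and fuzzy membership, then normalizes within cluster so the
#' indices sum to one across networks — making clusters of different sizes
#' comparable.
#'
#' @param u Membership matrix (parcels x clusters).
#' @param rsn_probs Matrix of RSN probabilities (parcels x networks),
#'   aligned to the rows of `u`.
#' @return Matrix networks x clusters of normalized indices.
#' @export
rsn_correspondence_index <- function(u, rsn_probs) {
  u <- as.matrix(u)
  rsn_probs <- as.matrix(rsn_probs)
  if (nrow(u) != nrow(rsn_probs))
    stop("membership and RSN probability rows must align", call. = FALSE)
  if (all(rsn_probs == 0))
    stop("RSN probabilities are all zero", call. = FALSE)
  raw <- t(rsn_probs) %*% u
  tot <- colSums(raw)
  if (any(tot <= 0)) stop("cluster with zero total membership mass",
                          call. = FALSE)
  sweep(raw, 2, tot, "/")
}
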