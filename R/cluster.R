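#' Pairwise Pearson correlation matrix over measure columns
#'
#' Correlations are computed pairwise-complete: for each pair of columns
#' only the animals with both values are used, and the per-pair n is carried
#' into the t-transform p value.  This keeps pre-surgery columns (n animals)
#' and post-surgery columns (fewer animals after attrition) in one matrix.
#'
#' @param table Measure table (data.frame, one row per animal).
#' @param columns Character vector of measure columns to correlate.
#' @return An object of class `etho_corr`: list with `measures`, symmetric
#'   unit-diagonal `r`, symmetric `p`, pairwise `n`, and `order` (the
#'   angular-order-of-eigenvectors display permutation).
#' @export
correlation_matrix <- function(table, columns = pre_measure_names()) {
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop("unknown measure column(s): ", paste(missing_cols, collapse = ", "),
         "; valid names are: ", paste(names(table), collapse = ", "),
         call. = FALSE)
  mat <- as.matrix(table[, columns, drop = FALSE])
  m <- ncol(mat)
  obs <- !is.na(mat)
  npair <- crossprod(obs)
  if (any(npair < 3))
    stop("correlation_matrix: every column pair needs >= 3 complete rows",
         call. = FALSE)
  for (j in seq_len(m)) {
    v <- mat[obs[, j], j]
    if (stats::sd(v) == 0)
      stop("correlation_matrix: column '", columns[j], "' is constant",
           call. = FALSE)
  }
  r <- stats::cor(mat, use = "pairwise.complete.obs")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  p <- matrix(1, m, m, dimnames = dimnames(r))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) p[i, j] <- p_from_r(r[i, j], npair[i, j])
    }
  }
  res <- structure(list(measures = columns, r = r, p = p, n = npair),
                   class = "etho_corr")
  res$order <- aoe_order(res)
  res
}

#' Angular-order-of-eigenvectors display permutation
#'
#' Computes the two leading eigenvectors of the correlation matrix, fixes
#' their signs (each flipped if its entries sum to a negative value), maps
#' each measure to the angle `atan2(e2_i, e1_i)` in \[0, 2*pi) and sorts
#' ascending, so strongly inter-correlated measures end up adjacent in the
#' displayed matrix.  Ties keep input order.
#'
#' @param corr An `etho_corr` (or a bare correlation matrix).
#' @return Integer permutation of the measures.
#' @export
aoe_order <- function(corr) {
  r <- if (inherits(corr, "etho_corr")) corr$r else as.matrix(corr)
  off <- r
  diag(off) <- 0
  # fully uncorrelated matrix: every ordering is equivalent; keep input order
  if (max(abs(off)) < 1e-12) return(seq_len(nrow(r)))
  ed <- eigen(r, symmetric = TRUE)
  e1 <- ed$vectors[, 1]
  e2 <- ed$vectors[, 2]
  if (sum(e1) < 0) e1 <- -e1
  if (sum(e2) < 0) e2 <- -e2
  ang <- atan2(e2, e1) %% (2 * pi)
  order(ang)
}

#' Convert a correlation matrix to a 1 - |r| distance matrix
#'
#' Directionality is deliberately discarded: perfectly correlated and
#' perfectly anti-correlated measures both map to distance 0, uncorrelated
#' measures to distance 1.
#'
#' @param corr An `etho_corr` or correlation matrix.
#' @return An object of class `etho_dist`: list with `measures` and the
#'   symmetric zero-diagonal `d` matrix, entries in \[0, 1\].
#' @export
correlation_to_distance <- function(corr) {
  r <- if (inherits(corr, "etho_corr")) corr$r else as.matrix(corr)
  d <- 1 - abs(r)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(list(measures = rownames(r), d = d), class = "etho_dist")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes, and returns
#' coordinates scaled by the square roots of the positive eigenvalues
#' (negative eigenvalues are dropped, with a warning if fewer than `dims`
#' positive eigenvalues exist).  Per-axis signs are fixed so the
#' largest-magnitude coordinate on each axis is positive, making the
#' embedding deterministic.
#'
#' @param dist An `etho_dist` or symmetric distance matrix.
#' @param dims Target dimensionality (default 2).
#' @return An object of class `etho_mds`: list with `points` (rows =
#'   measures) and `eig` (all eigenvalues, descending).
#' @export
classical_mds <- function(dist, dims = 2) {
  d <- if (inherits(dist, "etho_dist")) dist$d else as.matrix(dist)
  n <- nrow(d)
  fit <- withCallingHandlers(
    stats::cmdscale(stats::as.dist(d), k = min(dims, n - 1), eig = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  pts <- fit$points
  n_pos <- sum(fit$eig > 1e-10)
  if (n_pos < dims)
    warning("classical_mds: only ", n_pos, " positive eigenvalue(s); ",
            "returning ", min(ncol(pts), max(n_pos, 1)), " axis/axes",
            call. = FALSE)
  if (ncol(pts) > 0 && n_pos > 0 && ncol(pts) > n_pos)
    pts <- pts[, seq_len(n_pos), drop = FALSE]
  if (ncol(pts) == 0)  # fully degenerate: all objects coincide at the origin
    pts <- matrix(0, n, 1)
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  structure(list(points = pts, eig = fit$eig), class = "etho_mds")
}

# squared Euclidean distances from points to centers
dist2_to_centers <- function(points, centers) {
  outer(rowSums(points^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(points)), rowSums(centers^2)) -
    2 * points %*% t(centers)
}

# relabel so cluster ids appear in first-appearance order
canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}

#' K-means clustering (Lloyd's algorithm, spread-out seeding)
#'
#' Centers are seeded greedily: the first is a randomly chosen point, each
#' subsequent one the point farthest from all chosen centers
#' (farthest-first traversal, ties to the lowest index).  Lloyd iterations
#' then alternate assignment and centroid updates; an emptied cluster is
#' refilled with the point farthest from its center.  The best of
#' `restarts` runs by within-cluster sum of squares is returned, labels
#' canonicalized by first appearance.  Deterministic for a fixed seed.
#'
#' @param points Numeric matrix, one row per object.
#' @param k Number of clusters (<= number of points).
#' @param seed Integer seed for the restart draws.
#' @param restarts Number of independent seedings (>= 1).
#' @return List with `labels`, `centers`, `inertia` (total within-cluster
#'   sum of squares) and `wcss_trace` (per-iteration WCSS of the winning
#'   run, non-increasing).
#' @export
kmeans_cluster <- function(points, k, seed = 1L, restarts = 10L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("kmeans_cluster: k exceeds number of points", call. = FALSE)
  if (restarts < 1L) stop("kmeans_cluster: restarts must be >= 1", call. = FALSE)
  if (k < 1L) stop("kmeans_cluster: k must be >= 1", call. = FALSE)

  run_once <- function(first) {
    centers_idx <- first
    while (length(centers_idx) < k) {
      d2 <- dist2_to_centers(points, points[centers_idx, , drop = FALSE])
      mind <- apply(d2, 1, min)
      centers_idx <- c(centers_idx, which.max(mind))
    }
    centers <- points[centers_idx, , drop = FALSE]
    labels <- rep(0L, n)
    trace <- numeric(0)
    for (iter in 1:100) {
      d2 <- dist2_to_centers(points, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      for (c_id in seq_len(k)) {       # refill emptied clusters
        if (!any(new_labels == c_id)) {
          far <- which.max(apply(d2, 1, min))
          new_labels[far] <- c_id
          d2[far, ] <- 0
        }
      }
      wcss <- sum(vapply(seq_len(k), function(c_id) {
        pc <- points[new_labels == c_id, , drop = FALSE]
        ctr <- colMeans(pc)
        sum(sweep(pc, 2, ctr)^2)
      }, numeric(1)))
      trace <- c(trace, wcss)
      if (identical(new_labels, labels)) break
      labels <- new_labels
      centers <- do.call(rbind, lapply(seq_len(k), function(c_id)
        colMeans(points[labels == c_id, , drop = FALSE])))
    }
    list(labels = labels, centers = centers, inertia = wcss, trace = trace)
  }

  firsts <- with_local_seed(seed,
    sample.int(n, restarts, replace = restarts > n))
  best <- NULL
  for (f in firsts) {
    res <- run_once(f)
    if (is.null(best) || res$inertia < best$inertia - 1e-12) best <- res
  }
  lab <- canonicalize_labels(best$labels)
  centers <- do.call(rbind, lapply(sort(unique(lab)), function(c_id)
    colMeans(points[lab == c_id, , drop = FALSE])))
  list(labels = lab, centers = centers, inertia = best$inertia,
       wcss_trace = best$trace)
}

# ---- internal cluster-validity indices ------------------------------------

index_silhouette <- function(points, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(labels, stats::dist(points))
  mean(sil[, "sil_width"])
}

index_calinski_harabasz <- function(points, labels) {
  n <- nrow(points)
  k <- length(unique(labels))
  if (k < 2L || k >= n) return(NA_real_)
  grand <- colMeans(points)
  B <- 0
  W <- 0
  for (c_id in unique(labels)) {
    pc <- points[labels == c_id, , drop = FALSE]
    ctr <- colMeans(pc)
    B <- B + nrow(pc) * sum((ctr - grand)^2)
    W <- W + sum(sweep(pc, 2, ctr)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

index_davies_bouldin <- function(points, labels) {
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2L) return(NA_real_)
  ctrs <- do.call(rbind, lapply(ids, function(c_id)
    colMeans(points[labels == c_id, , drop = FALSE])))
  S <- vapply(seq_along(ids), function(i) {
    pc <- points[labels == ids[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pc, 2, ctrs[i, ])^2)))
  }, numeric(1))
  D <- as.matrix(stats::dist(ctrs))
  mean(vapply(seq_len(k), function(i) {
    ratio <- (S[i] + S[-i]) / D[i, -i]
    max(ratio[is.finite(ratio)], 0)
  }, numeric(1)))
}

index_dunn <- function(points, labels) {
  ids <- sort(unique(labels))
  if (length(ids) < 2L) return(NA_real_)
  D <- as.matrix(stats::dist(points))
  intra <- max(vapply(ids, function(c_id) {
    w <- which(labels == c_id)
    if (length(w) < 2L) 0 else max(D[w, w])
  }, numeric(1)))
  inter <- min(vapply(seq_along(ids)[-1], function(i) {
    min(vapply(seq_len(i - 1), function(j) {
      min(D[labels == ids[i], labels == ids[j]])
    }, numeric(1)))
  }, numeric(1)))
  if (intra == 0) return(Inf)
  inter / intra
}

#' Select the number of k-means clusters by a four-index vote
#'
#' For each k in `[k_min, k_max]` the k-means solution is scored by four
#' internal validity indices: mean silhouette width (maximum is best),
#' Calinski-Harabasz (max), Davies-Bouldin (min) and Dunn (max).  Each index
#' votes for its best k (per-index ties to the smallest k); the k with most
#' votes wins, ties broken by the smallest voted k.
#'
#' @param points Numeric matrix of objects to cluster.
#' @param k_min,k_max Search range; `k_min >= 2`,
#'   `k_max <= nrow(points) - 1`.
#' @param seed Seed forwarded to [kmeans_cluster()].
#' @param restarts Restarts per k.
#' @return List with `k` (chosen), `votes` (per index), `index_table`
#'   (per-k index values) and `solutions` (k-means result per k).
#' @export
select_k <- function(points, k_min = 2L, k_max, seed = 1L, restarts = 10L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k_min < 2L) stop("select_k: k_min must be >= 2", call. = FALSE)
  if (k_max > n - 1L)
    stop("select_k: k_max must be <= number of points - 1", call. = FALSE)
  if (k_max < k_min) stop("select_k: empty k range", call. = FALSE)
  ks <- k_min:k_max
  sols <- lapply(ks, function(k) kmeans_cluster(points, k, seed = seed,
                                                restarts = restarts))
  names(sols) <- ks
  idx <- data.frame(
    k = ks,
    silhouette = vapply(sols, function(s) index_silhouette(points, s$labels),
                        numeric(1)),
    calinski_harabasz = vapply(sols, function(s)
      index_calinski_harabasz(points, s$labels), numeric(1)),
    davies_bouldin = vapply(sols, function(s)
      index_davies_bouldin(points, s$labels), numeric(1)),
    dunn = vapply(sols, function(s) index_dunn(points, s$labels), numeric(1))
  )
  vote_best <- function(vals, maximize) {
    v <- if (maximize) vals else -vals
    v[!is.finite(v) & !is.infinite(v)] <- -Inf
    ks[which.max(v)]  # which.max takes the first (smallest k) on ties
  }
  votes <- c(silhouette = vote_best(idx$silhouette, TRUE),
             calinski_harabasz = vote_best(idx$calinski_harabasz, TRUE),
             davies_bouldin = vote_best(idx$davies_bouldin, FALSE),
             dunn = vote_best(idx$dunn, TRUE))
  tally <- table(votes)
  winners <- as.integer(names(tally)[tally == max(tally)])
  k_star <- min(winners)
  list(k = k_star, votes = votes, index_table = idx, solutions = sols)
}

#' Full data-reduction pipeline over a measure table
#'
#' Composes the stages of the correlation-based data reduction: pairwise
#' Pearson correlation matrix (with angular-order-of-eigenvectors display
#' permutation), conversion to the 1 - |r| distance, classical MDS to two
#' dimensions, cluster-count selection by the four-index vote and k-means
#' clustering at the chosen k.  All intermediates are returned for audit.
#'
#' @param table Measure table.
#' @param columns Measure columns to include.
#' @param k_min,k_max Cluster-count search range.
#' @param seed Seed for the k-means restarts.
#' @return An object of class `etho_clustering`: list with `correlation`,
#'   `distance`, `mds`, `selection`, `k`, `labels` (named by measure) and
#'   `mds_error` (maximum absolute error between embedded and input
#'   distances; the 1 - |r| matrix is generally non-Euclidean, so this is
#'   reported, never hidden).
#' @export
run_clustering <- function(table, columns = pre_measure_names(),
                           k_min = 2L, k_max = 6L, seed = 1L) {
  corr <- correlation_matrix(table, columns)
  dist <- correlation_to_distance(corr)
  mds <- classical_mds(dist, dims = 2)
  emb <- as.matrix(stats::dist(mds$points))
  mds_error <- max(abs(emb - dist$d))
  sel <- select_k(mds$points, k_min = k_min, k_max = k_max, seed = seed)
  labels <- sel$solutions[[as.character(sel$k)]]$labels
  names(labels) <- columns
  structure(list(correlation = corr, distance = dist, mds = mds,
                 selection = sel, k = sel$k, labels = labels,
                 mds_error = mds_error, k_range = c(k_min, k_max)),
            class = "etho_clustering")
}

#' @export
print.etho_clustering <- function(x, ...) {
  cat("Correlation -> 1-|r| distance -> classical MDS -> k-means\n")
  cat("  measures:", length(x$labels), "  chosen k:", x$k,
      " (range", x$k_range[1], "-", x$k_range[2], ")\n")
  cat("  votes:", paste(names(x$selection$votes), x$selection$votes,
                        sep = "=", collapse = ", "), "\n")
  cat("  max |embedded - input| distance:", format(x$mds_error, digits = 3),
      "\n")
  for (c_id in sort(unique(x$labels))) {
    cat("  cluster ", c_id, ": ",
        paste(names(x$labels)[x$labels == c_id], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
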