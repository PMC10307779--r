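test_that("correlation matrix matches a brute-force pairwise loop", {
  set.seed(11)
  tab <- as.data.frame(matrix(rnorm(15 * 8), 15, 8))
  names(tab) <- paste0("m", 1:8)
  res <- correlation_matrix(tab, names(tab))
  o <- oracle_corr(tab, names(tab))
  expect_equal(res$r, o$r, tolerance = 1e-12)
  expect_equal(res$p[upper.tri(res$p)], o$p[upper.tri(o$p)],
               tolerance = 1e-12)
  expect_equal(res$r, t(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 8))

  # pairwise-complete handling: per-pair n feeds the p transform
  tab$m1[1:2] <- NA
  res2 <- correlation_matrix(tab, names(tab))
  o2 <- oracle_corr(tab, names(tab))
  expect_equal(res2$r, o2$r, tolerance = 1e-12)
  expect_equal(res2$p[1, 2], o2$p[1, 2], tolerance = 1e-12)
  expect_equal(res2$n[1, 2], 13)

  tab$m2 <- tab$m1 * -1
  expect_equal(correlation_matrix(tab, c("m1", "m2"))$r[1, 2], -1)
  tab$m2 <- tab$m1
  expect_equal(correlation_matrix(tab, c("m1", "m2"))$r[1, 2], 1)
  tab$m3 <- 1
  expect_error(correlation_matrix(tab, c("m1", "m3")), "m3.*constant")
  expect_error(correlation_matrix(tab, c("m1", "nope")), "unknown measure")
})

test_that("angular eigenvector ordering groups correlated blocks", {
  expect_equal(aoe_order(diag(2)), c(1, 2))
  # two strong 2-blocks (unequal strengths keep the eigenvalues simple):
  # block members must be adjacent in the ordering
  R <- diag(4)
  R[1, 3] <- R[3, 1] <- 0.95
  R[2, 4] <- R[4, 2] <- 0.80
  ord <- aoe_order(R)
  pos <- order(ord)  # position of each measure in the display
  expect_equal(abs(pos[1] - pos[3]), 1)
  expect_equal(abs(pos[2] - pos[4]), 1)

  # permuting the input permutes the ordering consistently (same cyclic
  # neighbor structure of measure names)
  set.seed(12)
  tab <- as.data.frame(matrix(rnorm(30 * 5), 30, 5))
  names(tab) <- paste0("m", 1:5)
  cr <- correlation_matrix(tab, names(tab))
  perm <- c(3, 5, 1, 2, 4)
  cr_p <- correlation_matrix(tab, names(tab)[perm])
  ring <- function(x) {  # canonical rotation of a cyclic sequence
    k <- which(x == min(x))[1]
    x[c(k:length(x), seq_len(k - 1))]
  }
  expect_equal(ring(cr$measures[cr$order]),
               ring(cr_p$measures[cr_p$order]))
})

test_that("the 1-|r| distance discards directionality", {
  R <- matrix(c(1, -0.728, -0.728, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  d <- correlation_to_distance(R)
  expect_equal(d$d["a", "b"], 0.272)
  expect_equal(correlation_to_distance(matrix(c(1, 1, 1, 1), 2))$d[1, 2], 0)
  expect_equal(correlation_to_distance(matrix(c(1, -1, -1, 1), 2))$d[1, 2], 0)
  expect_equal(correlation_to_distance(diag(2))$d[1, 2], 1)
  set.seed(13)
  tab <- as.data.frame(matrix(rnorm(20 * 6), 20, 6))
  dd <- correlation_to_distance(correlation_matrix(tab, names(tab)))$d
  expect_equal(unname(diag(dd)), rep(0, 6))
  expect_equal(dd, t(dd))
  expect_true(all(dd >= 0 & dd <= 1))
})

test_that("classical MDS reconstructs Euclidean-embeddable distances", {
  # 3-4-5 right triangle
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
  mds <- classical_mds(D, dims = 2)
  expect_equal(as.matrix(dist(mds$points)), as.matrix(D),
               tolerance = 1e-9, ignore_attr = TRUE)
  # axis-sign convention: the largest-magnitude coordinate per axis positive
  for (j in seq_len(ncol(mds$points)))
    expect_gt(mds$points[which.max(abs(mds$points[, j])), j], 0)

  # degenerate geometries
  expect_warning(z <- classical_mds(matrix(0, 3, 3), dims = 2), "positive")
  expect_true(all(z$points == z$points[1, 1]))
  line <- as.matrix(dist(cbind(c(0, 1, 3, 6))))
  expect_warning(l1 <- classical_mds(line, dims = 2), "positive")
  expect_equal(ncol(l1$points), 1)
  expect_equal(as.matrix(dist(l1$points)), line, tolerance = 1e-9,
               ignore_attr = TRUE)

  # random Euclidean point sets embed exactly
  set.seed(14)
  for (rep in 1:5) {
    pts <- matrix(rnorm(12), 6, 2)
    D <- as.matrix(dist(pts))
    m <- classical_mds(D, dims = 2)
    expect_equal(as.matrix(dist(m$points)), D, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("k-means descends monotonically and recovers planted blobs", {
  set.seed(15)
  blob <- function(cx, cy, n = 20) cbind(rnorm(n, cx, 0.3), rnorm(n, cy, 0.3))
  pts <- rbind(blob(0, 0), blob(10, 0))
  truth <- rep(1:2, each = 20)
  km <- kmeans_cluster(pts, 2, seed = 1, restarts = 5)
  expect_true(same_partition(km$labels, truth))
  expect_true(all(diff(km$wcss_trace) <= 1e-9))  # monotone descent
  # agreement with the stats::kmeans oracle on the same separated data
  ref <- kmeans(pts, 2, nstart = 10)
  expect_equal(km$inertia, ref$tot.withinss, tolerance = 1e-8)

  km1 <- kmeans_cluster(pts, 1, seed = 1)
  ctr <- colMeans(pts)
  expect_equal(km1$inertia, sum(sweep(pts, 2, ctr)^2), tolerance = 1e-9)
  expect_equal(km1$labels, rep(1L, nrow(pts)))

  # duplicated points always share a label; fixed seed is deterministic
  dup <- rbind(pts, pts[1, ], pts[1, ])
  kd <- kmeans_cluster(dup, 2, seed = 7)
  expect_equal(kd$labels[41], kd$labels[42])
  expect_equal(kd$labels[41], kd$labels[1])
  expect_identical(kmeans_cluster(pts, 3, seed = 9),
                   kmeans_cluster(pts, 3, seed = 9))
  expect_error(kmeans_cluster(pts, nrow(pts) + 1, seed = 1), "exceeds")
})

test_that("the four-index vote selects planted cluster counts", {
  set.seed(16)
  blob <- function(cx, cy, n = 15) cbind(rnorm(n, cx, 0.4), rnorm(n, cy, 0.4))
  three <- rbind(blob(0, 0), blob(8, 0), blob(4, 7))
  sel3 <- select_k(three, 2, 6, seed = 2)
  expect_equal(sel3$k, 3)
  two <- rbind(blob(0, 0), blob(9, 0))
  sel2 <- select_k(two, 2, 4, seed = 2)
  expect_equal(sel2$k, 2)
  expect_equal(nrow(sel2$index_table), 3)

  # invariance to rigid rotation and uniform scaling
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sel3r <- select_k(3.7 * three %*% rot, 2, 6, seed = 2)
  expect_equal(sel3r$k, sel3$k)
  expect_true(same_partition(
    sel3r$solutions[[as.character(sel3r$k)]]$labels,
    sel3$solutions[[as.character(sel3$k)]]$labels))

  expect_error(select_k(three, 1, 4, seed = 1), "k_min")
  expect_error(select_k(three[1:4, ], 2, 4, seed = 1), "k_max")
})

test_that("the vote tie-break takes the smallest voted k", {
  votes <- c(silhouette = 4L, calinski_harabasz = 2L,
             davies_bouldin = 5L, dunn = 3L)
  tally <- table(votes)
  winners <- as.integer(names(tally)[tally == max(tally)])
  expect_equal(min(winners), 2L)  # documents the rule the pipeline applies
  # and the pipeline applies it: constructed geometry where indices disagree
  set.seed(17)
  pts <- rbind(cbind(rnorm(8, 0, 1.2), rnorm(8, 0, 1.2)),
               cbind(rnorm(8, 3, 1.2), rnorm(8, 3, 1.2)))
  sel <- select_k(pts, 2, 5, seed = 3)
  tly <- table(sel$votes)
  wins <- as.integer(names(tly)[tly == max(tly)])
  expect_equal(sel$k, min(wins))
})

test_that("the full pipeline recovers planted structure end to end", {
  cfg <- generator_config(n_animals = 200L, seed = 303L,
                          latent_corr = block_latent_corr())
  tab <- build_measure_table(generate_study(cfg))
  res <- run_clustering(tab, pre_measure_names(), k_min = 2, k_max = 6,
                        seed = 5)
  expect_equal(res$k, 3)
  expect_true(same_partition(res$labels, block_membership))
  # deterministic given seed and input
  res2 <- run_clustering(tab, pre_measure_names(), k_min = 2, k_max = 6,
                         seed = 5)
  expect_identical(res$labels, res2$labels)
  expect_identical(res$mds$points, res2$mds$points)
  # the 1-|r| matrix is generally non-Euclidean: the reconstruction error
  # must be reported
  expect_true(is.finite(res$mds_error))

  # orthogonal latent structure: no stable clustering, but a well-formed
  # report with labels covering every measure exactly once
  cfg0 <- generator_config(n_animals = 60L, seed = 304L,
                           latent_corr = diag(8))
  dimnames(cfg0$latent_corr) <- list(trait_names(), trait_names())
  tab0 <- build_measure_table(generate_study(cfg0))
  res0 <- run_clustering(tab0, pre_measure_names(), 2, 6, seed = 5)
  expect_length(res0$labels, 8)
  expect_named(res0$labels, pre_measure_names())
  expect_true(res0$k >= 2 && res0$k <= 6)
  expect_setequal(unique(unname(res0$labels)), seq_len(res0$k))
})
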