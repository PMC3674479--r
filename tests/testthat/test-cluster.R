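test_that("discretized marginals are normalized on the shared binning", {
  set.seed(41)
  fake <- structure(list(
    samples = cbind(D = runif(7500, 0, 2), F = runif(7500, 0, 2),
                    U = runif(7500), f = runif(7500)),
    prior = prior_box("etm")), class = "stp_posterior")
  m <- discretize_marginals(fake, n_bins = 20)
  expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-9)
  # uniform samples give near-uniform bins
  expect_lt(max(m["U", ]) / min(m["U", ]), 1.5)
  # concentrated samples put all mass in one bin
  fake$samples[, "U"] <- 0.205
  m2 <- discretize_marginals(fake, n_bins = 10)
  expect_gt(m2["U", 3], 0.999)
  expect_error(discretize_marginals(fake, n_bins = 1), "n_bins")
})

test_that("divergences satisfy their identities and match direct formulas", {
  p <- c(0.5, 0.5)
  q <- c(0.9, 0.1)
  expect_equal(skl_divergence(p, p), 0)
  expect_equal(hellinger_distance(q, q), 0)
  skl_direct <- (sum(p * log(p / q)) + sum(q * log(q / p))) / 2
  expect_equal(skl_divergence(p, q), skl_direct, tolerance = 1e-12)
  expect_identical(skl_divergence(p, q), skl_divergence(q, p))
  expect_equal(hellinger_distance(c(1, 0), c(0, 1)), 1)
  set.seed(42)
  a <- runif(30); a <- a / sum(a)
  b <- runif(30); b <- b / sum(b)
  expect_equal(hellinger_distance(a, b),
               sqrt(0.5 * sum((sqrt(a) - sqrt(b))^2)), tolerance = 1e-12)
  expect_equal(hellinger_distance(a, b), hellinger_distance(b, a))
  expect_error(skl_divergence(a, b[-1]), "equal length")
})

test_that("connection distance sums the per-parameter divergences", {
  mk <- function(seed) {
    set.seed(seed)
    v <- matrix(runif(4 * 25), nrow = 4,
                dimnames = list(c("D", "F", "U", "f"), NULL))
    v <- v / rowSums(v)
    structure(v, class = "stp_marginals", box = prior_box("etm"))
  }
  a <- mk(1); b <- mk(2)
  expect_equal(connection_distance(a, a), 0, tolerance = 1e-12)
  expect_equal(connection_distance(a, b), connection_distance(b, a))
  direct <- sum(vapply(1:4, function(i) hellinger_distance(a[i, ], b[i, ]),
                       numeric(1)))
  expect_equal(connection_distance(a, b, "hellinger"), direct,
               tolerance = 1e-12)
  direct_skl <- sum(vapply(1:4, function(i) skl_divergence(a[i, ], b[i, ]),
                           numeric(1)))
  expect_equal(connection_distance(a, b, "skl"), direct_skl,
               tolerance = 1e-12)
})

test_that("UPGMA reproduces a hand-worked 4-point example", {
  # distances: d(1,2)=2, d(3,4)=3, cross pairs 8,9,10,11
  d <- matrix(c(0, 2, 8, 9,
                2, 0, 10, 11,
                8, 10, 0, 3,
                9, 11, 3, 0), 4, 4, byrow = TRUE)
  hc <- agglomerative_cluster(d)
  # merge 1: {1,2} at height 2; merge 2: {3,4} at 3;
  # merge 3: average of cross distances (8+9+10+11)/4 = 9.5
  expect_equal(hc$height, c(2, 3, 9.5))
  expect_equal(hc$merge[1, ], c(-1, -2))
  expect_equal(hc$merge[2, ], c(-3, -4))
  expect_equal(hc$merge[3, ], c(1, 2))
  # two tight groups far apart: top split separates them
  expect_equal(unname(cutree(hc, 2)), c(1, 1, 2, 2))
  expect_error(agglomerative_cluster(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
  one <- agglomerative_cluster(matrix(0, 1, 1))
  expect_s3_class(one, "hclust")
  expect_equal(one$order, 1L)
})

test_that("pseudo-F matches hand-computed sums of squares and prefers true labels", {
  x <- matrix(c(0, 0.1, -0.1, 5, 5.1, 4.9), ncol = 1)
  labs <- c(1, 1, 1, 2, 2, 2)
  grand <- mean(x)
  T_ss <- sum((x - grand)^2)
  P_G <- sum((x[1:3] - mean(x[1:3]))^2) + sum((x[4:6] - mean(x[4:6]))^2)
  expect_equal(pseudo_f(x, labs), ((T_ss - P_G) / 1) / (P_G / 4),
               tolerance = 1e-12)
  # random labels on the same data score lower than the true split
  set.seed(43)
  expect_gt(pseudo_f(x, labs), pseudo_f(x, c(1, 2, 1, 2, 1, 2)))
  expect_error(pseudo_f(x, rep(1, 6)), "clusters")
  expect_warning(pf_inf <- pseudo_f(matrix(c(1, 1, 2, 2), ncol = 1),
                                    c(1, 1, 2, 2)), "infinite")
  expect_identical(pf_inf, Inf)
})

test_that("pseudo-F picks the generative number of clusters", {
  set.seed(44)
  mk_cloud <- function(center, n) {
    matrix(rnorm(n * 2, mean = rep(center, each = n), sd = 0.05), ncol = 2)
  }
  for (k in 2:3) {
    centers <- list(c(0, 0), c(4, 0), c(0, 4))[seq_len(k)]
    feat <- do.call(rbind, lapply(centers, mk_cloud, n = 6))
    hc <- agglomerative_cluster(as.matrix(dist(feat)))
    res <- choose_n_clusters(hc, feat, g_max = 6)
    expect_equal(res$g_best, k)
  }
  # with g_max = 2 the answer is 2 by construction
  feat <- do.call(rbind, lapply(list(c(0, 0), c(4, 0)), mk_cloud, n = 5))
  hc <- agglomerative_cluster(as.matrix(dist(feat)))
  expect_equal(choose_n_clusters(hc, feat, g_max = 2)$g_best, 2)
})

test_that("dendrogram purity matches exhaustive pair enumeration", {
  # perfectly separated two-class tree
  d <- matrix(c(0, 1, 9, 9,
                1, 0, 9, 9,
                9, 9, 0, 1,
                9, 9, 1, 0), 4, 4, byrow = TRUE)
  hc <- agglomerative_cluster(d)
  expect_equal(dendrogram_purity(hc, c("a", "a", "b", "b")), 1)
  expect_equal(dendrogram_purity(hc, rep("a", 4)), 1)
  # one misplaced leaf: enumerate the same-class pairs by hand.
  # tree: {1,2} then {{1,2},3} then all; labels a,b,a,b
  d2 <- matrix(c(0, 1, 4, 9,
                 1, 0, 4, 9,
                 4, 4, 0, 9,
                 9, 9, 9, 0), 4, 4, byrow = TRUE)
  hc2 <- agglomerative_cluster(d2)
  labs <- c("a", "b", "a", "b")
  # pair (1,3): LCA = {1,2,3}, purity 2/3; pair (2,4): LCA = all, 2/4
  expect_equal(dendrogram_purity(hc2, labs), (2 / 3 + 1 / 2) / 2,
               tolerance = 1e-12)
})
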