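#' Discretized posterior marginals on a shared binning
#'
#' Histograms the retained samples of each free dynamics parameter on
#' `n_bins` uniform bins spanning the prior support, adds a small floor
#' (1e-12) for divergence safety and normalizes each parameter's vector to
#' sum to one. Because every posterior shares the same prior box, the
#' binning is identical across connections, which makes the vectors
#' directly comparable.
#'
#' @param posterior An `stp_posterior`.
#' @param n_bins Number of bins (>= 2). Default 100.
#' @return Matrix (parameters x bins) of class `stp_marginals`, rows
#'   summing to one; bin edges stored in attribute `"box"`.
#' @export
discretize_marginals <- function(posterior, n_bins = 100) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (nrow(posterior$samples) == 0L) stop("posterior has no samples")
  pars <- setdiff(colnames(posterior$samples), "A")
  out <- matrix(0, nrow = length(pars), ncol = n_bins,
                dimnames = list(pars, NULL))
  for (p in pars) {
    lo <- posterior$prior[p, "lower"]
    hi <- posterior$prior[p, "upper"]
    br <- seq(lo, hi, length.out = n_bins + 1L)
    h <- tabulate(findInterval(posterior$samples[, p], br,
                               rightmost.closed = TRUE, all.inside = TRUE),
                  nbins = n_bins)
    v <- h + 1e-12
    out[p, ] <- v / sum(v)
  }
  structure(out, class = "stp_marginals",
            box = posterior$prior[pars, , drop = FALSE])
}

.check_prob_pair <- function(p, q) {
  if (length(p) != length(q)) stop("P and Q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be nonnegative")
}

#' Symmetrized Kullback-Leibler divergence
#'
#' `sKL(P, Q) = (KL(P, Q) + KL(Q, P)) / 2` in the natural-log convention.
#' Zero bins contribute zero to their own KL terms (0 log 0 = 0);
#' discretized marginals carry an epsilon floor so cross terms stay finite.
#'
#' @param p,q Probability vectors of equal length.
#' @return Nonnegative scalar; 0 iff `p == q`.
#' @export
skl_divergence <- function(p, q) {
  .check_prob_pair(p, q)
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, q) + kl(q, p)) / 2
}

#' Hellinger distance
#'
#' `HL(P, Q) = sqrt(0.5 * sum((sqrt(P) - sqrt(Q))^2))`; lies in \[0, 1\]
#' for normalized vectors, reaching 1 on disjoint supports.
#'
#' @inheritParams skl_divergence
#' @return Scalar in \[0, 1\].
#' @export
hellinger_distance <- function(p, q) {
  .check_prob_pair(p, q)
  sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
}

#' Distance between two connections' posterior marginals
#'
#' Sum of the chosen divergence over the (shared-binning) per-parameter
#' marginal vectors.
#'
#' @param a,b `stp_marginals` objects with identical parameters/binning.
#' @param metric `"hellinger"` (default) or `"skl"`.
#' @return Nonnegative scalar distance.
#' @export
connection_distance <- function(a, b, metric = c("hellinger", "skl")) {
  metric <- match.arg(metric)
  if (!identical(dim(a), dim(b)) || !identical(rownames(a), rownames(b)))
    stop("marginals have mismatched binning or parameters")
  fn <- if (metric == "hellinger") hellinger_distance else skl_divergence
  sum(vapply(rownames(a), function(p) fn(a[p, ], b[p, ]), numeric(1)))
}

#' Pairwise distance matrix over a list of discretized marginals
#'
#' @param marginals List of `stp_marginals` (one per connection).
#' @param metric Passed to [connection_distance()].
#' @return A symmetric zero-diagonal distance matrix.
#' @export
distance_matrix <- function(marginals, metric = c("hellinger", "skl")) {
  metric <- match.arg(metric)
  n <- length(marginals)
  d <- matrix(0, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- connection_distance(marginals[[i]],
                                              marginals[[j]], metric)
  }
  dimnames(d) <- list(names(marginals), names(marginals))
  d
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' @param distances Symmetric zero-diagonal distance matrix or a `dist`.
#' @return An `hclust` merge tree (method `"average"`).
#' @export
agglomerative_cluster <- function(distances) {
  if (!inherits(distances, "dist")) {
    distances <- as.matrix(distances)
    if (nrow(distances) == 1L) {
      # degenerate one-leaf tree
      return(structure(list(merge = matrix(integer(0), 0, 2),
                            height = numeric(0), order = 1L,
                            labels = rownames(distances),
                            method = "average"),
                       class = "hclust"))
    }
    if (nrow(distances) != ncol(distances) ||
        !isTRUE(all.equal(distances, t(distances), tolerance = 1e-10)))
      stop("distance matrix must be symmetric")
    if (any(diag(distances) != 0))
      stop("distance matrix must have a zero diagonal")
    distances <- as.dist(distances)
  }
  hclust(distances, method = "average")
}

#' Pseudo-F (Calinski-Harabasz) statistic of a clustering
#'
#' Ratio of between-cluster to within-cluster mean sums of squares:
#' `((T - P_G) / (G - 1)) / (P_G / (n - G))`, with T the total sum of
#' squares about the grand mean and P_G the pooled within-cluster sum of
#' squares. Larger values indicate tighter, better-separated clusters.
#'
#' @param features Numeric matrix (rows = items).
#' @param labels Cluster assignment, one per row; 2 <= G < n distinct
#'   values required.
#' @return The pseudo-F value; `+Inf` (with a warning) when the
#'   within-cluster sum of squares is zero.
#' @export
pseudo_f <- function(features, labels) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n) stop("one label per row required")
  G <- length(unique(labels))
  if (G < 2L || G >= n) stop("need 2 <= G < n clusters")
  center <- colMeans(features)
  T_ss <- sum(sweep(features, 2L, center)^2)
  P_G <- 0
  for (g in unique(labels)) {
    sub <- features[labels == g, , drop = FALSE]
    P_G <- P_G + sum(sweep(sub, 2L, colMeans(sub))^2)
  }
  if (P_G == 0) {
    warning("zero within-cluster sum of squares; pseudo-F is infinite")
    return(Inf)
  }
  ((T_ss - P_G) / (G - 1)) / (P_G / (n - G))
}

#' Choose the number of clusters by maximal pseudo-F
#'
#' Cuts the dendrogram at G = 2..g_max groups and returns the cut whose
#' pseudo-F on the feature representation is maximal.
#'
#' @param tree An `hclust` tree.
#' @param features Feature matrix used for the pseudo-F (e.g. concatenated
#'   discretized marginals or z-scored point estimates).
#' @param g_max Largest number of clusters to consider (>= 2).
#' @return List with `g_best`, `pseudo_f` (named vector over G) and
#'   `labels` (assignment at the best cut).
#' @export
choose_n_clusters <- function(tree, features, g_max = 10) {
  if (g_max < 2L) stop("g_max must be >= 2")
  n <- nrow(as.matrix(features))
  gs <- seq.int(2L, min(g_max, n - 1L))
  pf <- vapply(gs, function(g) pseudo_f(features, cutree(tree, k = g)),
               numeric(1))
  names(pf) <- gs
  g_best <- gs[which.max(pf)]
  list(g_best = g_best, pseudo_f = pf,
       labels = cutree(tree, k = g_best))
}

#' Dendrogram purity with respect to known classes
#'
#' Expected purity, over all pairs of same-class leaves, of the
#' least-common-ancestor subtree of the pair: the fraction of that
#' subtree's leaves belonging to the class. Equals 1 exactly when the tree
#' separates the classes perfectly.
#'
#' @param tree An `hclust` tree.
#' @param labels Class label per leaf (in leaf order 1..n).
#' @return Purity in \[0, 1\]; defined as 1 when no class has two or more
#'   leaves.
#' @export
dendrogram_purity <- function(tree, labels) {
  n <- length(labels)
  if (length(tree$order) != n) stop("one label per leaf required")
  classes <- unique(labels)
  # leaves under each internal node, built bottom-up from the merge matrix
  members <- vector("list", nrow(tree$merge))
  node_leaves <- function(i) {
    if (i < 0) -i else members[[i]]
  }
  total <- 0
  weighted <- 0
  for (m in seq_len(nrow(tree$merge))) {
    left <- node_leaves(tree$merge[m, 1])
    right <- node_leaves(tree$merge[m, 2])
    members[[m]] <- c(left, right)
    all_lab <- labels[members[[m]]]
    for (cl in classes) {
      n_pairs <- sum(labels[left] == cl) * sum(labels[right] == cl)
      if (n_pairs > 0) {
        total <- total + n_pairs
        weighted <- weighted + n_pairs * mean(all_lab == cl)
      }
    }
  }
  if (total == 0) return(1)
  weighted / total
}
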