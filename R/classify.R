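# truncated-Gaussian-kernel KDE log-density of point `pt` given samples `x`
.kde_logdens <- function(pt, x, lo, hi) {
  bw <- tryCatch(stats::bw.nrd(x), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) bw <- max((hi - lo) * 1e-3, 1e-8)
  mass <- pnorm(hi, mean = x, sd = bw) - pnorm(lo, mean = x, sd = bw)
  dens <- mean(dnorm(pt, mean = x, sd = bw) / pmax(mass, 1e-12))
  log(max(dens, 1e-300))
}

#' Naive Bayes classification of a connection from its MAP parameters
#'
#' The class-conditional likelihood of each synapse class is the product
#' over the free dynamics parameters of per-parameter kernel density
#' estimates built from the pooled posterior samples of that class's
#' training connections, evaluated at the test connection's MAP estimate.
#' Combined with a prior over classes (uniform by default), the class with
#' maximal posterior score is returned.
#'
#' @param class_samples Named list (one entry per class) of pooled
#'   posterior sample matrices with identical column names.
#' @param test_theta Named vector of the test connection's MAP dynamics
#'   parameters.
#' @param prior_over_classes Optional named prior probabilities; uniform
#'   when `NULL`.
#' @param box Prior box (used to truncate the kernel densities); default
#'   the eTM box restricted to the sampled parameters.
#' @return List with `class` (the MAP decision) and `scores` (normalized
#'   posterior class probabilities).
#' @export
naive_bayes_classify <- function(class_samples, test_theta,
                                 prior_over_classes = NULL, box = NULL) {
  if (!length(class_samples) || is.null(names(class_samples)))
    stop("class_samples must be a named list with >= 1 class")
  if (any(vapply(class_samples, nrow, 0L) == 0L))
    stop("every class needs at least one training sample")
  pars <- colnames(class_samples[[1]])
  pars <- intersect(setdiff(pars, "A"), names(test_theta))
  if (!length(pars)) stop("no common parameters to evaluate")
  if (is.null(box)) box <- prior_box("etm")[pars, , drop = FALSE]
  classes <- names(class_samples)
  if (is.null(prior_over_classes))
    prior_over_classes <- stats::setNames(rep(1 / length(classes),
                                              length(classes)), classes)
  logp <- vapply(classes, function(cl) {
    s <- class_samples[[cl]]
    log(prior_over_classes[[cl]]) +
      sum(vapply(pars, function(p) {
        .kde_logdens(test_theta[[p]], s[, p], box[p, "lower"],
                     box[p, "upper"])
      }, numeric(1)))
  }, numeric(1))
  scores <- exp(logp - max(logp))
  scores <- scores / sum(scores)
  list(class = classes[which.max(logp)], scores = scores)
}

#' Fit posteriors for every connection of a cohort
#'
#' Convenience wrapper running [infer_stp()] on each record.
#'
#' @param records List of [connection_record]s.
#' @inheritParams infer_stp
#' @return Object of class `stp_cohort_fit`: list with `posteriors`,
#'   `maps` (matrix of MAP dynamics parameters), `labels`, `ids`.
#' @export
fit_cohort <- function(records, variant = "etm", n_iter = 2000,
                       n_burn = 500, n_chains = 2, seed = NULL) {
  if (!length(records)) stop("empty cohort")
  posteriors <- vector("list", length(records))
  for (i in seq_along(records)) {
    posteriors[[i]] <- infer_stp(records[[i]]$train, variant = variant,
                                 n_iter = n_iter, n_burn = n_burn,
                                 n_chains = n_chains,
                                 seed = if (is.null(seed)) NULL else
                                   seed + i)
  }
  pars <- colnames(posteriors[[1]]$samples)
  maps <- t(vapply(posteriors, function(p) {
    map_estimate(p, as_params = FALSE)$theta
  }, numeric(length(pars))))
  colnames(maps) <- pars
  ids <- vapply(records, function(r) r$id, character(1))
  rownames(maps) <- ids
  structure(list(posteriors = posteriors, maps = maps,
                 labels = vapply(records, function(r) r$label,
                                 character(1)),
                 ids = ids),
            class = "stp_cohort_fit")
}

#' Cross-validated Naive Bayes synapse-type classification
#'
#' For each replicate, `k_train` connections per class are drawn to build
#' the class-conditional likelihoods (pooled posterior samples) and the
#' remaining connections are classified from their MAP estimates.
#' Accuracy is the percentage of correct classifications per connection
#' type. `mode = "kfold"` instead partitions each class into `k_train`
#' folds and tests each fold against the others.
#'
#' @param fit An `stp_cohort_fit` from [fit_cohort()].
#' @param k_train Connections per class used for training (leave-K-out
#'   mode), or the number of folds (k-fold mode).
#' @param mode `"leave_k_out"` (default) or `"kfold"`.
#' @param n_reps Number of random splits in leave-K-out mode.
#' @param seed Optional RNG seed.
#' @return List with `per_class_accuracy` (percent), `overall_accuracy`,
#'   and `confusion` (true x predicted counts).
#' @export
cross_validate <- function(fit, k_train = 7, mode = c("leave_k_out",
                                                      "kfold"),
                           n_reps = 20, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  labels <- fit$labels
  classes <- unique(labels)
  idx_by_class <- split(seq_along(labels), labels)
  splits <- list()
  if (mode == "leave_k_out") {
    sizes <- vapply(idx_by_class, length, 0L)
    if (any(sizes <= k_train) && length(classes) > 1L)
      stop("every class must have more than k_train connections")
    for (r in seq_len(n_reps)) {
      train_idx <- unlist(lapply(idx_by_class, function(ix) {
        if (length(ix) > k_train) sample(ix, k_train) else ix[-1]
      }))
      splits[[r]] <- list(train = train_idx,
                          test = setdiff(seq_along(labels), train_idx))
    }
  } else {
    fold_of <- integer(length(labels))
    for (ix in idx_by_class) {
      fold_of[ix] <- sample(rep_len(seq_len(min(k_train, length(ix))),
                                    length(ix)))
    }
    for (fd in sort(unique(fold_of))) {
      splits[[length(splits) + 1L]] <- list(
        train = which(fold_of != fd), test = which(fold_of == fd))
    }
  }
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (sp in splits) {
    class_samples <- lapply(classes, function(cl) {
      ix <- intersect(sp$train, which(labels == cl))
      if (!length(ix)) stop("empty training set for class ", cl)
      do.call(rbind, lapply(fit$posteriors[ix],
                            function(p) p$samples))
    })
    names(class_samples) <- classes
    for (i in sp$test) {
      pred <- naive_bayes_classify(class_samples, fit$maps[i, ])$class
      confusion[labels[i], pred] <- confusion[labels[i], pred] + 1L
    }
  }
  totals <- rowSums(confusion)
  acc <- 100 * diag(confusion) / pmax(totals, 1L)
  acc[totals == 0] <- NA_real_
  list(per_class_accuracy = acc,
       overall_accuracy = 100 * sum(diag(confusion)) / sum(confusion),
       confusion = confusion)
}
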