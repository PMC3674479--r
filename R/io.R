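#' Write connection records to the PSP CSV schema
#'
#' One row per pulse: `connection_id, label, pulse_index` (1-based),
#' `spike_time_s, mean_amp_mV, sigma_mV`.
#'
#' @param records List of [connection_record]s (or a single record).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psp_csv <- function(records, path) {
  if (inherits(records, "connection_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    tr <- r$train
    data.frame(connection_id = r$id, label = r$label,
               pulse_index = seq_along(tr$times),
               spike_time_s = tr$times, mean_amp_mV = tr$amplitudes,
               sigma_mV = tr$sigmas)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read connection records from a PSP CSV file
#'
#' Expects columns `connection_id, pulse_index, spike_time_s, mean_amp_mV`
#' and either `sigma_mV` or `cv` (from which sigmas are derived as
#' `cv * abs(mean_amp_mV)`); an optional `label` column carries the
#' synapse class. Rows are grouped by connection and sorted by pulse
#' index. Negative mean amplitudes are accepted.
#'
#' @param path CSV path.
#' @return List of [connection_record]s (empty, with a warning, for a file
#'   with no data rows).
#' @export
read_psp_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("connection_id", "pulse_index", "spike_time_s",
                "mean_amp_mV")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (!("sigma_mV" %in% names(df)) && !("cv" %in% names(df)))
    stop("need a 'sigma_mV' or 'cv' column")
  if (nrow(df) == 0L) {
    warning("no data rows in ", path)
    return(list())
  }
  df$.row <- seq_len(nrow(df)) + 1L  # file line numbers (header = line 1)
  records <- lapply(split(df, df$connection_id), function(g) {
    g <- g[order(g$pulse_index), ]
    if (any(diff(g$spike_time_s) <= 0))
      stop("nonmonotone spike times for connection '", g$connection_id[1],
           "' (rows ", paste(g$.row, collapse = ","), ")")
    sig <- if ("sigma_mV" %in% names(g)) g$sigma_mV else
      g$cv * abs(g$mean_amp_mV)
    bad <- which(!is.finite(sig) | sig <= 0)
    if (length(bad))
      stop("nonpositive noise level for connection '", g$connection_id[1],
           "' (rows ", paste(g$.row[bad], collapse = ","), ")")
    lab <- if ("label" %in% names(g)) g$label[1] else "unknown"
    connection_record(g$connection_id[1], lab,
                      psp_train(g$spike_time_s, g$mean_amp_mV,
                                sigmas = sig))
  })
  unname(records[unique(df$connection_id)])
}

#' Quality-control filter on mean amplitude
#'
#' Drops connections whose across-pulse mean amplitude is below the
#' threshold (default 0.015 mV), logging each exclusion.
#'
#' @param records List of [connection_record]s.
#' @param min_mean_amp Threshold (mV), >= 0.
#' @return The filtered list.
#' @export
apply_qc <- function(records, min_mean_amp = 0.015) {
  if (min_mean_amp < 0) stop("min_mean_amp must be >= 0")
  keep <- vapply(records, function(r) {
    ok <- mean(r$train$amplitudes) >= min_mean_amp
    if (!ok)
      message("QC: dropping connection '", r$id, "' (mean amplitude ",
              signif(mean(r$train$amplitudes), 3), " mV < ", min_mean_amp,
              " mV)")
    ok
  }, logical(1))
  records[keep]
}

#' Write posterior samples to CSV
#'
#' Columns: `chain, iteration` (post-burn-in index within chain), the free
#' parameters, and `log_post`.
#'
#' @param posterior An `stp_posterior`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(posterior, path) {
  kept <- posterior$n_iter - posterior$n_burn
  df <- data.frame(chain = posterior$chain,
                   iteration = rep(seq_len(kept), posterior$n_chains))
  df <- cbind(df, as.data.frame(posterior$samples))
  df$log_post <- posterior$log_post
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram to Newick format
#'
#' @param tree An `hclust` tree (e.g. from [agglomerative_cluster()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
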