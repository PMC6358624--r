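#' Bootstrap test for excess cross-cluster coancestry
#'
#' Tests, for every ordered pair of clusters (recipient, source), whether the
#' mean coancestry among individuals within the recipient cluster is smaller
#' than their mean coancestry with the source cluster. Theory predicts this
#' inversion can only arise from admixture into the recipient from a highly
#' drifted source-related population, so flagged pairs are a targeted
#' admixture signal.
#'
#' To remove cluster-size bias, each resample draws an equal-size subsample
#' (without replacement) from every eligible cluster, recomputes the
#' coancestry matrix by repainting the subsampled panel only, and compares
#' the mean within-recipient coancestry (diagonal excluded) with the mean
#' recipient-source coancestry. S counts the null-consistent resamples
#' (within >= cross) and p = (S + 1) / (n_resamples + 1), so a consistent
#' excess of cross-coancestry yields a small p.
#'
#' @param panel A [hap_panel()].
#' @param partition Tibble (`id`, `cluster`) or label vector along samples.
#' @param subsample_size Individuals drawn per cluster (default 13).
#' @param n_resamples Number of bootstrap resamples (default 200).
#' @param params [copying_params()] used for the repainting.
#' @param flag_p Reporting threshold for flagged pairs (default 0.02, not
#'   multiplicity-corrected).
#' @param seed Optional integer seed.
#' @return Object of class `drift_test`: tibble (`recipient`, `source`, `S`,
#'   `p`, `mean_within`, `mean_cross`, `flagged`) over ordered cluster pairs;
#'   clusters smaller than `subsample_size` are excluded with a warning.
#' @export
bootstrap_coancestry_test <- function(panel, partition, subsample_size = 13,
                                      n_resamples = 200,
                                      params = copying_params(),
                                      flag_p = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- panel$samples$id
  z <- if (is.data.frame(partition)) {
    partition$cluster[match(ids, partition$id)]
  } else rep_len(partition, length(ids))
  keep <- !is.na(z)
  members <- split(ids[keep], z[keep])
  sizes <- lengths(members)
  small <- sizes < subsample_size
  if (any(small)) {
    warning("excluding cluster(s) smaller than subsample_size: ",
            paste(names(members)[small], collapse = ", "))
    members <- members[!small]
  }
  if (length(members) < 2)
    stop("need at least 2 clusters of size >= subsample_size", call. = FALSE)
  cl <- names(members)
  nc <- length(cl)

  win <- array(0, dim = c(nc, nc, n_resamples))        # mean within (rows rep.)
  crs <- array(0, dim = c(nc, nc, n_resamples))
  for (r in seq_len(n_resamples)) {
    sub_ids <- unlist(lapply(members, function(m)
      m[sample.int(length(m), subsample_size)]), use.names = FALSE)
    sub <- panel_subset(panel, sub_ids)
    cmx <- coancestry_square(sub, params, chunk_heuristic = FALSE)
    grp <- rep(cl, each = subsample_size)
    for (a in seq_len(nc)) {
      ra <- which(grp == cl[a])
      blk <- cmx[ra, ra]
      mw <- mean(blk[row(blk) != col(blk)])
      for (b in seq_len(nc)) {
        if (a == b) next
        win[a, b, r] <- mw
        crs[a, b, r] <- mean(cmx[ra, which(grp == cl[b])])
      }
    }
  }
  S <- apply(win >= crs, c(1, 2), sum)
  res <- tidyr::expand_grid(recipient = cl, source = cl) |>
    dplyr::filter(.data$recipient != .data$source)
  res$S <- S[cbind(match(res$recipient, cl), match(res$source, cl))]
  res$p <- (res$S + 1) / (n_resamples + 1)
  res$mean_within <- apply(win, c(1, 2), mean)[cbind(match(res$recipient, cl),
                                                     match(res$source, cl))]
  res$mean_cross <- apply(crs, c(1, 2), mean)[cbind(match(res$recipient, cl),
                                                    match(res$source, cl))]
  res$flagged <- res$p < flag_p
  structure(res, class = c("drift_test", class(res)),
            n_resamples = n_resamples, subsample_size = subsample_size,
            flag_p = flag_p)
}
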