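#' Convert a coancestry matrix to effective counts
#'
#' The clustering likelihood treats coancestry as multinomial counts of
#' effectively independent copied segments. Rows are divided by the c-factor
#' (the effective cM per independent segment), rounded half-to-even, and each
#' row's total is then repaired by adjusting its largest entry so that row
#' sums are preserved under rounding.
#'
#' @param x Square (or block) coancestry matrix.
#' @param c_factor Positive scaling constant. `NULL` uses the mean chunk
#'   length recorded by the painting when available (the mean-chunk-size
#'   heuristic), else `mean(off-diagonal positive entries) / 5`.
#' @return Integer matrix of counts, with attribute `c_factor`.
#' @export
coancestry_counts <- function(x, c_factor = NULL) {
  c_heur <- attr(x, "c_heuristic")
  x <- unclass(as.matrix(x))
  if (is.null(c_factor)) {
    if (!is.null(c_heur)) {
      c_factor <- c_heur           # mean chunk length from the painting
    } else {
      off <- x[row(x) != col(x)]
      c_factor <- mean(off[off > 0]) / 5
    }
  }
  if (!is.numeric(c_factor) || c_factor <= 0)
    stop("c_factor must be > 0", call. = FALSE)
  n <- round(x / c_factor)
  target <- round(rowSums(x) / c_factor)
  for (i in seq_len(nrow(n))) {
    d <- target[i] - sum(n[i, ])
    if (d != 0) {
      j <- which.max(n[i, ])
      n[i, j] <- max(0, n[i, j] + d)
    }
  }
  storage.mode(n) <- "integer"
  attr(n, "c_factor") <- c_factor
  n
}

partition_vector <- function(partition, ids) {
  if (is.data.frame(partition)) {
    z <- partition$cluster[match(ids, partition$id)]
  } else if (!is.null(names(partition))) {
    z <- partition[ids]
  } else z <- partition
  if (anyNA(z)) stop("partition does not cover all individuals", call. = FALSE)
  as.integer(factor(z, levels = unique(z)))
}

#' Log marginal likelihood of a partition under the clustering model
#'
#' The Dirichlet-multinomial product-partition likelihood: rows of the
#' 1/c-scaled, rounded coancestry matrix are aggregated over donor clusters
#' (the same partition), and rows within a cluster share an integrated-out
#' Dirichlet copying profile. Invariant to cluster relabelling and to
#' individual reordering. Used by the MCMC (with a CRP prior added) and by
#' greedy tree building.
#'
#' @param coancestry Square `coancestry_matrix` (or plain matrix), or a
#'   [build_external_sharing_matrix()] block object.
#' @param partition Cluster labels: a vector along individuals, a named
#'   vector, or a tibble (`id`, `cluster`).
#' @param c_factor See [coancestry_counts()].
#' @param beta Dirichlet concentration per donor cluster (default 1).
#' @return Log marginal likelihood (finite scalar).
#' @export
fs_log_marginal <- function(coancestry, partition, c_factor = NULL, beta = 1) {
  prep <- fs_prepare(coancestry, c_factor)
  z <- partition_vector(partition, prep$ids)
  if (!is.null(prep$fixed_z)) {
    # block mode: partition covers recipients; donors keep their groups
    z_rec <- partition_vector(partition, prep$rec_ids)
    z <- c(z_rec, max(z_rec) + prep$fixed_z)
  }
  fs_dm_loglik(prep$counts, z, beta)
}

# plain-R reference implementation of the likelihood (cross-checked against
# the C++ evaluator in the tests). Each row i in cluster a is multinomial
# over the N donor columns with probabilities q_{a,b(j)} / n_b (equal within
# a donor cluster); the cluster-level q are integrated out under a symmetric
# Dirichlet(beta). Data-dependent multinomial coefficients are constant in
# the partition and dropped.
fs_dm_loglik <- function(counts, z, beta = 1) {
  K <- max(z)
  Zm <- outer(z, seq_len(K), "==") + 0
  n_b <- colSums(Zm)
  M <- counts %*% Zm                     # N x K column aggregation
  S <- t(Zm) %*% M                       # K x K pooled per row-cluster
  # within-cluster uniform spread, excluding each row's own (zero) column:
  # a row in cluster b sees n_b - 1 available columns of its own cluster
  colS <- colSums(S); dS <- diag(S)
  lp <- -sum((colS - dS) * log(n_b)) -
    sum(dS[n_b > 1] * log(n_b[n_b > 1] - 1))
  lp <- lp + K * lgamma(K * beta) - sum(lgamma(K * beta + rowSums(S)))
  lp + sum(lgamma(beta + S)) - K * K * lgamma(beta)
}

fs_crp_logprior <- function(z, crp_alpha = 1) {
  sizes <- tabulate(z)
  sizes <- sizes[sizes > 0]
  length(sizes) * log(crp_alpha) + sum(lgamma(sizes)) +
    lgamma(crp_alpha) - lgamma(crp_alpha + length(z))
}

# normalize square/block inputs into counts + id bookkeeping
fs_prepare <- function(coancestry, c_factor) {
  if (inherits(coancestry, "block_matrix")) {
    Cm <- coancestry$C
    attr(Cm, "c_heuristic") <- coancestry$c_heuristic
    counts <- coancestry_counts(Cm, c_factor)
    list(counts = counts, ids = c(coancestry$recipients, coancestry$donors),
         rec_ids = coancestry$recipients,
         fixed_z = as.integer(factor(coancestry$groups,
                                     levels = unique(coancestry$groups))),
         fixed = c(rep(FALSE, length(coancestry$recipients)),
                   rep(TRUE, length(coancestry$donors))))
  } else {
    x <- as.matrix(coancestry)
    if (nrow(x) != ncol(x)) stop("coancestry matrix must be square (or a block_matrix)",
                                 call. = FALSE)
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
    list(counts = coancestry_counts(x, c_factor), ids = ids,
         rec_ids = ids, fixed_z = NULL, fixed = rep(FALSE, nrow(x)))
  }
}

#' MCMC partition inference on a coancestry matrix
#'
#' Samples partitions of individuals from the Dirichlet-multinomial posterior
#' with a CRP prior, using Gibbs single-individual reassignment plus
#' split/merge proposals. The number of clusters is inferred, not fixed. For
#' block matrices from [build_external_sharing_matrix()], donor groups are
#' held fixed and only recipients are (re)clustered.
#'
#' @param coancestry Square matrix or `block_matrix`.
#' @param c_factor See [coancestry_counts()].
#' @param n_burn,n_sample,thin MCMC schedule in sweeps: `n_burn` discarded
#'   sweeps, then `n_sample` retained samples taken every `thin` sweeps.
#' @param seed Optional integer seed.
#' @param beta,crp_alpha Model hyperparameters.
#' @param init `"singleton"` starts every free individual in its own
#'   cluster; `"single"` starts them in one cluster.
#' @return An object of class `fs_fit`: `partition` (tibble `id`, `cluster`
#'   of the highest-posterior sample), `trace` (samples matrix, log-posterior
#'   vector), `K`, `counts`, plus bookkeeping for certainty and trees.
#' @export
fs_mcmc <- function(coancestry, c_factor = NULL, n_burn = 200, n_sample = 150,
                    thin = 2, seed = NULL, beta = 1, crp_alpha = 1,
                    init = c("singleton", "single")) {
  init <- match.arg(init)
  if (n_burn < 1 || n_sample < 2 || thin < 1)
    stop("need n_burn >= 1, n_sample >= 2, thin >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  prep <- fs_prepare(coancestry, c_factor)
  n_free <- sum(!prep$fixed)
  if (is.null(prep$fixed_z)) {
    z0 <- if (init == "singleton") seq_len(n_free) else rep(1L, n_free)
  } else {
    zf <- if (init == "singleton") seq_len(n_free) else rep(1L, n_free)
    z0 <- c(zf, max(zf) + prep$fixed_z)
  }
  res <- fs_mcmc_cpp(prep$counts, as.integer(z0), prep$fixed,
                     as.integer(n_burn), as.integer(n_sample),
                     as.integer(thin), beta, crp_alpha, TRUE)
  free_ids <- prep$ids[!prep$fixed]
  map_free <- res$map_z[!prep$fixed]
  partition <- tibble::tibble(
    id = free_ids,
    cluster = as.integer(factor(map_free, levels = unique(map_free))))
  structure(list(partition = partition,
                 trace = list(samples = res$samples[, !prep$fixed, drop = FALSE],
                              logpost = as.numeric(res$logpost),
                              sm_tried = res$sm_tried,
                              sm_accepted = res$sm_accepted, seed = seed,
                              n_burn = n_burn, n_sample = n_sample, thin = thin),
                 K = max(partition$cluster),
                 ids = free_ids,
                 counts = prep$counts,
                 fixed = prep$fixed, fixed_z = prep$fixed_z,
                 beta = beta, crp_alpha = crp_alpha,
                 c_factor = attr(prep$counts, "c_factor"),
                 map_logpost = res$map_logpost),
            class = "fs_fit")
}

#' @export
print.fs_fit <- function(x, ...) {
  cat("<fs_fit> ", length(x$ids), " individuals in ", x$K,
      " clusters (MAP log-posterior ", format(x$map_logpost, digits = 8),
      ", ", nrow(x$trace$samples), " retained samples)\n", sep = "")
  invisible(x)
}

#' Pairwise coincidence matrix of an MCMC trace
#'
#' Fraction of retained samples in which each pair of individuals is
#' co-clustered; the standard convergence diagnostic (two independent runs
#' should give strongly correlated coincidence matrices).
#'
#' @param fit An `fs_fit`.
#' @return Symmetric matrix in `[0, 1]`.
#' @export
pairwise_coincidence <- function(fit) {
  s <- fit$trace$samples
  n <- ncol(s)
  out <- matrix(0, n, n, dimnames = list(fit$ids, fit$ids))
  for (r in seq_len(nrow(s)))
    out <- out + outer(s[r, ], s[r, ], "==")
  out / nrow(s)
}

#' Greedy cluster tree by smallest posterior decrease
#'
#' Starting from a partition, successively merges the pair of clusters whose
#' merge decreases the log posterior least, until one cluster remains. Ties
#' break on the lexicographically smallest cluster-id pair.
#'
#' @param fit An `fs_fit`, or a list with `counts`, `partition` as built by
#'   [fs_mcmc()].
#' @param partition Optional partition tibble overriding the fit's MAP.
#' @return An object of class `cluster_tree`: tibble of merges (`step`,
#'   `c1`, `c2`, `into`, `score` = posterior decrease, clamped at 0),
#'   plus the leaf partition.
#' @export
build_tree <- function(fit, partition = NULL) {
  if (is.null(partition)) partition <- fit$partition
  z_leaf <- partition_vector(partition, fit$ids)
  K <- max(z_leaf)
  lp <- function(lab) {
    zfree <- as.integer(factor(lab[z_leaf], levels = unique(lab[z_leaf])))
    zz <- if (is.null(fit$fixed_z)) zfree else c(zfree, max(zfree) + fit$fixed_z)
    fs_dm_loglik(fit$counts, zz, fit$beta) + fs_crp_logprior(zz, fit$crp_alpha)
  }
  lab <- seq_len(K)              # current label of each leaf cluster
  active <- seq_len(K)
  cur <- lp(lab)
  merges <- vector("list", max(0, K - 1))
  for (step in seq_len(max(0, K - 1))) {
    best <- NULL
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (ai >= bi) next
      a <- active[ai]; b <- active[bi]
      lab2 <- lab
      lab2[lab2 == b] <- a
      val <- lp(lab2)
      if (is.null(best) || val > best$val + 1e-12) best <- list(a = a, b = b, val = val)
    }
    merges[[step]] <- tibble::tibble(step = step, c1 = best$a, c2 = best$b,
                                     into = best$a,
                                     score = max(0, cur - best$val),
                                     decrease = cur - best$val)
    lab[lab == best$b] <- best$a
    active <- setdiff(active, best$b)
    cur <- best$val
  }
  structure(list(merges = dplyr::bind_rows(merges), partition = partition,
                 K = K),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree> ", x$K, " leaf clusters, ", nrow(x$merges), " merges\n",
      sep = "")
  invisible(x)
}

#' Cluster membership at a given tree level
#'
#' @param tree A `cluster_tree`.
#' @param level Number of clusters wanted (between 1 and K).
#' @return Tibble (`id`, `cluster`) with `level` distinct clusters.
#' @export
cut_tree <- function(tree, level) {
  K <- tree$K
  if (level < 1 || level > K) stop("level must be in 1..K", call. = FALSE)
  z <- partition_vector(tree$partition, tree$partition$id)
  lab <- seq_len(K)
  n_merge <- K - level
  for (s in seq_len(n_merge)) {
    m <- tree$merges[s, ]
    lab[lab == m$c2] <- m$c1
  }
  tibble::tibble(id = tree$partition$id,
                 cluster = as.integer(factor(lab[z], levels = unique(lab[z]))))
}

#' Select a tree level by cluster-size rule
#'
#' Two published rules: `"all-greater-than"` returns the finest level at
#' which every cluster exceeds `size`; `"first-large-merge"` walks up from
#' the leaves and returns the level just before the first merge of two
#' clusters that each exceed `size`.
#'
#' @param tree A `cluster_tree`.
#' @param rule `"all-greater-than"` or `"first-large-merge"`.
#' @param size Size threshold (default 20 for the coarse rule, 15 for the
#'   fine rule in the published analyses).
#' @return The selected level (number of clusters), with the membership
#'   tibble as attribute `membership`. Falls back to the root with a warning
#'   if the rule is unsatisfiable.
#' @export
select_tree_level <- function(tree, rule = c("all-greater-than",
                                             "first-large-merge"),
                              size = if (match.arg(rule) == "all-greater-than") 20 else 15) {
  rule <- match.arg(rule)
  K <- tree$K
  sizes_at <- function(level) table(cut_tree(tree, level)$cluster)
  if (rule == "all-greater-than") {
    for (level in K:1) {
      if (all(sizes_at(level) > size)) {
        out <- level
        attr(out, "membership") <- cut_tree(tree, level)
        return(out)
      }
    }
    warning("all-greater-than rule unsatisfiable; returning root")
    out <- 1L
  } else {
    out <- 1L
    found <- FALSE
    if (K > 1) for (s in seq_len(nrow(tree$merges))) {
      level_before <- K - s + 1L
      memb <- cut_tree(tree, level_before)
      m <- tree$merges[s, ]
      # sizes of the two clusters about to merge, in leaf-label terms
      z <- partition_vector(tree$partition, tree$partition$id)
      lab <- seq_len(K)
      if (s > 1) for (q in seq_len(s - 1L)) {
        lab[lab == tree$merges$c2[q]] <- tree$merges$c1[q]
      }
      sz1 <- sum(lab[z] == m$c1); sz2 <- sum(lab[z] == m$c2)
      if (sz1 > size && sz2 > size) { out <- level_before; found <- TRUE; break }
    }
    if (!found && K > 1) {
      warning("first-large-merge rule unsatisfiable; returning root")
      out <- 1L
    }
    attr(out, "membership") <- cut_tree(tree, as.integer(out))
  }
  if (is.null(attr(out, "membership")))
    attr(out, "membership") <- cut_tree(tree, as.integer(out))
  out
}

#' Per-individual cluster assignment certainty
#'
#' For each individual i and final cluster k, the average over MCMC samples
#' of the overlap between i's sampled cluster and k (|sampled cluster of i
#' intersected with k| / |sampled cluster of i|). Rows sum to 1; the value at
#' i's own final cluster is the assignment certainty. With a tree and a
#' level, certainties are aggregated by summing over the clusters merged at
#' that level.
#'
#' @param fit An `fs_fit` with at least 2 retained samples.
#' @param partition Final partition (default the fit's MAP).
#' @param tree,level Optional `cluster_tree` and level for aggregation.
#' @return Matrix individuals x clusters of certainties, with tidy form in
#'   attribute `tbl`.
#' @export
assignment_certainty <- function(fit, partition = NULL, tree = NULL,
                                 level = NULL) {
  if (nrow(fit$trace$samples) < 2) stop("need >= 2 trace samples", call. = FALSE)
  if (is.null(partition)) partition <- fit$partition
  z_fin <- partition_vector(partition, fit$ids)
  K <- max(z_fin)
  S <- fit$trace$samples
  n <- length(fit$ids)
  cert <- matrix(0, n, K)
  for (r in seq_len(nrow(S))) {
    zs <- S[r, ]
    # overlap(i, k) = |(c_s(i) \ {i}) n final_k| / |c_s(i) \ {i}|; the
    # individual itself is left out so that an individual co-clustered with
    # exactly final cluster B in a sample scores a full overlap with B
    tab <- table(factor(zs), factor(z_fin, levels = seq_len(K)))
    rows <- match(zs, as.integer(rownames(tab)))
    num <- unclass(tab)[rows, , drop = FALSE]
    num[cbind(seq_len(n), z_fin)] <- num[cbind(seq_len(n), z_fin)] - 1
    den <- rowSums(num)
    ov <- num / pmax(den, 1)
    singleton <- den == 0
    if (any(singleton))                # no co-members: credit the own cluster
      ov[cbind(which(singleton), z_fin[singleton])] <- 1
    cert <- cert + ov
  }
  cert <- cert / nrow(S)
  dimnames(cert) <- list(fit$ids, paste0("cluster", seq_len(K)))
  if (!is.null(tree) && !is.null(level)) {
    lab <- seq_len(tree$K)
    for (s in seq_len(tree$K - level)) {
      m <- tree$merges[s, ]
      lab[lab == m$c2] <- m$c1
    }
    groups <- factor(lab, levels = unique(lab))
    cert <- t(rowsum(t(cert), groups))
    colnames(cert) <- paste0("cluster", seq_len(ncol(cert)))
  }
  attr(cert, "tbl") <- tibble::as_tibble(as.data.frame.table(cert,
                                                             responseName = "certainty")) |>
    dplyr::rename(id = "Var1", cluster = "Var2")
  cert
}

#' Block matrix for clustering on external haplotype sharing
#'
#' Embeds the rectangular recipients-by-donors matrix X in a square
#' (N+M) x (N+M) matrix C = \[0 X; 0 Y\] in which Y is zero except for
#' within-donor-group diagonal blocks whose entries all equal the calibration
#' constant g_k, chosen so that the group-k mean of Y equals the group-k mean
#' of X. The zero blocks stop recipient-recipient sharing from contributing
#' to the clustering likelihood, so recipients cluster purely on their
#' sharing with external groups.
#'
#' @param X Rectangular coancestry matrix (recipients x donor individuals),
#'   or a [coancestry_restricted()] object.
#' @param donor_groups Character vector of group labels per donor column
#'   (ignored when `X` is a `coancestry_restricted`).
#' @return An object of class `block_matrix`: `C`, `g_k` (named vector),
#'   `recipients`, `donors`, `groups`.
#' @export
build_external_sharing_matrix <- function(X, donor_groups = NULL) {
  c_heur <- NULL
  if (inherits(X, "coancestry_restricted")) {
    donor_groups <- X$donor_groups$group
    c_heur <- X$c_heuristic
    X <- X$X
  }
  X <- as.matrix(X)
  N <- nrow(X); M <- ncol(X)
  if (is.null(donor_groups) || length(donor_groups) != M)
    stop("need one donor group label per donor column", call. = FALSE)
  if (anyNA(donor_groups)) stop("unlabeled donor column", call. = FALSE)
  rec_ids <- rownames(X); if (is.null(rec_ids)) rec_ids <- paste0("R", seq_len(N))
  don_ids <- colnames(X); if (is.null(don_ids)) don_ids <- paste0("D", seq_len(M))
  groups <- as.character(donor_groups)
  g_k <- vapply(split(seq_len(M), groups), function(cols) mean(X[, cols]),
                numeric(1))
  Y <- matrix(0, M, M, dimnames = list(don_ids, don_ids))
  for (k in names(g_k)) {
    cols <- which(groups == k)
    Y[cols, cols] <- g_k[[k]]
  }
  C <- rbind(cbind(matrix(0, N, N), X),
             cbind(matrix(0, M, N), Y))
  dimnames(C) <- list(c(rec_ids, don_ids), c(rec_ids, don_ids))
  structure(list(C = C, g_k = g_k, recipients = rec_ids, donors = don_ids,
                 groups = groups, c_heuristic = c_heur),
            class = "block_matrix")
}

#' Cluster recipients on their sharing with external donor groups
#'
#' Runs [fs_mcmc()] on a [build_external_sharing_matrix()] block matrix with
#' the donor groups forced (never split or merged), so the inferred clusters
#' of recipients reflect only differences in copying from external groups;
#' private drift within recipients cannot contribute.
#'
#' @inheritParams fs_mcmc
#' @param block A `block_matrix`.
#' @return An `fs_fit` whose partition covers recipients only.
#' @export
cluster_on_external_sharing <- function(block, c_factor = NULL, n_burn = 200,
                                        n_sample = 150, thin = 2, seed = NULL,
                                        beta = 1, crp_alpha = 1,
                                        init = c("singleton", "single")) {
  stopifnot(inherits(block, "block_matrix"))
  fs_mcmc(block, c_factor = c_factor, n_burn = n_burn, n_sample = n_sample,
          thin = thin, seed = seed, beta = beta, crp_alpha = crp_alpha,
          init = match.arg(init))
}

#' Adjusted Rand index between two partitions
#' @param a,b Cluster label vectors over the same individuals (or tibbles
#'   with `id`, `cluster`; matched on id).
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b)) {
    b <- b$cluster[match(a$id, b$id)]
    a <- a$cluster
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
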