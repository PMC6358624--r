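#' Non-negative least squares on the simplex
#'
#' Lawson-Hanson active-set NNLS with the sum-to-one constraint imposed by a
#' heavily weighted augmentation row. Deterministic. (No constrained
#' least-squares solver ships with the supported R stack, so the primitive is
#' implemented here.)
#'
#' @param A Design matrix (rows = observations, columns = coefficients).
#' @param b Response vector.
#' @param sum_to_one Append the constraint row (default TRUE).
#' @param weight Weight of the constraint row.
#' @return List `coef` (non-negative; sums to ~1 when constrained),
#'   `residual` (RSS on the unaugmented system).
#' @keywords internal
nnls_simplex <- function(A, b, sum_to_one = TRUE, weight = 1e4) {
  A <- as.matrix(A)
  if (sum_to_one) {
    scale <- weight * max(abs(A), 1)
    A2 <- rbind(A, rep(scale, ncol(A)))
    b2 <- c(b, scale)
  } else { A2 <- A; b2 <- b }
  m <- ncol(A2)
  passive <- rep(FALSE, m)
  x <- numeric(m)
  w <- crossprod(A2, b2 - A2 %*% x)
  iter <- 0L
  while (any(!passive & w > 1e-10 * max(abs(w), 1)) && iter < 30 * m) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      sP <- numeric(m)
      Ap <- A2[, passive, drop = FALSE]
      sP[passive] <- qr.coef(qr(Ap), b2)
      sP[is.na(sP)] <- 0
      if (all(sP[passive] > 1e-12)) { x <- sP; break }
      neg <- passive & sP <= 1e-12
      alpha <- min(x[neg] / (x[neg] - sP[neg]))
      x <- x + alpha * (sP - x)
      passive[passive & x <= 1e-10] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A2, b2 - A2 %*% x)
  }
  list(coef = x, residual = sum((b - A %*% x)^2))
}

#' Donor-group self-copying basis
#'
#' Paints every donor individual against all donor haplotypes except its own
#' two (optionally excluding its whole group), aggregates expected lengths by
#' donor group, averages within group, and normalizes rows to proportions.
#' Row k is the copying profile of group k - the basis vector that ancestry
#' profiles mix.
#'
#' @param donors A [hap_panel()] with `samples$group`; every group needs at
#'   least 2 members.
#' @param params A [copying_params()].
#' @param include_own_group Allow copying from other members of the
#'   individual's own group (default TRUE, keeping the basis square).
#' @return A G x G matrix `B` with rows summing to 1.
#' @export
donor_basis_vectors <- function(donors, params = copying_params(),
                                include_own_group = TRUE) {
  grp <- donors$samples$group
  if (is.null(grp)) stop("donor panel needs samples$group", call. = FALSE)
  glev <- unique(grp)
  if (length(glev) < 2) stop("need >= 2 donor groups", call. = FALSE)
  if (include_own_group && any(table(grp) < 2))
    stop("every donor group needs >= 2 members to leave self out", call. = FALSE)
  M <- nrow(donors$samples)
  chrom_idx <- map_chrom_index(donors$map)
  donor_group_by_hap <- rep(match(grp, glev), each = 2L)
  B <- matrix(0, length(glev), length(glev), dimnames = list(glev, glev))
  for (i in seq_len(M)) {
    own <- c(2L * i - 1L, 2L * i)
    excl <- if (include_own_group) own else which(donor_group_by_hap == match(grp[i], glev))
    donor_cols <- setdiff(seq_len(2L * M), excl)
    acc <- numeric(length(glev))
    for (h in own) {
      res <- paint_col(donors$geno, chrom_idx, donors$map$cm, h, donor_cols,
                       params, "length")
      agg <- rowsum(rowSums(res$lengths), donor_group_by_hap[donor_cols])
      acc[as.integer(rownames(agg))] <- acc[as.integer(rownames(agg))] + agg[, 1]
    }
    B[match(grp[i], glev), ] <- B[match(grp[i], glev), ] + acc
  }
  B <- B / as.numeric(table(factor(grp, levels = glev)))  # group means
  B / rowSums(B)
}

#' Cluster-averaged copying vector
#'
#' @param X_group Recipients x donor-groups coancestry matrix (e.g.
#'   `$X_group` of [coancestry_restricted()]).
#' @param members Character ids of the cluster members (rows of `X_group`).
#' @return Named proportion vector (mean of member rows, normalized).
#' @export
cluster_mean_vector <- function(X_group, members) {
  rows <- X_group[members, , drop = FALSE]
  if (!nrow(rows)) stop("empty cluster", call. = FALSE)
  v <- colMeans(rows)
  v / sum(v)
}

#' Fit a sum-to-one non-negative ancestry profile
#'
#' Expresses a target copying proportion vector as the best non-negative,
#' sum-to-one mixture of the donor-group basis rows. Coefficients below 1e-4
#' are zeroed and the profile renormalized (display convention for trace
#' components).
#'
#' @param y Target proportion vector over donor groups.
#' @param B Basis matrix from [donor_basis_vectors()] (rows = donor groups).
#' @return Object of class `ancestry_profile`: tibble (`group`,
#'   `coefficient`) with attributes `residual` and `nonunique` (TRUE when B
#'   is rank-deficient).
#' @export
fit_ancestry_profile <- function(y, B) {
  B <- as.matrix(B)
  if (length(y) != ncol(B)) stop("dimension mismatch between y and B", call. = FALSE)
  fit <- nnls_simplex(t(B), as.numeric(y))
  beta <- fit$coef
  beta[beta < 1e-4] <- 0
  if (sum(beta) > 0) beta <- beta / sum(beta)
  nonunique <- qr(B)$rank < nrow(B)
  if (nonunique) warning("basis is rank-deficient; profile may be non-unique")
  out <- tibble::tibble(group = rownames(B), coefficient = as.numeric(beta))
  structure(out, class = c("ancestry_profile", class(out)),
            residual = fit$residual, nonunique = nonunique)
}

#' Pseudo-individual bootstrap intervals for an ancestry profile
#'
#' Re-estimates the cluster-averaged copying vector from sets of
#' pseudo-individuals (each assembled by drawing a random member per
#' chromosome and summing chromosome-level vectors), refits the profile, and
#' reports the inner 95% range per coefficient. A donor group is `reported`
#' when its interval excludes zero and the point estimate exceeds 0.001.
#'
#' @param chrom_vectors Members x donor-groups x chromosomes array for the
#'   cluster (subset of [chromosome_level_vectors()], `by = "group"`).
#' @param B Donor basis.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return Tibble (`group`, `coefficient`, `lo95`, `hi95`, `reported`) with
#'   the point profile from the full mean.
#' @export
bootstrap_profile_intervals <- function(chrom_vectors, B, n_boot = 1000,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dm <- dim(chrom_vectors)
  n <- dm[1]; G <- dm[2]; C <- dm[3]
  if (C < 2) stop("need >= 2 chromosomes for the pseudo-individual bootstrap",
                  call. = FALSE)
  if (n < 2) stop("need >= 2 cluster members", call. = FALSE)
  totals <- apply(chrom_vectors, c(1, 2), sum)
  y0 <- colSums(totals) / sum(totals)
  point <- fit_ancestry_profile(y0, B)
  boot <- matrix(0, n_boot, G)
  for (r in seq_len(n_boot)) {
    pick <- matrix(sample.int(n, n * C, replace = TRUE), n, C)
    acc <- numeric(G)
    for (cc in seq_len(C))
      acc <- acc + colSums(matrix(chrom_vectors[pick[, cc], , cc], n, G))
    y <- acc / sum(acc)
    boot[r, ] <- fit_ancestry_profile(y, B)$coefficient
  }
  lo <- apply(boot, 2, stats::quantile, 0.025)
  hi <- apply(boot, 2, stats::quantile, 0.975)
  tibble::tibble(group = point$group, coefficient = point$coefficient,
                 lo95 = lo, hi95 = hi,
                 reported = (lo > 0 | hi < 0) & point$coefficient > 0.001)
}

#' Self-profile of a donor group
#'
#' Treats donor group k itself as the target: removes its own entry from its
#' copying vector and from the basis, renormalizes, and fits the mixture of
#' the remaining groups (used to quantify, e.g., European-like ancestry
#' within a north-African donor group).
#'
#' @param group Name of the donor group to profile.
#' @param B Donor basis from [donor_basis_vectors()].
#' @return An `ancestry_profile` over the remaining groups.
#' @export
donor_self_profile <- function(group, B) {
  B <- as.matrix(B)
  if (nrow(B) < 3) stop("need >= 3 donor groups", call. = FALSE)
  k <- match(group, rownames(B))
  if (is.na(k)) stop("unknown donor group: ", group, call. = FALSE)
  y <- B[k, -k]
  y <- y / sum(y)
  Bk <- B[-k, -k, drop = FALSE]
  Bk <- Bk / rowSums(Bk)
  fit_ancestry_profile(y, Bk)
}
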