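#' Parameters of the haplotype-copying model
#'
#' The painting stage models each recipient haplotype as an imperfect mosaic
#' of the donor haplotypes: a hidden copying state switches between donors as
#' a Poisson process along the genetic map and emits the observed allele with
#' a small miscopy probability. These two knobs are deliberately plain
#' configuration (not EM-estimated): they control the expected chunk scale
#' (`1 / switch_rate` cM) and the tolerance to mutation/genotyping error.
#'
#' @param switch_rate Expected copying switches per cM (> 0). Default 0.1,
#'   i.e. a 10-cM expected chunk length.
#' @param miscopy Per-site miscopy probability, in `[0, 0.5)`. Default 0.01.
#' @return An object of class `copying_params`.
#' @export
copying_params <- function(switch_rate = 0.1, miscopy = 0.01) {
  if (switch_rate <= 0) stop("switch_rate must be > 0", call. = FALSE)
  if (miscopy < 0 || miscopy >= 0.5) stop("miscopy must lie in [0, 0.5)", call. = FALSE)
  structure(list(switch_rate = switch_rate, miscopy = miscopy),
            class = "copying_params")
}

map_chrom_index <- function(map) {
  as.integer(factor(map$chrom, levels = unique(map$chrom)))
}

#' Expected copied length per donor haplotype
#'
#' Runs the forward-backward algorithm of the copying model for a single
#' recipient haplotype and returns, for each donor haplotype, the expected
#' total genome length (cM) copied from it. Each inter-SNP interval is
#' attributed according to the posterior copying state at its left SNP, so
#' the vector sums exactly to the total map length.
#'
#' @param recipient Integer vector of 0/1 alleles (length = SNPs).
#' @param donors Integer matrix of donor haplotypes (SNPs x donors).
#' @param map Map tibble (`chrom`, `bp`, `cm`) on the same SNP grid.
#' @param params A [copying_params()].
#' @param measure `"length"` (default, total cM) or `"count"` (expected
#'   number of contiguous copied chunks).
#' @param by_chrom If `TRUE` return a donors x chromosomes matrix instead of
#'   the total vector.
#' @return Numeric vector (or matrix) of expected lengths/counts per donor.
#' @export
paint_expected_lengths <- function(recipient, donors, map,
                                   params = copying_params(),
                                   measure = c("length", "count"),
                                   by_chrom = FALSE) {
  measure <- match.arg(measure)
  donors <- as.matrix(donors)
  if (length(recipient) != nrow(map) || nrow(donors) != nrow(map))
    stop("SNP grid mismatch between recipient, donors and map", call. = FALSE)
  if (ncol(donors) < 1) stop("empty donor set", call. = FALSE)
  geno <- cbind(as.integer(recipient), donors)
  storage.mode(geno) <- "integer"
  res <- paint_col(geno, map_chrom_index(map), map$cm, 1L,
                   1L + seq_len(ncol(donors)), params, measure)
  out <- if (measure == "count") res$counts else res$lengths
  rownames(out) <- colnames(donors)
  colnames(out) <- unique(map$chrom)
  if (by_chrom) out else rowSums(out)
}

# paint one haplotype column of a panel against donor columns (both 1-based;
# converted to 0-based for the kernel); returns donors x chromosomes matrix
# of expected lengths (and optionally per-SNP group posteriors)
paint_col <- function(geno, chrom_idx, cm, hap_col, donor_cols, params,
                      measure = "length", donor_group = NULL) {
  res <- cp_paint_hap_cpp(geno, chrom_idx, cm, hap_col - 1L, donor_cols - 1L,
                          params$switch_rate, params$miscopy,
                          measure == "count",
                          if (is.null(donor_group)) integer(0) else as.integer(donor_group),
                          if (is.null(donor_group)) 0L else max(donor_group),
                          !is.null(donor_group))
  res
}

new_coancestry <- function(values, map_length, measure, kind,
                           c_heuristic = NULL) {
  structure(values, map_length = map_length, measure = measure, kind = kind,
            c_heuristic = c_heuristic,
            class = c("coancestry_matrix", "matrix"))
}

#' All-versus-all coancestry matrix
#'
#' Paints every individual's two haplotypes using all other individuals'
#' haplotypes as donors (leave-own-haplotypes-out) and sums the expected
#' copied lengths per donor individual. The result is the square coancestry
#' matrix used for cluster inference: entry (i, j) is the total cM over which
#' individual i's genome is most closely matched by individual j among the
#' sample. Rows sum to 2 x the total map length; the diagonal is zero.
#'
#' @param panel A [hap_panel()] with at least 3 individuals.
#' @param params A [copying_params()].
#' @param measure `"length"` or `"count"`.
#' @return An N x N `coancestry_matrix` with sample ids as dimnames.
#' @export
coancestry_square <- function(panel, params = copying_params(),
                              measure = c("length", "count"),
                              chunk_heuristic = TRUE) {
  measure <- match.arg(measure)
  N <- nrow(panel$samples)
  if (N < 3) stop("need at least 3 individuals for all-vs-all painting",
                  call. = FALSE)
  chrom_idx <- map_chrom_index(panel$map)
  out <- matrix(0, N, N, dimnames = list(panel$samples$id, panel$samples$id))
  tot_len <- 0; tot_chunks <- 0
  for (i in seq_len(N)) {
    own <- c(2L * i - 1L, 2L * i)
    donor_cols <- setdiff(seq_len(2L * N), own)
    donor_of <- ceiling(donor_cols / 2)                 # individual per donor hap
    for (h in own) {
      res <- paint_col(panel$geno, chrom_idx, panel$map$cm, h, donor_cols,
                       params,
                       if (chunk_heuristic || measure == "count") "count" else "length")
      v <- rowSums(if (measure == "count") res$counts else res$lengths)
      if (chunk_heuristic) {
        tot_len <- tot_len + sum(res$lengths)
        tot_chunks <- tot_chunks + sum(res$counts)
      }
      agg <- rowsum(v, donor_of)
      out[i, as.integer(rownames(agg))] <- out[i, as.integer(rownames(agg))] + agg[, 1]
    }
  }
  # data-driven clustering scale: mean chunk length (cM per effectively
  # independent copied segment); for the count measure a count already is one
  # effective observation
  c_heur <- if (!chunk_heuristic) NULL else if (measure == "length") tot_len / tot_chunks else 1
  new_coancestry(out, map_length(panel$map), measure, "square",
                 c_heuristic = c_heur)
}

#' Restricted coancestry: recipients copy only from an external donor panel
#'
#' Paints each recipient individual allowing copying only from the donor
#' panel's haplotypes, giving the rectangular matrix X (recipients x donor
#' individuals) together with its donor-group-aggregated form (recipients x
#' groups). Row sums equal 2 x total map length in both.
#'
#' @param recipients,donors [hap_panel()] objects on the same SNP grid with
#'   disjoint sample ids; `donors$samples` must carry a `group` column.
#' @param params A [copying_params()].
#' @param measure `"length"` or `"count"`.
#' @return A list of class `coancestry_restricted`: `X` (N x M matrix),
#'   `X_group` (N x n_groups), `donor_groups` (tibble id, group),
#'   `map_length`.
#' @export
coancestry_restricted <- function(recipients, donors,
                                  params = copying_params(),
                                  measure = c("length", "count")) {
  measure <- match.arg(measure)
  if (length(intersect(recipients$samples$id, donors$samples$id)))
    stop("recipient and donor ids overlap", call. = FALSE)
  if (!"group" %in% names(donors$samples))
    stop("donor panel needs a samples$group column", call. = FALSE)
  ch <- chromosome_level_vectors(recipients, donors, params, measure,
                                 by = "individual")
  X <- apply(ch, c(1, 2), sum)
  chg <- chromosome_level_vectors(recipients, donors, params, measure,
                                  by = "group", precomputed = attr(ch, "raw"))
  Xg <- apply(chg, c(1, 2), sum)
  structure(list(X = X, X_group = Xg,
                 donor_groups = tibble::tibble(id = donors$samples$id,
                                               group = donors$samples$group),
                 map_length = map_length(recipients$map), measure = measure,
                 c_heuristic = attr(attr(ch, "raw"), "c_heuristic")),
            class = "coancestry_restricted")
}

#' Per-chromosome copying vectors
#'
#' Restricted painting resolved by chromosome: for every recipient
#' individual, the expected cM copied from each donor individual (or donor
#' group) on each chromosome. Chromosome slices sum exactly to the totals of
#' [coancestry_restricted()]; they are the raw material of the
#' pseudo-individual bootstrap.
#'
#' @param recipients,donors As in [coancestry_restricted()].
#' @param params A [copying_params()].
#' @param measure `"length"` or `"count"`.
#' @param by `"individual"` or `"group"` aggregation of donor columns.
#' @param precomputed Internal reuse of raw per-donor results.
#' @return A 3-d array (recipients x donors-or-groups x chromosomes).
#' @export
chromosome_level_vectors <- function(recipients, donors,
                                     params = copying_params(),
                                     measure = c("length", "count"),
                                     by = c("individual", "group"),
                                     precomputed = NULL) {
  measure <- match.arg(measure)
  by <- match.arg(by)
  if (!isTRUE(all.equal(as.data.frame(recipients$map), as.data.frame(donors$map))))
    stop("recipients and donors are on different SNP grids", call. = FALSE)
  N <- nrow(recipients$samples)
  M <- nrow(donors$samples)
  chroms <- unique(recipients$map$chrom)
  raw <- precomputed
  if (is.null(raw)) {
    chrom_idx <- map_chrom_index(recipients$map)
    geno <- cbind(recipients$geno, donors$geno)
    storage.mode(geno) <- "integer"
    donor_cols <- 2L * N + seq_len(2L * M)
    raw <- array(0, dim = c(N, M, length(chroms)))
    tot_len <- 0; tot_chunks <- 0
    for (i in seq_len(N)) {
      for (h in c(2L * i - 1L, 2L * i)) {
        res <- paint_col(geno, chrom_idx, recipients$map$cm, h, donor_cols,
                         params, "count")
        v <- if (measure == "count") res$counts else res$lengths
        tot_len <- tot_len + sum(res$lengths)
        tot_chunks <- tot_chunks + sum(res$counts)
        # pool the two haplotypes of each donor individual
        raw[i, , ] <- raw[i, , ] + v[seq(1, 2 * M, 2), , drop = FALSE] +
          v[seq(2, 2 * M, 2), , drop = FALSE]
      }
    }
    dimnames(raw) <- list(recipients$samples$id, donors$samples$id, chroms)
    attr(raw, "c_heuristic") <- if (measure == "length") tot_len / tot_chunks else 1
  }
  if (by == "individual") {
    out <- raw
  } else {
    grp <- factor(donors$samples$group, levels = unique(donors$samples$group))
    out <- array(0, dim = c(N, nlevels(grp), length(chroms)),
                 dimnames = list(recipients$samples$id, levels(grp), chroms))
    for (cc in seq_along(chroms))
      out[, , cc] <- t(rowsum(t(matrix(raw[, , cc], N, M)), grp))
  }
  attr(out, "raw") <- raw
  attr(out, "map_length") <- map_length(recipients$map)
  out
}

#' Per-SNP copying posteriors aggregated by donor group
#'
#' The "paintings" that coancestry curves are built from: for each recipient
#' haplotype, the posterior probability at every SNP of copying from each
#' donor group, under restricted painting against an external donor panel.
#'
#' @param recipients,donors As in [coancestry_restricted()].
#' @param params A [copying_params()].
#' @return A list of class `copy_posteriors`: `post` (array SNPs x groups x
#'   haplotypes), `groups`, `map`, `hap_of` (individual id per haplotype).
#' @export
paint_posteriors <- function(recipients, donors, params = copying_params()) {
  if (!"group" %in% names(donors$samples))
    stop("donor panel needs a samples$group column", call. = FALSE)
  N <- nrow(recipients$samples)
  M <- nrow(donors$samples)
  grp <- factor(donors$samples$group, levels = unique(donors$samples$group))
  donor_group_by_hap <- rep(as.integer(grp), each = 2L)
  chrom_idx <- map_chrom_index(recipients$map)
  geno <- cbind(recipients$geno, donors$geno)
  storage.mode(geno) <- "integer"
  donor_cols <- 2L * N + seq_len(2L * M)
  H <- 2L * N
  post <- array(0, dim = c(nrow(recipients$map), nlevels(grp), H),
                dimnames = list(NULL, levels(grp), colnames(recipients$geno)))
  for (h in seq_len(H)) {
    res <- paint_col(geno, chrom_idx, recipients$map$cm, h, donor_cols,
                     params, "length", donor_group = donor_group_by_hap)
    post[, , h] <- res$posterior
  }
  structure(list(post = post, groups = levels(grp), map = recipients$map,
                 hap_of = rep(recipients$samples$id, each = 2L)),
            class = "copy_posteriors")
}
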