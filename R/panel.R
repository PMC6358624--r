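#' Phased haplotype panel
#'
#' The central data container of coanpipe: a set of phased biallelic
#' haplotypes on a shared SNP grid, together with a per-SNP genetic map and a
#' per-individual metadata table. Haplotypes are stored as an integer matrix
#' with one row per SNP and one column per haplotype; columns `2i - 1` and
#' `2i` belong to diploid individual `i` of `samples`.
#'
#' @param geno Integer matrix of 0/1 alleles, SNPs in rows, haplotypes in
#'   columns. Column count must be twice the number of rows of `samples`.
#' @param map Data frame with one row per SNP and columns `chrom`, `bp`,
#'   `cm` (cumulative centiMorgans within chromosome, strictly increasing).
#' @param samples Data frame with at least an `id` column (unique character
#'   ids) and optionally `group` plus geographic columns.
#'
#' @return An object of class `hap_panel`: a list with elements `geno`,
#'   `map` (tibble) and `samples` (tibble).
#' @export
hap_panel <- function(geno, map, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- tibble::as_tibble(map)
  samples <- tibble::as_tibble(samples)
  panel <- structure(list(geno = geno, map = map, samples = samples),
                     class = "hap_panel")
  validate_hap_panel(panel)
}

validate_hap_panel <- function(panel) {
  geno <- panel$geno; map <- panel$map; samples <- panel$samples
  if (!all(c("chrom", "bp", "cm") %in% names(map)))
    stop("map must have columns chrom, bp, cm", call. = FALSE)
  if (nrow(map) != nrow(geno))
    stop("map rows (", nrow(map), ") != geno SNP rows (", nrow(geno), ")",
         call. = FALSE)
  if (!"id" %in% names(samples)) stop("samples must have an id column", call. = FALSE)
  if (anyDuplicated(samples$id)) stop("duplicate sample ids", call. = FALSE)
  if (ncol(geno) != 2L * nrow(samples))
    stop("geno has ", ncol(geno), " haplotype columns; expected 2 x ",
         nrow(samples), " samples", call. = FALSE)
  if (length(geno) && !all(geno %in% c(0L, 1L)))
    stop("geno must be strictly 0/1 (biallelic, phased)", call. = FALSE)
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$cm) > 0) || dplyr::n() == 1L)
  if (!all(bad$ok))
    stop("map cm positions must be strictly increasing within chromosome",
         call. = FALSE)
  colnames(panel$geno) <- hap_ids(samples$id)
  panel
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("<hap_panel> ", nrow(x$samples), " diploid individuals, ",
      nrow(x$map), " SNPs on ", length(unique(x$map$chrom)),
      " chromosome(s), total map ", format(map_length(x$map), digits = 5),
      " cM\n", sep = "")
  invisible(x)
}

hap_ids <- function(ids) as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))

#' Haplotype column indices of a set of individuals
#' @param panel A `hap_panel`.
#' @param ids Character vector of sample ids.
#' @return Integer vector of `geno` column indices (two per individual).
#' @export
hap_index <- function(panel, ids) {
  pos <- match(ids, panel$samples$id)
  if (anyNA(pos)) stop("unknown sample id(s): ",
                       paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
  as.vector(rbind(2L * pos - 1L, 2L * pos))
}

#' Total genetic map length
#'
#' Sum over chromosomes of the cM span between the first and last SNP; the
#' length that expected-length painting conserves per haplotype.
#'
#' @param map A map tibble (`chrom`, `bp`, `cm`).
#' @return Length in centiMorgans.
#' @export
map_length <- function(map) {
  map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$cm) - min(.data$cm)) |>
    dplyr::pull(.data$len) |>
    sum()
}

#' Subset a panel by individuals
#' @param panel A `hap_panel`.
#' @param ids Sample ids to keep, in the order given.
#' @return A `hap_panel` with only those individuals.
#' @export
panel_subset <- function(panel, ids) {
  idx <- hap_index(panel, ids)
  out <- hap_panel(panel$geno[, idx, drop = FALSE], panel$map,
                   panel$samples[match(ids, panel$samples$id), , drop = FALSE])
  out$pool_freqs <- panel$pool_freqs
  out
}

#' Concatenate two panels on the same SNP grid
#' @param a,b `hap_panel` objects sharing an identical map.
#' @return Combined `hap_panel`.
#' @export
panel_bind <- function(a, b) {
  if (!isTRUE(all.equal(as.data.frame(a$map), as.data.frame(b$map))))
    stop("panels are on different SNP grids", call. = FALSE)
  samples <- dplyr::bind_rows(a$samples, b$samples)
  out <- hap_panel(cbind(a$geno, b$geno), a$map, samples)
  out$pool_freqs <- a$pool_freqs
  out
}

# split row indices of the map by chromosome, preserving order of appearance
chrom_rows <- function(map) split(seq_len(nrow(map)), factor(map$chrom, unique(map$chrom)))
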