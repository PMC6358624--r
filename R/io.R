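#' Read and write phased haplotype panels
#'
#' Two on-disk representations are supported, both plain text: HAP/SAMPLE
#' (one SNP per row: `chrom`, `snp_id`, `bp`, `a0`, `a1`, then two 0/1
#' alleles per individual) and phased VCF (GT-only, `0|1`-style genotypes).
#' The genetic map travels separately as a three-column TSV (see
#' [read_genetic_map()]) because neither format carries cM positions.
#'
#' @param prefix Path prefix; `<prefix>.hap` and `<prefix>.sample` are
#'   written/read.
#' @param panel A [hap_panel()].
#' @return `write_hap_sample()` returns the prefix invisibly;
#'   `read_hap_sample()` returns a [hap_panel()].
#' @export
write_hap_sample <- function(panel, prefix) {
  n <- nrow(panel$samples)
  hap <- cbind(panel$map$chrom, paste0("snp", seq_len(nrow(panel$map))),
               panel$map$bp, "A", "G",
               matrix(as.character(panel$geno), nrow(panel$geno)))
  utils::write.table(hap, paste0(prefix, ".hap"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  utils::write.table(panel$samples, paste0(prefix, ".sample"), quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_hap_sample
#' @param map Map tibble matching the SNP rows (from [read_genetic_map()]).
#' @export
read_hap_sample <- function(prefix, map) {
  hap <- utils::read.table(paste0(prefix, ".hap"), header = FALSE,
                           colClasses = "character")
  samples <- utils::read.table(paste0(prefix, ".sample"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  geno <- as.matrix(hap[, -(1:5), drop = FALSE])
  storage.mode(geno) <- "integer"
  check_map_panel(map, tibble::tibble(chrom = hap[[1]],
                                      bp = as.integer(hap[[3]])))
  hap_panel(geno, map, samples)
}

check_map_panel <- function(map, sites) {
  bad <- which(map$chrom != sites$chrom | map$bp != sites$bp)
  if (length(bad))
    stop("map/panel mismatch at ", length(bad), " site(s); first offenders: ",
         paste(utils::head(paste0(sites$chrom[bad], ":", sites$bp[bad]), 5),
               collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Write a panel as phased VCF
#'
#' Minimal VCFv4.2 writer for the GT-only phased biallelic panels this
#' package produces (see the package vignette for why the general-purpose
#' Bioconductor writer is not used here).
#'
#' @param panel A [hap_panel()].
#' @param path Output path.
#' @export
write_phased_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=coanpipe",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples$id), collapse = "\t")),
             con)
  n <- nrow(panel$samples)
  gt <- matrix("", nrow(panel$map), n)
  for (i in seq_len(n))
    gt[, i] <- paste0(panel$geno[, 2 * i - 1], "|", panel$geno[, 2 * i])
  body <- cbind(panel$map$chrom, panel$map$bp,
                paste0("snp", seq_len(nrow(panel$map))), "A", "G", ".",
                "PASS", ".", "GT", gt)
  utils::write.table(body, con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a phased VCF into a panel
#'
#' Accepts biallelic, fully phased records only: an unphased genotype or a
#' multiallelic ALT raises an error naming the site.
#'
#' @param path VCF file path.
#' @param map Map tibble (from [read_genetic_map()]) aligned to the records.
#' @param samples Optional metadata tibble (default: ids only).
#' @return A [hap_panel()].
#' @export
read_phased_vcf <- function(path, map, samples = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("missing #CHROM header line", call. = FALSE)
  cols <- strsplit(hdr, "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t")
  chrom <- vapply(fields, `[[`, character(1), 1)
  bp <- as.integer(vapply(fields, `[[`, character(1), 2))
  alt <- vapply(fields, `[[`, character(1), 5)
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multiallelic site at ", chrom[multi][1], ":", bp[multi][1],
         call. = FALSE)
  geno <- matrix(0L, length(body), 2L * length(ids))
  for (r in seq_along(fields)) {
    gts <- fields[[r]][-(1:9)]
    gt <- sub(":.*", "", gts)
    bad <- !grepl("^[01]\\|[01]$", gt)
    if (any(bad))
      stop("unphased or invalid genotype at ", chrom[r], ":", bp[r],
           " (sample ", ids[which(bad)[1]], ")", call. = FALSE)
    geno[r, seq(1, ncol(geno), 2)] <- as.integer(substr(gt, 1, 1))
    geno[r, seq(2, ncol(geno), 2)] <- as.integer(substr(gt, 3, 3))
  }
  check_map_panel(map, tibble::tibble(chrom = chrom, bp = bp))
  if (is.null(samples)) samples <- tibble::tibble(id = ids)
  hap_panel(geno, map, samples)
}

#' Genetic map IO
#'
#' Three-column TSV: `chrom`, `bp`, `cm` (cumulative cM within chromosome).
#'
#' @param path File path.
#' @param map Map tibble.
#' @return `read_genetic_map()` returns the map tibble.
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- setdiff(c("chrom", "bp", "cm"), names(map))
  if (length(need)) stop("genetic map missing column(s): ",
                         paste(need, collapse = ", "), call. = FALSE)
  tibble::as_tibble(map)
}

#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(format_num_df(map), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Sample metadata IO
#'
#' TSV with at least an `id` column; deme/group labels and grandparental
#' coordinates (`gp1_x` ... `gp4_y`) travel in the same table. Individuals
#' with missing grandparent columns simply load as not placeable.
#'
#' @param path File path.
#' @param samples Metadata tibble.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"id" %in% names(md)) stop("metadata missing id column", call. = FALSE)
  md$id <- as.character(md$id)
  tibble::as_tibble(md)
}

#' @rdname read_metadata
#' @export
write_metadata <- function(samples, path) {
  utils::write.table(format_num_df(samples), path, quote = FALSE,
                     row.names = FALSE, sep = "\t", na = "NA")
  invisible(path)
}

# full-precision numeric formatting so write -> read round-trips exactly
format_num_df <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Coancestry matrix IO
#'
#' TSV with row and column ids; numeric values are written in full precision
#' so a write/read round trip is exact.
#'
#' @param x Matrix (square or rectangular) with dimnames.
#' @param path File path.
#' @export
write_matrix <- function(x, path) {
  x <- as.matrix(x)
  df <- data.frame(id = rownames(x),
                   matrix(sprintf("%.17g", x), nrow(x),
                          dimnames = list(NULL, colnames(x))),
                   check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Partition IO
#'
#' TSV (`id`, `cluster`, optional `certainty`).
#'
#' @param partition Tibble (`id`, `cluster`, ...).
#' @param path File path.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(format_num_df(partition), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  tibble::as_tibble(df)
}

#' Write a cluster tree as Newick
#'
#' Leaves are cluster labels; branch lengths carry the merge scores
#' (posterior decreases), accumulated so that node heights are monotone.
#'
#' @param tree A [build_tree()] result.
#' @param path File path.
#' @param labels Optional leaf labels (default `cluster<k>`).
#' @return The `ape::phylo` tree, invisibly.
#' @export
write_newick <- function(tree, path, labels = NULL) {
  K <- tree$K
  if (is.null(labels)) labels <- paste0("cluster", seq_len(K))
  if (K == 1) {
    writeLines(paste0("(", labels[1], ");"), path)
    return(invisible(NULL))
  }
  m <- tree$merges
  hc_merge <- matrix(0L, K - 1, 2)
  node_of <- -seq_len(K)            # hclust convention: negatives = leaves
  heights <- cumsum(pmax(m$score, 1e-12))
  for (s in seq_len(K - 1)) {
    hc_merge[s, ] <- c(node_of[m$c1[s]], node_of[m$c2[s]])
    node_of[m$c1[s]] <- s
  }
  hc <- structure(list(merge = hc_merge, height = heights,
                       order = seq_len(K), labels = labels,
                       method = "greedy-posterior"),
                  class = "hclust")
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(phy)
}

#' Read a Newick tree
#' @param path File path.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Truth-tract IO
#' @param truth Truth record from [simulate_structured_panel()].
#' @param path File path.
#' @export
write_tracts <- function(truth, path) {
  utils::write.table(format_num_df(truth$tracts), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}
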