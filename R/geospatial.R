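#' Place individuals at grandparental centroids
#'
#' Each individual with four grandparental coordinates is placed at their
#' centroid. Individuals are `retained` for mapping when all four
#' grandparents lie within `max_gp_km` of the centroid (default 80 km; the
#' `"pairwise"` rule instead requires all grandparents within `max_gp_km` of
#' each other). Individuals sharing a display coordinate are deterministically
#' jittered by at most `jitter_km` (default 24 km).
#'
#' @param samples Metadata tibble with `id` and `gp1_x` ... `gp4_y` columns
#'   (e.g. from [assign_geography()]).
#' @param max_gp_km Retention radius (km).
#' @param jitter_km Maximum display displacement (km).
#' @param rule `"centroid"` (default) or `"pairwise"` reading of the filter.
#' @param seed Optional integer seed for the jitter.
#' @return Tibble of class `placed_individuals`: `id`, `x_km`, `y_km`
#'   (centroid), `max_gp_km` (largest grandparent distance under the rule),
#'   `retained`, `display_x`, `display_y`, `placeable`, `reason`.
#' @export
place_individuals <- function(samples, max_gp_km = 80, jitter_km = 24,
                              rule = c("centroid", "pairwise"), seed = NULL) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  gp_cols <- paste0("gp", rep(1:4, each = 2), c("_x", "_y"))
  missing_cols <- setdiff(gp_cols, names(samples))
  if (length(missing_cols))
    samples[missing_cols] <- NA_real_
  gx <- as.matrix(samples[paste0("gp", 1:4, "_x")])
  gy <- as.matrix(samples[paste0("gp", 1:4, "_y")])
  placeable <- stats::complete.cases(gx) & stats::complete.cases(gy)
  cx <- rowMeans(gx); cy <- rowMeans(gy)
  if (rule == "centroid") {
    d <- sqrt((gx - cx)^2 + (gy - cy)^2)
    maxd <- apply(d, 1, max)
  } else {
    maxd <- vapply(seq_len(nrow(gx)), function(i) {
      dx <- outer(gx[i, ], gx[i, ], "-"); dy <- outer(gy[i, ], gy[i, ], "-")
      max(sqrt(dx^2 + dy^2))
    }, numeric(1))
  }
  retained <- placeable & maxd <= max_gp_km
  out <- tibble::tibble(id = samples$id, x_km = cx, y_km = cy,
                        max_gp_km = maxd, retained = retained,
                        display_x = cx, display_y = cy,
                        placeable = placeable,
                        reason = ifelse(placeable, NA_character_,
                                        "missing grandparent coordinates"))
  # deterministic jitter of coinciding display points
  key <- paste(round(cx, 6), round(cy, 6))
  dup_groups <- split(which(placeable), key[placeable])
  for (g in dup_groups) {
    if (length(g) < 2) next
    r <- jitter_km * sqrt(stats::runif(length(g)))
    th <- 2 * pi * stats::runif(length(g))
    out$display_x[g] <- out$x_km[g] + r * cos(th)
    out$display_y[g] <- out$y_km[g] + r * sin(th)
  }
  structure(out, class = c("placed_individuals", class(out)))
}

# regular grid of cell-centre coordinates (cells identified by lower-left
# corner, half-open) covering the points with a margin
make_grid <- function(x, y, cell_km, pad = 0) {
  x0 <- floor((min(x) - pad) / cell_km) * cell_km
  x1 <- ceiling((max(x) + pad) / cell_km) * cell_km
  y0 <- floor((min(y) - pad) / cell_km) * cell_km
  y1 <- ceiling((max(y) + pad) / cell_km) * cell_km
  x1 <- max(x1, x0 + cell_km)        # degenerate extents still get one cell
  y1 <- max(y1, y0 + cell_km)
  tidyr::expand_grid(cell_x = seq(x0, x1 - cell_km, by = cell_km),
                     cell_y = seq(y0, y1 - cell_km, by = cell_km))
}

#' Per-cell cluster density contributions
#'
#' Colours a regular grid by the relative contribution of each cluster,
#' measured by Gaussian kernel densities centred on the retained individuals.
#' Contributions are normalized to sum to 1 in every cell.
#'
#' @param placed A [place_individuals()] tibble (only `retained` rows used).
#' @param partition Tibble (`id`, `cluster`).
#' @param cell_km Grid cell width (default 3 km).
#' @param kernel_km Gaussian kernel standard deviation (km).
#' @param pad_km Margin around the bounding box.
#' @return Tibble (`cell_x`, `cell_y`, `cluster`, `contribution`).
#' @export
cluster_density_grid <- function(placed, partition, cell_km = 3,
                                 kernel_km = 20, pad_km = 0) {
  pts <- placed[placed$retained, ]
  if (!nrow(pts)) stop("no retained individuals", call. = FALSE)
  cl <- partition$cluster[match(pts$id, partition$id)]
  grid <- make_grid(pts$x_km, pts$y_km, cell_km, pad_km)
  ctr_x <- grid$cell_x + cell_km / 2
  ctr_y <- grid$cell_y + cell_km / 2
  d2 <- outer(ctr_x, pts$x_km, "-")^2 + outer(ctr_y, pts$y_km, "-")^2
  w <- exp(-d2 / (2 * kernel_km^2))
  dens <- rowsum(t(w), cl)                   # clusters x cells
  tot <- colSums(dens)
  contrib <- t(dens) / tot                   # cells x clusters
  tibble::tibble(cell_x = rep(grid$cell_x, times = nrow(dens)),
                 cell_y = rep(grid$cell_y, times = nrow(dens)),
                 cluster = rep(rownames(dens), each = nrow(grid)),
                 contribution = as.vector(contrib))
}

#' Spatially smoothed copying vectors on a grid
#'
#' Gaussian kernel average of per-individual copying vectors at each cell of
#' a regular grid, with an adaptive bandwidth: at each cell the kernel sd is
#' the larger of `base_bw_km` and the distance to the `k_nn`-th nearest
#' retained individual, so sparsely sampled regions are smoothed more. Cells
#' inside an optional constant region all receive the plain average vector of
#' the designated individuals (for regions with no fine-scale geography).
#'
#' @param placed A [place_individuals()] tibble.
#' @param vectors Matrix individuals x donor groups (rownames = ids), e.g.
#'   `$X_group` of [coancestry_restricted()].
#' @param cell_km,base_bw_km,k_nn Smoothing parameters (defaults 3 km, 3 km,
#'   10 neighbours).
#' @param pad_km Margin around the bounding box.
#' @param constant_region Optional predicate `function(x, y)` returning TRUE
#'   for cells in the constant region.
#' @param constant_ids Ids whose average vector fills the constant region.
#' @return Object of class `smoothed_grid`: list with `grid` (tibble
#'   `cell_x`, `cell_y`, `bandwidth`, `constant`, `flagged`) and `Y` (cells x
#'   groups matrix of smoothed proportion vectors).
#' @export
smoothed_copying_grid <- function(placed, vectors, cell_km = 3,
                                  base_bw_km = 3, k_nn = 10, pad_km = 0,
                                  constant_region = NULL,
                                  constant_ids = NULL) {
  pts <- placed[placed$retained & placed$id %in% rownames(vectors), ]
  if (!nrow(pts)) stop("no retained individuals with vectors", call. = FALSE)
  V <- vectors[pts$id, , drop = FALSE]
  V <- V / rowSums(V)
  grid <- make_grid(pts$x_km, pts$y_km, cell_km, pad_km)
  ctr_x <- grid$cell_x + cell_km / 2
  ctr_y <- grid$cell_y + cell_km / 2
  D <- sqrt(outer(ctr_x, pts$x_km, "-")^2 + outer(ctr_y, pts$y_km, "-")^2)
  k <- min(k_nn, nrow(pts))
  bw <- pmax(base_bw_km, apply(D, 1, function(d) sort(d)[k]))
  W <- exp(-D^2 / (2 * bw^2))
  tot <- rowSums(W)
  flagged <- tot < 1e-300
  Y <- (W %*% V) / pmax(tot, 1e-300)
  const <- rep(FALSE, nrow(grid))
  if (!is.null(constant_region)) {
    const <- mapply(constant_region, ctr_x, ctr_y)
    if (is.null(constant_ids)) stop("constant_region needs constant_ids",
                                    call. = FALSE)
    avg <- colMeans(vectors[intersect(constant_ids, rownames(vectors)), ,
                            drop = FALSE])
    avg <- avg / sum(avg)
    Y[const, ] <- matrix(avg, sum(const), length(avg), byrow = TRUE)
    flagged[const] <- FALSE
  }
  structure(list(grid = tibble::tibble(cell_x = grid$cell_x,
                                       cell_y = grid$cell_y,
                                       bandwidth = bw, constant = const,
                                       flagged = flagged),
                 Y = Y, groups = colnames(vectors)),
            class = "smoothed_grid")
}

#' Ancestry profiles at every grid cell
#'
#' Fits [fit_ancestry_profile()] to each cell's smoothed copying vector,
#' giving per-cell mixture coefficients over donor groups (a map of, e.g.,
#' the north-African coefficient is one column of the result).
#'
#' @param grid A [smoothed_copying_grid()] result.
#' @param B Donor basis from [donor_basis_vectors()].
#' @return Tibble (`cell_x`, `cell_y`, `group`, `coefficient`).
#' @export
grid_profiles <- function(grid, B) {
  G <- nrow(B)
  ok <- !grid$grid$flagged
  coefs <- matrix(NA_real_, nrow(grid$grid), G)
  seen <- list()
  for (i in which(ok)) {
    key <- paste(signif(grid$Y[i, ], 12), collapse = ",")
    if (!is.null(seen[[key]])) {
      coefs[i, ] <- seen[[key]]
    } else {
      fit <- fit_ancestry_profile(grid$Y[i, ], B)
      coefs[i, ] <- fit$coefficient
      seen[[key]] <- fit$coefficient
    }
  }
  tibble::tibble(cell_x = rep(grid$grid$cell_x, times = G),
                 cell_y = rep(grid$grid$cell_y, times = G),
                 group = rep(rownames(B), each = nrow(grid$grid)),
                 coefficient = as.vector(coefs))
}
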