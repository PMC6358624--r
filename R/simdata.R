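#' Specify a synthetic demographic scenario
#'
#' Describes a stated world for the generator: a set of demes drawn from
#' Balding-Nichols drifted allele frequencies around a shared base pool,
#' optional external donor pools, and optional dated single-pulse admixture
#' events. Every downstream stage of the package can be exercised against the
#' truth records this scenario implies.
#'
#' @param demes Data frame with columns `label`, `n` (diploid sample
#'   size, at least 2), `drift` (Balding-Nichols F in `[0, 1)`), and
#'   optionally `x_km`,
#'   `y_km` (planar centroid) and `dispersion_km` (grandparental scatter).
#' @param donors Optional data frame with columns `label`, `n`, `divergence`
#'   (Balding-Nichols F of the pool relative to the base pool).
#' @param pulses Optional data frame with columns `source` (a deme or donor
#'   label), `recipient` (a deme label), `alpha` (admixture proportion in
#'   `[0, 1]`) and `g` (age in generations, integer >= 1).
#' @param n_chrom Number of chromosomes.
#' @param chrom_cm Genetic length per chromosome in cM (scalar or vector of
#'   length `n_chrom`); maps are uniform within a chromosome.
#' @param snps_per_chrom SNPs per chromosome.
#' @param seed Integer seed; all randomness of the scenario flows from it.
#'
#' @return An object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(demes, donors = NULL, pulses = NULL,
                                 n_chrom = 2L, chrom_cm = 100,
                                 snps_per_chrom = 200L, seed = 1L) {
  demes <- tibble::as_tibble(demes)
  need <- setdiff(c("label", "n", "drift"), names(demes))
  if (length(need)) stop("demes: missing field(s) ", paste(need, collapse = ", "),
                         call. = FALSE)
  if (!"x_km" %in% names(demes)) demes$x_km <- 0
  if (!"y_km" %in% names(demes)) demes$y_km <- 0
  if (!"dispersion_km" %in% names(demes)) demes$dispersion_km <- 0
  if (any(demes$n < 2)) stop("demes: field n must be >= 2", call. = FALSE)
  if (any(demes$drift < 0 | demes$drift >= 1))
    stop("demes: field drift must lie in [0, 1)", call. = FALSE)
  if (!is.null(donors)) {
    donors <- tibble::as_tibble(donors)
    need <- setdiff(c("label", "n", "divergence"), names(donors))
    if (length(need)) stop("donors: missing field(s) ",
                           paste(need, collapse = ", "), call. = FALSE)
    if (any(donors$n < 2)) stop("donors: field n must be >= 2", call. = FALSE)
    if (any(donors$divergence < 0 | donors$divergence >= 1))
      stop("donors: field divergence must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(pulses)) {
    pulses <- tibble::as_tibble(pulses)
    need <- setdiff(c("source", "recipient", "alpha", "g"), names(pulses))
    if (length(need)) stop("pulses: missing field(s) ",
                           paste(need, collapse = ", "), call. = FALSE)
    if (any(pulses$alpha < 0 | pulses$alpha > 1))
      stop("pulses: field alpha must lie in [0, 1]", call. = FALSE)
    if (any(pulses$g < 1 | pulses$g != round(pulses$g)))
      stop("pulses: field g must be an integer >= 1", call. = FALSE)
    known <- c(demes$label, if (!is.null(donors)) donors$label)
    if (!all(pulses$source %in% known))
      stop("pulses: field source has unknown label(s)", call. = FALSE)
    if (!all(pulses$recipient %in% demes$label))
      stop("pulses: field recipient has unknown deme label(s)", call. = FALSE)
  }
  chrom_cm <- rep_len(chrom_cm, n_chrom)
  if (any(chrom_cm <= 0)) stop("chrom_cm: map lengths must be > 0", call. = FALSE)
  if (anyDuplicated(c(demes$label, if (!is.null(donors)) donors$label)))
    stop("label: deme/donor labels must be unique", call. = FALSE)
  structure(list(demes = demes, donors = donors, pulses = pulses,
                 n_chrom = as.integer(n_chrom), chrom_cm = chrom_cm,
                 snps_per_chrom = as.integer(snps_per_chrom),
                 seed = as.integer(seed)),
            class = "demographic_scenario")
}

scenario_map <- function(scenario) {
  purrr::map_dfr(seq_len(scenario$n_chrom), function(cc) {
    cm <- seq(0, scenario$chrom_cm[cc], length.out = scenario$snps_per_chrom)
    tibble::tibble(chrom = paste0("chr", cc), bp = as.integer(round(cm * 1e6)) + 1L,
                   cm = cm)
  })
}

# iid haplotypes from a frequency vector: L x (2n) integer matrix
draw_pool_haps <- function(freq, n_dip) {
  H <- 2L * n_dip
  matrix(stats::rbinom(length(freq) * H, 1L, rep(freq, H)),
         nrow = length(freq), ncol = H)
}

bn_freq <- function(base, F) {
  if (F == 0) return(base)
  stats::rbeta(length(base), base * (1 - F) / F, (1 - base) * (1 - F) / F)
}

#' Simulate a structured phased haplotype panel with known truth
#'
#' Draws per-pool allele frequencies by Balding-Nichols perturbation of a
#' shared base pool, samples phased haplotypes i.i.d. within each pool, then
#' applies the scenario's admixture pulses in order. Deterministic under the
#' scenario seed.
#'
#' @param scenario A [demographic_scenario()].
#' @return A list with elements `panel` (a [hap_panel()] holding deme and
#'   donor individuals, distinguished by `samples$role`) and `truth` (list of
#'   `tracts`, `demes`, `pulses` realized).
#' @export
simulate_structured_panel <- function(scenario) {
  stopifnot(inherits(scenario, "demographic_scenario"))
  set.seed(scenario$seed)
  map <- scenario_map(scenario)
  L <- nrow(map)
  base <- stats::runif(L, 0.05, 0.95)

  pools <- dplyr::bind_rows(
    dplyr::transmute(scenario$demes, label = .data$label, n = .data$n,
                     F = .data$drift, role = "deme"),
    if (!is.null(scenario$donors))
      dplyr::transmute(scenario$donors, label = .data$label, n = .data$n,
                       F = .data$divergence, role = "donor"))

  geno_list <- vector("list", nrow(pools))
  samples <- vector("list", nrow(pools))
  pool_freqs <- matrix(0, L, nrow(pools), dimnames = list(NULL, pools$label))
  for (k in seq_len(nrow(pools))) {
    freq <- bn_freq(base, pools$F[k])
    pool_freqs[, k] <- freq
    geno_list[[k]] <- draw_pool_haps(freq, pools$n[k])
    samples[[k]] <- tibble::tibble(
      id = sprintf("%s_%02d", pools$label[k], seq_len(pools$n[k])),
      group = pools$label[k], role = pools$role[k])
  }
  samples <- dplyr::bind_rows(samples)
  panel <- hap_panel(do.call(cbind, geno_list), map, samples)
  panel$pool_freqs <- pool_freqs

  tracts <- tidyr::expand_grid(
    hap = colnames(panel$geno),
    map |> dplyr::group_by(.data$chrom) |>
      dplyr::summarise(start_cm = min(.data$cm), end_cm = max(.data$cm))) |>
    dplyr::mutate(source = samples$group[match(sub("_[12]$", "", .data$hap),
                                               samples$id)]) |>
    dplyr::select("hap", "chrom", "start_cm", "end_cm", "source")

  truth <- list(tracts = tracts,
                demes = dplyr::filter(samples, .data$role == "deme") |>
                  dplyr::transmute(id = .data$id, deme = .data$group),
                pulses = tibble::tibble(source = character(), recipient = character(),
                                        alpha = numeric(), g = numeric(),
                                        realized_alpha = numeric()))
  if (!is.null(scenario$pulses)) {
    for (k in seq_len(nrow(scenario$pulses))) {
      p <- scenario$pulses[k, ]
      res <- apply_admixture_pulse(panel, truth, source = p$source,
                                   recipient = p$recipient,
                                   alpha = p$alpha, g = p$g)
      panel <- res$panel; truth <- res$truth
    }
  }
  list(panel = panel, truth = truth)
}

#' Overlay a dated admixture pulse on a panel
#'
#' Rebuilds every haplotype of the recipient deme as a sequence of ancestry
#' tracts: tract boundaries are laid down as a Poisson process with rate `g`
#' per Morgan along each chromosome, and each inter-boundary segment is
#' independently labelled "source" with probability `alpha` (its alleles then
#' copied from a uniformly chosen source-pool haplotype) or left as the
#' recipient's own sequence. Segment lengths are therefore exponential with
#' mean `100 / g` cM, the tract-length signature of a pulse `g` generations
#' ago that all downstream dating rests on.
#'
#' @param panel A [hap_panel()].
#' @param truth Matching truth record (from [simulate_structured_panel()]).
#' @param source Label of the source pool (any deme or donor group present in
#'   `panel$samples$group`).
#' @param recipient Label of the recipient deme.
#' @param alpha Admixture proportion in `[0, 1]`.
#' @param g Pulse age in generations (>= 1).
#' @param seed Optional integer seed (sets the RNG stream).
#' @return A list `panel`, `truth` with tracts updated; tracts still tile
#'   every chromosome exactly.
#' @export
apply_admixture_pulse <- function(panel, truth, source, recipient, alpha, g,
                                  seed = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (g < 1) stop("g must be >= 1", call. = FALSE)
  if (!source %in% panel$samples$group)
    stop("unknown source label: ", source, call. = FALSE)
  if (!recipient %in% panel$samples$group)
    stop("unknown recipient label: ", recipient, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  rec_ids <- panel$samples$id[panel$samples$group == recipient]
  out <- record_pulse <- NULL
  if (alpha == 0) {
    truth$pulses <- dplyr::bind_rows(truth$pulses, tibble::tibble(
      source = source, recipient = recipient, alpha = 0, g = as.numeric(g),
      realized_alpha = 0))
    return(list(panel = panel, truth = truth))
  }

  # Source material for admixed tracts: fresh haplotypes drawn from the
  # source pool's allele frequencies when available (the historical admixers
  # were distinct members of the source population, not clones of the
  # sampled donors); otherwise segments are copied from the sampled source
  # haplotypes themselves.
  src_freq <- if (!is.null(panel$pool_freqs) &&
                  source %in% colnames(panel$pool_freqs))
    panel$pool_freqs[, source] else NULL
  src_cols <- which(panel$samples$group[ceiling(seq_len(ncol(panel$geno)) / 2)] == source)
  rec_haps <- hap_index(panel, rec_ids)
  geno <- panel$geno
  rows_by_chrom <- chrom_rows(panel$map)
  chroms <- names(rows_by_chrom)

  # plain-vector bookkeeping (this loop dominates simulation time)
  tract_key <- paste(truth$tracts$hap, truth$tracts$chrom, sep = "\r")
  old_by_key <- split(seq_len(nrow(truth$tracts)), tract_key)
  ot_start <- truth$tracts$start_cm; ot_end <- truth$tracts$end_cm
  ot_source <- truth$tracts$source
  acc_hap <- list(); acc_chrom <- list(); acc_start <- list()
  acc_end <- list(); acc_source <- list()
  ti <- 0L
  src_len <- 0; tot_len <- 0
  for (h in rec_haps) {
    hap_name <- colnames(panel$geno)[h]
    for (cc in chroms) {
      rows <- rows_by_chrom[[cc]]
      cm <- panel$map$cm[rows]
      c0 <- cm[1]; c1 <- cm[length(cm)]
      # Poisson switch points: iid exponential gaps, rate g per Morgan
      gaps <- stats::rexp(max(8, ceiling(2 * g * (c1 - c0) / 100)), rate = g / 100)
      while (sum(gaps) < c1 - c0) gaps <- c(gaps, stats::rexp(8, rate = g / 100))
      bounds <- c0 + cumsum(gaps)
      bounds <- c(c0, bounds[bounds < c1])
      starts <- bounds; ends <- c(bounds[-1], c1)
      nseg <- length(starts)
      lab_src <- stats::runif(nseg) < alpha
      old_idx <- old_by_key[[paste(hap_name, cc, sep = "\r")]]
      seg_start <- numeric(0); seg_end <- numeric(0); seg_src <- character(0)
      for (s in seq_len(nseg)) {
        if (lab_src[s]) {
          sel <- if (s == nseg) cm >= starts[s] & cm <= ends[s] else
            cm >= starts[s] & cm < ends[s]
          if (!is.null(src_freq)) {
            geno[rows[sel], h] <- stats::rbinom(sum(sel), 1L, src_freq[rows[sel]])
          } else {
            don <- src_cols[sample.int(length(src_cols), 1L)]
            geno[rows[sel], h] <- panel$geno[rows[sel], don]
          }
          seg_start <- c(seg_start, starts[s])
          seg_end <- c(seg_end, ends[s])
          seg_src <- c(seg_src, source)
          src_len <- src_len + (ends[s] - starts[s])
        } else {
          # keep own sequence; intersect prior tracts with this segment
          ov <- old_idx[ot_end[old_idx] > starts[s] & ot_start[old_idx] < ends[s]]
          seg_start <- c(seg_start, pmax(ot_start[ov], starts[s]))
          seg_end <- c(seg_end, pmin(ot_end[ov], ends[s]))
          seg_src <- c(seg_src, ot_source[ov])
        }
        tot_len <- tot_len + (ends[s] - starts[s])
      }
      ti <- ti + 1L
      acc_hap[[ti]] <- rep(hap_name, length(seg_start))
      acc_chrom[[ti]] <- rep(cc, length(seg_start))
      acc_start[[ti]] <- seg_start
      acc_end[[ti]] <- seg_end
      acc_source[[ti]] <- seg_src
    }
  }
  touched <- tract_key %in% paste(rep(colnames(panel$geno)[rec_haps],
                                      each = length(chroms)),
                                  rep(chroms, length(rec_haps)), sep = "\r")
  truth$tracts <- dplyr::bind_rows(
    truth$tracts[!touched, ],
    tibble::tibble(hap = unlist(acc_hap), chrom = unlist(acc_chrom),
                   start_cm = unlist(acc_start), end_cm = unlist(acc_end),
                   source = unlist(acc_source))) |>
    dplyr::arrange(.data$hap, .data$chrom, .data$start_cm)
  truth$pulses <- dplyr::bind_rows(truth$pulses, tibble::tibble(
    source = source, recipient = recipient, alpha = alpha, g = as.numeric(g),
    realized_alpha = src_len / tot_len))
  panel$geno <- geno
  list(panel = panel, truth = truth)
}

#' Canonical two-focal-cluster demographic cartoons
#'
#' Builds small panels realizing the textbook scenarios in which two clusters
#' (`alpha`, `beta`) show high mutual coancestry: a pure split; admixture into
#' `alpha` from an external pool; admixture into `beta` from a highly drifted
#' `alpha`; or mutual exchange. Three mildly drifted background demes are
#' included so that copying is not artificially confined to the two focal
#' clusters (as in a realistic many-cluster sample); the focal coancestry
#' orderings these cartoons predict are asserted by the drift-test module.
#'
#' @param which One of `"split"`, `"mix-into-alpha"`,
#'   `"mix-into-beta-from-drifted"`, `"bidirectional"`.
#' @param seed Integer seed.
#' @param n_per_deme Diploid individuals per deme (default 18, so that the
#'   equal-size bootstrap subsample of 13 still varies across resamples).
#' @param snps_per_chrom,n_chrom,chrom_cm Genome spec, as in
#'   [demographic_scenario()].
#' @return A list `panel`, `truth`, `focal` (the two focal deme labels).
#' @export
simulate_two_cluster_scenario <- function(which = c("split", "mix-into-alpha",
                                                    "mix-into-beta-from-drifted",
                                                    "bidirectional"),
                                          seed = 1L, n_per_deme = 18L,
                                          snps_per_chrom = 200L, n_chrom = 2L,
                                          chrom_cm = 100) {
  which <- match.arg(which)
  bg <- tibble::tibble(label = c("bg1", "bg2", "bg3"), n = n_per_deme,
                       drift = c(0.01, 0.012, 0.008))
  focal <- switch(which,
    "split" = tibble::tibble(label = c("alpha", "beta"), n = n_per_deme,
                             drift = c(0.12, 0.12)),
    "mix-into-alpha" = tibble::tibble(label = c("alpha", "beta"), n = n_per_deme,
                                      drift = c(0.1, 0.1)),
    "mix-into-beta-from-drifted" = tibble::tibble(label = c("alpha", "beta"),
                                                  n = n_per_deme,
                                                  drift = c(0.5, 0.02)),
    "bidirectional" = tibble::tibble(label = c("alpha", "beta"), n = n_per_deme,
                                     drift = c(0.15, 0.15)))
  donors <- if (which == "mix-into-alpha")
    tibble::tibble(label = "ext", n = 10L, divergence = 0.1) else NULL
  pulses <- switch(which,
    "split" = NULL,
    "mix-into-alpha" = tibble::tibble(source = "ext", recipient = "alpha",
                                      alpha = 0.3, g = 20),
    "mix-into-beta-from-drifted" = tibble::tibble(source = "alpha",
                                                  recipient = "beta",
                                                  alpha = 0.4, g = 20),
    "bidirectional" = tibble::tibble(source = c("alpha", "beta"),
                                     recipient = c("beta", "alpha"),
                                     alpha = c(0.15, 0.15), g = c(20, 20)))
  sc <- demographic_scenario(dplyr::bind_rows(focal, bg), donors = donors,
                             pulses = pulses, n_chrom = n_chrom,
                             chrom_cm = chrom_cm,
                             snps_per_chrom = snps_per_chrom, seed = seed)
  sim <- simulate_structured_panel(sc)
  # drop external donor pool individuals: the emitted panel holds demes only
  deme_ids <- sim$panel$samples$id[sim$panel$samples$role == "deme"]
  sim$panel <- panel_subset(sim$panel, deme_ids)
  sim$truth$tracts <- dplyr::filter(sim$truth$tracts,
                                    .data$hap %in% colnames(sim$panel$geno))
  list(panel = sim$panel, truth = sim$truth, focal = c("alpha", "beta"))
}

#' Draw grandparental birthplace coordinates around deme centroids
#'
#' Gives each deme individual four "grandparent" coordinates drawn from an
#' isotropic Gaussian around the deme centroid with the deme's dispersion (so
#' the RMS grandparent-centroid distance is `sqrt(2) * dispersion_km`). A
#' configurable fraction of individuals receive one distant grandparent, to
#' exercise the 80-km placement filter downstream.
#'
#' @param panel A [hap_panel()] whose samples carry `group` labels.
#' @param scenario The generating [demographic_scenario()] (for centroids and
#'   dispersions).
#' @param distant_fraction Fraction of individuals whose first grandparent is
#'   displaced by `distant_km`.
#' @param distant_km Displacement of the distant grandparent (km).
#' @param seed Optional integer seed.
#' @return The panel with `gp1_x` ... `gp4_y` columns added to `samples`
#'   (NA for donor-pool individuals).
#' @export
assign_geography <- function(panel, scenario, distant_fraction = 0,
                             distant_km = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- panel$samples
  for (col in paste0("gp", rep(1:4, each = 2), c("_x", "_y"))) s[[col]] <- NA_real_
  s$distant_gp <- FALSE
  for (k in seq_len(nrow(scenario$demes))) {
    d <- scenario$demes[k, ]
    rows <- which(s$group == d$label)
    if (!length(rows)) next
    for (gp in 1:4) {
      s[[paste0("gp", gp, "_x")]][rows] <- stats::rnorm(length(rows), d$x_km,
                                                        d$dispersion_km)
      s[[paste0("gp", gp, "_y")]][rows] <- stats::rnorm(length(rows), d$y_km,
                                                        d$dispersion_km)
    }
    far <- rows[stats::runif(length(rows)) < distant_fraction]
    s$gp1_x[far] <- s$gp1_x[far] + distant_km
    s$distant_gp[far] <- TRUE
  }
  panel$samples <- s
  panel
}
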