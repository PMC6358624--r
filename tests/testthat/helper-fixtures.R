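# Shared fixtures, memoized so expensive painted panels are built once per
# test run. Everything is generated in code under fixed seeds.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# tiny random painting instance for oracle comparisons
tiny_instance <- function(seed, L = 5, D = 3, n_chrom = 1) {
  set.seed(seed)
  chrom <- sort(rep_len(paste0("chr", seq_len(n_chrom)), L))
  map <- tibble::tibble(chrom = chrom, bp = seq_len(L), cm = 0) |>
    dplyr::group_by(chrom) |>
    dplyr::mutate(cm = sort(stats::runif(dplyr::n(), 0, 5))) |>
    dplyr::ungroup()
  list(recipient = stats::rbinom(L, 1, 0.5),
       donors = matrix(stats::rbinom(L * D, 1, 0.5), L, D),
       map = map)
}

# brute-force oracle: enumerate all D^L copying paths
oracle_paint <- function(recipient, donors, map, params,
                         measure = "length") {
  L <- length(recipient); D <- ncol(donors)
  rho <- params$switch_rate; th <- params$miscopy
  chrom <- as.integer(factor(map$chrom, unique(map$chrom)))
  paths <- as.matrix(expand.grid(rep(list(seq_len(D)), L)))
  out <- numeric(D); Z <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    pr <- 1
    for (j in seq_len(L)) {
      em <- if (recipient[j] == donors[j, path[j]]) 1 - th else th
      if (j == 1 || chrom[j] != chrom[j - 1]) {
        pr <- pr * em / D
      } else {
        rr <- exp(-rho * (map$cm[j] - map$cm[j - 1]))
        tr <- if (path[j] == path[j - 1]) rr + (1 - rr) / D else (1 - rr) / D
        pr <- pr * em * tr
      }
    }
    Z <- Z + pr
    if (measure == "length") {
      for (j in seq_len(L - 1))
        if (chrom[j] == chrom[j + 1])
          out[path[j]] <- out[path[j]] + pr * (map$cm[j + 1] - map$cm[j])
    } else {
      ch <- numeric(D); ch[path[1]] <- ch[path[1]] + 1
      for (j in 2:L) {
        if (chrom[j] != chrom[j - 1] || path[j] != path[j - 1])
          ch[path[j]] <- ch[path[j]] + 1
      }
      out <- out + pr * ch
    }
  }
  out / Z
}

# simplex grid-search oracle for ancestry profiles (step 0.01 by default)
oracle_simplex_fit <- function(y, B, step = 0.01) {
  G <- nrow(B)
  grid <- seq(0, 1, by = step)
  best <- NULL
  rec <- function(prefix, remaining, k) {
    if (k == G) {
      beta <- c(prefix, remaining)
      r <- sum((as.vector(t(B) %*% beta) - y)^2)
      if (is.null(best) || r < best$r) best <<- list(r = r, beta = beta)
      return(invisible())
    }
    for (v in grid[grid <= remaining + 1e-9])
      rec(c(prefix, v), remaining - v, k + 1)
  }
  rec(numeric(0), 1, 1)
  best$beta
}

three_deme_sim <- function() memo("three_deme", {
  sc <- demographic_scenario(
    demes = tibble::tibble(label = c("A", "B", "C"), n = 20,
                           drift = c(0.2, 0.22, 0.24),
                           x_km = c(0, 120, 60), y_km = c(0, 0, 100),
                           dispersion_km = 8),
    n_chrom = 2, chrom_cm = 100, snps_per_chrom = 800, seed = 1)
  sim <- simulate_structured_panel(sc)
  sim$scenario <- sc
  sim
})

three_deme_square <- function() memo("three_deme_square", {
  coancestry_square(three_deme_sim()$panel)
})

three_deme_fit <- function() memo("three_deme_fit", {
  fs_mcmc(three_deme_square(), seed = 3)
})

# recipients + strongly diverged donor pools with a dated pulse, for
# profiles/dating tests
dated_sim <- function() memo("dated_sim", {
  sc <- demographic_scenario(
    demes = tibble::tibble(label = "T", n = 30, drift = 0.02),
    donors = tibble::tibble(label = c("P1", "P2"), n = c(15, 15),
                            divergence = c(0.05, 0.5)),
    pulses = tibble::tibble(source = "P2", recipient = "T",
                            alpha = 0.1, g = 30),
    n_chrom = 5, chrom_cm = 160, snps_per_chrom = 640, seed = 21)
  sim <- simulate_structured_panel(sc)
  sim$targets <- panel_subset(sim$panel,
                              sim$panel$samples$id[sim$panel$samples$group == "T"])
  sim$donors <- panel_subset(sim$panel,
                             sim$panel$samples$id[sim$panel$samples$role == "donor"])
  sim
})

dated_posteriors <- function() memo("dated_posteriors", {
  sim <- dated_sim()
  paint_posteriors(sim$targets, sim$donors, copying_params(switch_rate = 2))
})

dated_basis <- function() memo("dated_basis", {
  donor_basis_vectors(dated_sim()$donors, copying_params(switch_rate = 2))
})

# small three-group donor panel for profile tests
donor_trio <- function() memo("donor_trio", {
  sc <- demographic_scenario(
    demes = tibble::tibble(label = "T", n = 6, drift = 0.05),
    donors = tibble::tibble(label = c("G1", "G2", "G3"), n = 8,
                            divergence = c(0.3, 0.4, 0.5)),
    n_chrom = 2, chrom_cm = 100, snps_per_chrom = 300, seed = 5)
  sim <- simulate_structured_panel(sc)
  list(sim = sim,
       demes = panel_subset(sim$panel,
                            sim$panel$samples$id[sim$panel$samples$role == "deme"]),
       donors = panel_subset(sim$panel,
                             sim$panel$samples$id[sim$panel$samples$role == "donor"]))
})

random_profile_basis <- function(G, seed) {
  set.seed(seed)
  B <- matrix(stats::runif(G * G, 0.02, 1), G)
  B <- B / rowSums(B)
  dimnames(B) <- list(paste0("g", seq_len(G)), paste0("g", seq_len(G)))
  B
}
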