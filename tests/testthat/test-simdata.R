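test_that("scenario validation names the offending field", {
  demes <- tibble::tibble(label = "A", n = 5, drift = 0.1)
  expect_error(demographic_scenario(dplyr::mutate(demes, n = 1)), "n must be")
  expect_error(demographic_scenario(dplyr::mutate(demes, drift = 1.2)),
               "drift")
  expect_error(demographic_scenario(demes, pulses = tibble::tibble(
    source = "X", recipient = "A", alpha = 0.1, g = 5)), "source")
  expect_error(demographic_scenario(demes, pulses = tibble::tibble(
    source = "A", recipient = "A", alpha = 1.5, g = 5)), "alpha")
  expect_error(demographic_scenario(demes, pulses = tibble::tibble(
    source = "A", recipient = "A", alpha = 0.5, g = 0.5)), "g must be")
  expect_error(demographic_scenario(demes, chrom_cm = -1), "map lengths")
})

test_that("panels are deterministic under the scenario seed", {
  sc <- demographic_scenario(tibble::tibble(label = c("A", "B"), n = 4,
                                            drift = 0.2),
                             snps_per_chrom = 50, seed = 7)
  s1 <- simulate_structured_panel(sc)
  s2 <- simulate_structured_panel(sc)
  expect_identical(s1$panel$geno, s2$panel$geno)
  expect_identical(s1$truth$tracts, s2$truth$tracts)
})

test_that("zero drift gives exchangeable haplotypes; drift creates structure", {
  sc0 <- demographic_scenario(tibble::tibble(label = "P", n = 20, drift = 0),
                              n_chrom = 2, snps_per_chrom = 300, seed = 2)
  g <- simulate_structured_panel(sc0)$panel$geno
  # split haplotypes arbitrarily in two halves: identity means agree
  idx <- seq_len(ncol(g))
  d_within1 <- mean(g[, idx[1:20]] == g[, idx[21:40]])
  d_within2 <- mean(g[, idx[1:10]] == g[, idx[31:40]])
  expect_lt(abs(d_within1 - d_within2), 0.02)

  sc <- demographic_scenario(tibble::tibble(label = c("A", "B"), n = 20,
                                            drift = 0.2),
                             n_chrom = 2, snps_per_chrom = 300, seed = 3)
  g2 <- simulate_structured_panel(sc)$panel$geno
  ha <- g2[, 1:40]; hb <- g2[, 41:80]
  within <- (mean(ha[, 1:20] == ha[, 21:40]) +
             mean(hb[, 1:20] == hb[, 21:40])) / 2
  between <- mean(ha == hb)
  expect_gt(within, between)
})

test_that("null and full admixture pulses behave as contracts", {
  sc <- demographic_scenario(
    tibble::tibble(label = c("A", "B"), n = 4, drift = 0.1),
    snps_per_chrom = 60, seed = 4)
  sim <- simulate_structured_panel(sc)
  p0 <- apply_admixture_pulse(sim$panel, sim$truth, "B", "A", alpha = 0,
                              g = 10, seed = 1)
  expect_identical(p0$panel$geno, sim$panel$geno)
  expect_equal(sum(p0$truth$tracts$source == "B" &
                     grepl("^A", p0$truth$tracts$hap)), 0)

  p1 <- apply_admixture_pulse(sim$panel, sim$truth, "B", "A", alpha = 1,
                              g = 10, seed = 1)
  a_tracts <- dplyr::filter(p1$truth$tracts, grepl("^A", .data$hap))
  expect_true(all(a_tracts$source == "B"))
  expect_equal(p1$truth$pulses$realized_alpha[nrow(p1$truth$pulses)], 1)

  expect_error(apply_admixture_pulse(sim$panel, sim$truth, "B", "A",
                                     alpha = 1.2, g = 10), "alpha")
  expect_error(apply_admixture_pulse(sim$panel, sim$truth, "Z", "A",
                                     alpha = 0.5, g = 10), "unknown source")
})

test_that("tracts tile each chromosome exactly after pulses", {
  sc <- demographic_scenario(
    tibble::tibble(label = c("A", "B"), n = 5, drift = 0.1),
    pulses = tibble::tibble(source = "B", recipient = "A",
                            alpha = c(0.3, 0.2), g = c(25, 10)),
    n_chrom = 3, chrom_cm = c(80, 100, 120), snps_per_chrom = 100, seed = 6)
  sim <- simulate_structured_panel(sc)
  cover <- sim$truth$tracts |>
    dplyr::group_by(.data$hap, .data$chrom) |>
    dplyr::summarise(len = sum(.data$end_cm - .data$start_cm),
                     gaps = all(abs(.data$start_cm[-1] -
                                      .data$end_cm[-dplyr::n()]) < 1e-9),
                     .groups = "drop") |>
    dplyr::left_join(sim$panel$map |>
                       dplyr::group_by(.data$chrom) |>
                       dplyr::summarise(L = max(.data$cm) - min(.data$cm)),
                     by = "chrom")
  expect_true(all(abs(cover$len - cover$L) < 1e-9))
  expect_true(all(cover$gaps))
})

test_that("pulse tract lengths are exponential with mean 100/g", {
  sc <- demographic_scenario(
    tibble::tibble(label = c("A", "B"), n = 30, drift = 0.05),
    n_chrom = 2, chrom_cm = 150, snps_per_chrom = 100, seed = 8)
  sim <- simulate_structured_panel(sc)
  g <- 30
  pul <- apply_admixture_pulse(sim$panel, sim$truth, "B", "A", alpha = 0.5,
                               g = g, seed = 11)
  tr <- dplyr::filter(pul$truth$tracts, grepl("^A", .data$hap))
  # interior segments only (the last segment of each chromosome is censored
  # at the map end)
  interior <- tr |>
    dplyr::group_by(.data$hap, .data$chrom) |>
    dplyr::filter(.data$end_cm < max(.data$end_cm)) |>
    dplyr::ungroup()
  lens <- interior$end_cm - interior$start_cm
  expect_gt(length(lens), 1000)
  expect_lt(abs(mean(lens) - 100 / g) / (100 / g), 0.1)
  ks <- suppressWarnings(stats::ks.test(lens, "pexp", rate = g / 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("realized admixture fraction converges to alpha (3 SE)", {
  sc <- demographic_scenario(
    tibble::tibble(label = c("A", "B"), n = c(100, 10), drift = 0.05),
    n_chrom = 2, chrom_cm = 150, snps_per_chrom = 80, seed = 12)
  sim <- simulate_structured_panel(sc)
  alpha <- 0.25
  pul <- apply_admixture_pulse(sim$panel, sim$truth, "B", "A", alpha = alpha,
                               g = 20, seed = 13)
  per_hap <- pul$truth$tracts |>
    dplyr::filter(grepl("^A", .data$hap)) |>
    dplyr::group_by(.data$hap) |>
    dplyr::summarise(f = sum((.data$end_cm - .data$start_cm) *
                               (.data$source == "B")) /
                       sum(.data$end_cm - .data$start_cm))
  se <- stats::sd(per_hap$f) / sqrt(nrow(per_hap))
  expect_lt(abs(mean(per_hap$f) - alpha), 3 * se + 1e-12)
  expect_lt(abs(pul$truth$pulses$realized_alpha[nrow(pul$truth$pulses)] - alpha),
            3 * se + 1e-12)
})

test_that("two-cluster cartoons are deterministic and carry both focal demes", {
  s1 <- simulate_two_cluster_scenario("split", seed = 2, n_per_deme = 14,
                                      snps_per_chrom = 80)
  s2 <- simulate_two_cluster_scenario("split", seed = 2, n_per_deme = 14,
                                      snps_per_chrom = 80)
  expect_identical(s1$panel$geno, s2$panel$geno)
  expect_setequal(s1$focal, c("alpha", "beta"))
  expect_true(all(c("alpha", "beta") %in% s1$panel$samples$group))
  expect_error(simulate_two_cluster_scenario("nope"), "arg")
})

test_that("geography assignment matches its kernel", {
  sc <- demographic_scenario(
    tibble::tibble(label = "A", n = 120, drift = 0.05, x_km = 50, y_km = -20,
                   dispersion_km = 5),
    snps_per_chrom = 20, seed = 14)
  sim <- simulate_structured_panel(sc)
  pan <- assign_geography(sim$panel, sc, seed = 15)
  d <- sqrt((pan$samples$gp1_x - 50)^2 + (pan$samples$gp1_y + 20)^2)
  rms <- sqrt(mean(d^2))
  expect_lt(abs(rms - 5 * sqrt(2)) / (5 * sqrt(2)), 0.15)

  # zero dispersion puts every grandparent at the centroid
  sc0 <- demographic_scenario(
    tibble::tibble(label = "A", n = 10, drift = 0.05, x_km = 1, y_km = 2,
                   dispersion_km = 0),
    snps_per_chrom = 20, seed = 16)
  sim0 <- simulate_structured_panel(sc0)
  pan0 <- assign_geography(sim0$panel, sc0, seed = 17)
  expect_true(all(pan0$samples$gp3_x == 1 & pan0$samples$gp3_y == 2))

  # distant-grandparent flagging is a seeded binomial draw
  pan2 <- assign_geography(sim$panel, sc, distant_fraction = 0.2,
                           distant_km = 300, seed = 18)
  n_far <- sum(pan2$samples$distant_gp)
  expect_gt(n_far, 120 * 0.2 - 3 * sqrt(120 * 0.2 * 0.8))
  expect_lt(n_far, 120 * 0.2 + 3 * sqrt(120 * 0.2 * 0.8))
})
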