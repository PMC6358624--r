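test_that("forward-backward matches brute-force path enumeration", {
  params <- copying_params(switch_rate = 0.3, miscopy = 0.05)
  for (seed in 1:4) {
    inst <- tiny_instance(seed, L = 5, D = 3)
    fb <- paint_expected_lengths(inst$recipient, inst$donors, inst$map, params)
    or <- oracle_paint(inst$recipient, inst$donors, inst$map, params)
    expect_lt(max(abs(fb - or)), 1e-8)
  }
  # multi-chromosome instance and a larger donor set
  inst <- tiny_instance(9, L = 6, D = 4, n_chrom = 2)
  fb <- paint_expected_lengths(inst$recipient, inst$donors, inst$map, params)
  or <- oracle_paint(inst$recipient, inst$donors, inst$map, params)
  expect_lt(max(abs(fb - or)), 1e-8)
})

test_that("expected chunk counts match brute-force enumeration", {
  params <- copying_params(switch_rate = 0.5, miscopy = 0.02)
  for (seed in 5:7) {
    inst <- tiny_instance(seed, L = 5, D = 3, n_chrom = seed %% 2 + 1)
    fb <- paint_expected_lengths(inst$recipient, inst$donors, inst$map,
                                 params, measure = "count")
    or <- oracle_paint(inst$recipient, inst$donors, inst$map, params,
                       measure = "count")
    expect_lt(max(abs(fb - or)), 1e-8)
  }
})

test_that("painting conserves map length and handles edge cases", {
  inst <- tiny_instance(11, L = 40, D = 6)
  params <- copying_params()
  v <- paint_expected_lengths(inst$recipient, inst$donors, inst$map, params)
  expect_lt(abs(sum(v) - map_length(inst$map)), 1e-8)

  # a single donor is forced to carry the full map
  v1 <- paint_expected_lengths(inst$recipient,
                               inst$donors[, 1, drop = FALSE],
                               inst$map, params)
  expect_equal(unname(v1), map_length(inst$map), tolerance = 1e-12)

  expect_error(paint_expected_lengths(inst$recipient,
                                      inst$donors[, integer(0)], inst$map,
                                      params), "donor")
  expect_error(paint_expected_lengths(inst$recipient[-1], inst$donors,
                                      inst$map, params), "mismatch")
})

test_that("an identical donor absorbs nearly all copied length", {
  set.seed(21)
  L <- 200
  map <- tibble::tibble(chrom = "chr1", bp = 1:L, cm = seq(0, 100, length.out = L))
  rec <- stats::rbinom(L, 1, 0.5)
  donors <- cbind(rec, 1 - rec)   # perfect match vs maximal mismatch
  v <- paint_expected_lengths(rec, donors, map,
                              copying_params(miscopy = 0.01))
  expect_gt(v[1] / sum(v), 0.99)
})

test_that("increasing donor identity never decreases copied length", {
  params <- copying_params()
  set.seed(22)
  for (rep in 1:5) {
    inst <- tiny_instance(30 + rep, L = 30, D = 4)
    v0 <- paint_expected_lengths(inst$recipient, inst$donors, inst$map, params)
    d2 <- inst$donors
    mism <- which(d2[, 2] != inst$recipient)
    if (!length(mism)) next
    fix <- mism[seq_len(ceiling(length(mism) / 2))]
    d2[fix, 2] <- inst$recipient[fix]
    v1 <- paint_expected_lengths(inst$recipient, d2, inst$map, params)
    expect_gte(v1[2], v0[2] - 1e-10)
  }
})

test_that("square coancestry conserves rows, zeroes the diagonal and is equivariant", {
  sim <- three_deme_sim()
  small <- panel_subset(sim$panel, sim$panel$samples$id[c(1:4, 21:24)])
  cmx <- coancestry_square(small)
  expect_true(all(abs(rowSums(cmx) / (2 * map_length(small$map)) - 1) < 1e-6))
  expect_true(all(diag(cmx) == 0))
  expect_true(all(cmx >= 0))

  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  cmx_p <- coancestry_square(panel_subset(small, small$samples$id[perm]))
  expect_equal(unclass(cmx_p), unclass(cmx)[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("near-identical individuals dominate each other's rows", {
  set.seed(31)
  L <- 400
  map <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = L / 2), bp = 1:L,
                        cm = rep(seq(0, 100, length.out = L / 2), 2))
  base <- stats::runif(L, 0.1, 0.9)
  geno <- matrix(stats::rbinom(L * 12, 1, base), L, 12)
  # individuals 1 and 2 nearly identical on both haplotypes
  geno[, 3] <- geno[, 1]; geno[, 4] <- geno[, 2]
  flip <- sample(L, 8)
  geno[flip, 3] <- 1L - geno[flip, 3]
  panel <- hap_panel(geno, map, tibble::tibble(id = paste0("i", 1:6)))
  cmx <- coancestry_square(panel)
  expect_equal(which.max(cmx[1, ]), c(i2 = 2L))
  expect_equal(which.max(cmx[2, ]), c(i1 = 1L))
})

test_that("restricted painting aggregates and conserves", {
  trio <- donor_trio()
  restr <- coancestry_restricted(trio$demes, trio$donors)
  ml <- 2 * map_length(trio$demes$map)
  expect_true(all(abs(rowSums(restr$X) / ml - 1) < 1e-6))
  expect_equal(unname(rowSums(restr$X_group)), unname(rowSums(restr$X)),
               tolerance = 1e-12)
  agg <- t(rowsum(t(restr$X), trio$donors$samples$group))
  expect_equal(unname(agg[, colnames(restr$X_group)]),
               unname(restr$X_group), tolerance = 1e-12)
  expect_error(coancestry_restricted(trio$demes, trio$demes), "overlap")
})

test_that("each recipient's top donor group is its own source pool", {
  sc <- demographic_scenario(
    demes = tibble::tibble(label = "mix", n = 4, drift = 0),
    donors = tibble::tibble(label = c("Q1", "Q2"), n = 10,
                            divergence = c(0.4, 0.45)),
    n_chrom = 2, snps_per_chrom = 300, seed = 41)
  sim <- simulate_structured_panel(sc)
  donors <- panel_subset(sim$panel,
                         sim$panel$samples$id[sim$panel$samples$role == "donor"])
  # recipients drawn from the pools themselves: 3 from each donor pool
  rec <- panel_subset(sim$panel, c(paste0("Q1_0", 1:3), paste0("Q2_0", 1:3)))
  rec$samples$id <- paste0("r", 1:6)
  colnames(rec$geno) <- hap_ids(rec$samples$id)
  restr <- coancestry_restricted(rec, donors)
  top <- colnames(restr$X_group)[apply(restr$X_group, 1, which.max)]
  expect_equal(top, c("Q1", "Q1", "Q1", "Q2", "Q2", "Q2"))
})

test_that("chromosome-level vectors add up exactly and track their maps", {
  trio <- donor_trio()
  ch <- chromosome_level_vectors(trio$demes, trio$donors, by = "group")
  restr <- coancestry_restricted(trio$demes, trio$donors)
  expect_equal(apply(ch, c(1, 2), sum), restr$X_group, tolerance = 1e-10,
               ignore_attr = TRUE)
  # single-chromosome genome: the chromosome slice is the total
  one <- trio$demes
  keep <- one$map$chrom == "chr1"
  one <- hap_panel(one$geno[keep, ], one$map[keep, ], one$samples)
  oned <- trio$donors
  oned <- hap_panel(oned$geno[keep, ], oned$map[keep, ], oned$samples)
  ch1 <- chromosome_level_vectors(one, oned, by = "group")
  expect_equal(dim(ch1)[3], 1L)
  r1 <- coancestry_restricted(one, oned)
  expect_equal(matrix(ch1[, , 1], dim(ch1)[1]), unname(r1$X_group),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("swapping chromosome maps swaps the chromosome vectors", {
  trio <- donor_trio()
  ch <- chromosome_level_vectors(trio$demes, trio$donors, by = "group")
  swap <- function(panel) {
    o <- order(match(panel$map$chrom, c("chr2", "chr1")))
    p <- hap_panel(panel$geno[o, ], dplyr::mutate(
      panel$map[o, ], chrom = rep(c("chr1", "chr2"),
                                  each = nrow(panel$map) / 2)),
      panel$samples)
    p
  }
  ch2 <- chromosome_level_vectors(swap(trio$demes), swap(trio$donors),
                                  by = "group")
  expect_equal(ch2[, , 1], ch[, , 2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ch2[, , 2], ch[, , 1], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("chunk counts rank donors like chunk lengths on structured panels", {
  trio <- donor_trio()
  len <- coancestry_restricted(trio$demes, trio$donors, measure = "length")
  cnt <- coancestry_restricted(trio$demes, trio$donors, measure = "count")
  rho <- stats::cor(as.vector(len$X), as.vector(cnt$X), method = "spearman")
  expect_gt(rho, 0.9)
})
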