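test_that("triplet loader mirrors counts and validates bin indices", {
  tf <- withr::local_tempfile()
  writeLines(c("0\t0\t4", "0\t1\t2"), tf)
  cm <- load_contacts(tf, n_bins = 2, mask_quantile = 0)
  expect_equal(cm$counts, matrix(c(4, 2, 2, 0), 2))

  writeLines("0\t0\t5", tf)
  cm1 <- load_contacts(tf, n_bins = 1, mask_quantile = 0)
  expect_equal(dim(cm1$counts), c(1L, 1L))

  writeLines("0\t5\t1", tf)
  expect_error(load_contacts(tf, n_bins = 3), "out of range")

  writeLines(c("0\t1\t2", "1\t0\t3"), tf)
  expect_warning(cm2 <- load_contacts(tf, n_bins = 2, mask_quantile = 0),
                 "summed")
  expect_equal(cm2$counts[1, 2], 5)

  expect_error(load_contacts(tf, n_bins = 2, format = "hdf5_container"),
               "triplet_tsv")
})

test_that("balancing reaches the equal-row-sum fixed point of the Sinkhorn oracle", {
  # an already doubly stochastic matrix is a fixed point
  ds <- matrix(c(0.5, 0.5, 0.5, 0.5), 2) / 1
  cm <- contact_matrix(ds, mask_quantile = 0)
  out <- kr_balance(cm)
  expect_equal(out$scaling, c(1, 1), tolerance = 1e-5)

  set.seed(1)
  for (n in c(3, 8, 20)) {
    m <- matrix(runif(n * n, 1, 10), n)
    m <- (m + t(m)) / 2
    cm <- contact_matrix(m, mask_quantile = 0)
    out <- kr_balance(cm, tol = 1e-8)
    rs <- rowSums(out$cm$counts)
    expect_lt(max(rs) / min(rs), 1 + 10 * 1e-8)
    want <- oracle_sinkhorn(m)
    got <- out$cm$counts / mean(rowSums(out$cm$counts))
    expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
  }

  # an all-zero row is masked, the remainder balances
  mz <- matrix(runif(16, 1, 5), 4); mz <- (mz + t(mz)) / 2
  mz[2, ] <- 0; mz[, 2] <- 0
  cmz <- contact_matrix(mz, mask_quantile = 0)
  outz <- kr_balance(cmz)
  expect_false(outz$cm$bins$valid[2])
  rs <- rowSums(outz$cm$counts[-2, -2])
  expect_lt(max(rs) / min(rs), 1 + 1e-4)
})

test_that("distance normalisation yields unit diagonals and the planted factor", {
  # Toeplitz input: every entry becomes 1
  n <- 8
  tp <- outer(1:n, 1:n, function(i, j) 10 / (1 + abs(i - j)))
  cm <- contact_matrix(tp, mask_quantile = 0)
  oe <- observed_expected(cm)
  expect_equal(unname(oe[is.finite(oe)]), rep(1, n * n), tolerance = 1e-12)

  # mean over each off-diagonal is 1 by construction
  set.seed(2)
  m <- matrix(runif(100, 1, 20), 10); m <- (m + t(m)) / 2
  oe2 <- observed_expected(contact_matrix(m, mask_quantile = 0))
  for (s in 0:9) {
    vals <- oe2[abs(row(oe2) - col(oe2)) == s]
    expect_equal(mean(vals), 1, tolerance = 1e-12)
  }

  # analytic checkerboard times decay: O/E equals the checkerboard factor
  # renormalised by its per-diagonal mean
  a <- c(1, 1, -1, -1, 1, -1, 1, -1)
  cfac <- 1 + 0.4 * outer(a, a)
  s <- pmax(abs(outer(1:8, 1:8, "-")), 1)
  m3 <- 100 * s^(-1) * cfac
  oe3 <- observed_expected(contact_matrix(m3, mask_quantile = 0))
  want <- cfac
  for (d in 0:7) {
    sel <- abs(row(want) - col(want)) == d
    want[sel] <- cfac[sel] / mean(cfac[sel])
  }
  expect_equal(oe3, want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("bin-pair correlation matches the textbook formula", {
  set.seed(3)
  m <- matrix(runif(36, 0.5, 2), 6); m <- (m + t(m)) / 2
  oe <- observed_expected(contact_matrix(m, mask_quantile = 0))
  cc <- pearson_correlation(oe)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(cc[i, j], oracle_pearson(oe[i, ], oe[j, ]),
                   tolerance = 1e-12)
    }
  }
  expect_equal(diag(cc), rep(1, 6), ignore_attr = TRUE)
  expect_error(pearson_correlation(oe[1:2, 1:2]), "too short")
})

test_that("PC1 recovers block structure and matches the dense spectral oracle", {
  # two-block checkerboard correlation: sign pattern equals the blocks
  blocks <- c(rep(1, 5), rep(-1, 5))
  corr <- outer(blocks, blocks)
  attr(corr, "bins") <- tibble::tibble(bin = 0:9, start = 0, end = 1,
                                       valid = TRUE)
  prof <- leading_eigenvector(corr)
  # the PC sign is arbitrary until oriented; the partition must match exactly
  expect_equal(sign(sign_align(blocks, prof$values)), blocks)
  expect_equal(sqrt(sum(prof$values^2)), 1, tolerance = 1e-12)

  # equivalence with the dense full-spectrum oracle up to sign
  set.seed(4)
  for (n in c(5, 12, 30, 50)) {
    x <- matrix(rnorm(n * 3 * n), 3 * n, n)
    corr <- stats::cor(x)
    prof <- leading_eigenvector(corr)
    want <- oracle_pc1(corr)
    expect_equal(prof$values, sign_align(prof$values, want),
                 tolerance = 1e-8)
    expect_gte(prof$explained_fraction, 0)
    expect_lte(prof$explained_fraction, 1)
  }

  # degenerate constant matrix is flagged and masked
  const <- matrix(1, 5, 5)
  expect_warning(pc <- leading_eigenvector(const), "degenerate")
  expect_true(all(!is.finite(pc$values)))
})

test_that("sign orientation follows the anchor and falls back to first-bin rule", {
  mkprof <- function(v) {
    structure(list(values = v,
                   bins = tibble::tibble(bin = seq_along(v) - 1L, start = 0,
                                         end = 1, valid = is.finite(v)),
                   scaffold = "s", bin_size = 1,
                   explained_fraction = 0.5, sign_anchor = "none"),
              class = "eigen_profile")
  }
  p <- mkprof(c(0.3, -0.4, 0.5))
  flipped <- orient_sign(p, mkprof(-p$values))
  expect_equal(flipped$values, -p$values)
  expect_equal(flipped$sign_anchor, "reference-correlation")

  neg <- orient_sign(mkprof(c(-0.3, 0.4, -0.5)))
  expect_equal(neg$values[1], 0.3)
  expect_equal(neg$sign_anchor, "first-bin-positive")

  # exactly zero correlation with the anchor -> fallback rule
  z <- mkprof(c(-1, 0, 1))
  anchor <- mkprof(c(1, 1, 1))  # sd zero -> cor undefined -> fallback
  zo <- suppressWarnings(orient_sign(z, anchor))
  expect_equal(zo$values[1], 1)  # first valid bin made non-negative

  noov <- mkprof(c(NA, NA, 0.5))
  anch2 <- mkprof(c(0.1, 0.2, NA))
  expect_warning(orient_sign(noov, anch2), "overlap")
})

test_that("the compartment pipeline is deterministic and recovers planted profiles", {
  cfg <- sim_config(chrom_lengths = 20e6, seed = 8)
  asm <- sim_rearrange(sim_genome(cfg), list())
  cm1 <- sim_hic(asm)[[1]]
  cm2 <- sim_hic(asm)[[1]]
  expect_identical(cm1$counts, cm2$counts)
  p1 <- hic_eigenvector(cm1)
  p2 <- hic_eigenvector(cm2)
  expect_identical(p1$values, p2$values)

  a <- attr(cm1, "planted_sign")
  ok <- is.finite(p1$values)
  expect_gte(abs(stats::cor(p1$values[ok], a[ok])), 0.8)
})
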