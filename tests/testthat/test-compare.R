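mk_profile <- function(values, scaffold = "s1", bin_size = 500e3) {
  n <- length(values)
  structure(list(values = values,
                 bins = tibble::tibble(bin = seq_len(n) - 1L,
                                       start = (seq_len(n) - 1) * bin_size,
                                       end = seq_len(n) * bin_size,
                                       valid = is.finite(values)),
                 scaffold = scaffold, bin_size = bin_size,
                 explained_fraction = 0.5, sign_anchor = "none"),
            class = "eigen_profile")
}

test_that("liftover through identity and whole-scaffold inverted HSBs", {
  v <- c(0.4, -0.2, 0.1, -0.5, 0.3, 0.2)
  p <- mk_profile(v)
  ident <- blk("chr1", 0, 3e6, "s1", 0, 3e6)
  lifted <- liftover_profile(p, ident)
  expect_equal(lifted$value, v)
  expect_false(any(lifted$was_inverted))

  # single whole-scaffold minus HSB: values reordered, never negated
  minus <- blk("chr1", 0, 3e6, "s1", 0, 3e6, orientation = "-")
  lifted_m <- liftover_profile(p, minus)
  expect_equal(lifted_m$value, rev(v))      # explicit index flip
  expect_true(all(lifted_m$was_inverted))

  # no HSB overlap -> empty with a warning
  expect_warning(out <- liftover_profile(mk_profile(v, "sX"), ident),
                 "no HSBs")
  expect_equal(nrow(out), 0)
})

test_that("fission truth splits a profile into partial lifts that concatenate", {
  cfg <- sim_config(chrom_lengths = 20e6, seed = 17)
  g <- sim_genome(cfg)
  asm <- sim_rearrange(g, list(list(kind = "fission", chrom = "chr1",
                                    pos = 8e6)))
  expect_equal(nrow(asm$scaffolds), 2)
  v <- sin(seq_len(40))
  lifted <- dplyr::bind_rows(
    liftover_profile(mk_profile(v[1:16], "s1"), asm$truth_blocks,
                     ref_lengths = c(chr1 = 20e6)),
    liftover_profile(mk_profile(v[17:40], "s2"), asm$truth_blocks,
                     ref_lengths = c(chr1 = 20e6)))
  got <- lifted$value[is.finite(lifted$value)][order(
    lifted$bin[is.finite(lifted$value)])]
  expect_equal(got, v)
})

test_that("round trip through rearrangement-free HSBs is the identity (r = 1)", {
  v <- rnorm(30)
  p <- mk_profile(v)
  hsb <- blk("chr1", 0, 15e6, "s1", 0, 15e6)
  lifted <- liftover_profile(p, hsb)
  ref <- tibble::tibble(ref_chrom = "chr1", bin = 0:29,
                        start = (0:29) * 5e5, end = (1:30) * 5e5, value = v)
  seg <- tibble::tibble(segment_id = 1L, tgt_scaffold = "s1",
                        ref_chrom = "chr1", ref_start = 0, ref_end = 15e6)
  sim <- segment_similarity(ref, lifted, seg, min_bins = 10)
  expect_equal(sim$r, 1, tolerance = 1e-12)
  expect_equal(sim$n_bins_compared, 30L)

  # negated target gives r = -1
  lifted_neg <- lifted
  lifted_neg$value <- -lifted_neg$value
  expect_equal(segment_similarity(ref, lifted_neg, seg)$r, -1,
               tolerance = 1e-12)

  # too few bins -> not assessed
  short <- segment_similarity(ref, lifted, seg, min_bins = 50)
  expect_false(short$assessed)
  expect_true(is.na(short$r))
})

test_that("noisy profiles land in the correlation band predicted by the noise model", {
  # z = x + eps with sd(eps) = 0.5 sd(x) gives population r = 1/sqrt(1.25)
  set.seed(99)
  rs <- replicate(100, {
    x <- rnorm(200)
    z <- x + rnorm(200, sd = 0.5 * stats::sd(x))
    stats::cor(x, z)
  })
  expect_gte(mean(rs), 0.85)
  expect_lte(mean(rs), 0.95)

  # the same band holds through the liftover + similarity machinery
  v <- rnorm(200)
  p <- mk_profile(v + rnorm(200, sd = 0.5 * stats::sd(v)))
  lifted <- liftover_profile(p, blk("chr1", 0, 100e6, "s1", 0, 100e6))
  ref <- tibble::tibble(ref_chrom = "chr1", bin = 0:199, value = v)
  seg <- tibble::tibble(segment_id = 1L, tgt_scaffold = "s1",
                        ref_chrom = "chr1", ref_start = 0, ref_end = 100e6)
  expect_gt(segment_similarity(ref, lifted, seg)$r, 0.75)
})

test_that("compartment shifts are runs of sign disagreement of minimum length", {
  n <- 10
  ref <- tibble::tibble(ref_chrom = "chr1", bin = 0:(n - 1),
                        start = (0:(n - 1)) * 5e5, end = (1:n) * 5e5,
                        value = rep(0.5, n))
  tgt <- ref
  tgt$value <- rep(0.5, n)
  expect_equal(nrow(call_compartment_shifts(ref, tgt)), 0)

  tgt$value[4:6] <- -0.5
  sh <- call_compartment_shifts(ref, tgt, min_run = 2, species = "sp")
  expect_equal(nrow(sh), 1)
  expect_equal(sh$n_bins, 3L)
  expect_equal(sh$direction, "A->B")
  expect_equal(c(sh$ref_start, sh$ref_end), c(3 * 5e5, 6 * 5e5))

  tgt$value <- rep(0.5, n)
  tgt$value[4] <- -0.5
  expect_equal(nrow(call_compartment_shifts(ref, tgt, min_run = 2)), 0)

  # B -> A direction follows the reference sign
  ref2 <- ref; ref2$value <- -0.5
  tgt2 <- ref; tgt2$value <- 0.5
  sh2 <- call_compartment_shifts(ref2, tgt2, min_run = 2)
  expect_equal(unique(sh2$direction), "B->A")
})

test_that("orient_to_reference flips anti-correlated lifted profiles", {
  v <- rnorm(40)
  lifted <- tibble::tibble(ref_chrom = "chr1", bin = 0:39, value = -v)
  ref <- tibble::tibble(ref_chrom = "chr1", bin = 0:39, value = v)
  out <- orient_to_reference(lifted, ref)
  expect_equal(out$value, v)
  # already aligned profiles are untouched
  out2 <- orient_to_reference(out, ref)
  expect_equal(out2$value, v)
})
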