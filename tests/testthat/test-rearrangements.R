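hsb3 <- function() {
  blk(c("chrA", "chrA", "chrB"), c(0, 2e6, 0), c(2e6, 4e6, 3e6),
      "s1", c(0, 2e6, 4e6), c(2e6, 4e6, 7e6),
      orientation = c("+", "-", "+"))
}

test_that("segment map groups runs of one reference chromosome along the target", {
  seg <- build_segment_map(hsb3())
  expect_equal(nrow(seg), 2)
  expect_equal(seg$ref_chrom, c("chrA", "chrB"))
  expect_equal(seg$order_index, c(1L, 2L))
  expect_equal(seg$orientation_majority, c("+", "+"))  # equal span tie -> +

  one <- blk("chrA", 0, 2e6, "s1", 0, 2e6)
  seg1 <- build_segment_map(one)
  expect_equal(nrow(seg1), 1)
  expect_equal(c(seg1$ref_start, seg1$ref_end), c(0, 2e6))

  expect_equal(nrow(build_segment_map(one[0, ])), 0)
})

test_that("fusion/fission counting follows the segment-count formula", {
  # identity map: each reference chromosome on its own scaffold
  ident <- build_segment_map(
    blk(c("chr1", "chr2"), 0, 5e6, c("s1", "s2"), 0, 5e6))
  ff <- count_fusions_fissions(ident, exclude = character())
  expect_equal(c(ff$n_fusions, ff$n_fissions), c(0L, 0L))

  # two reference chromosomes fused onto one scaffold
  fused <- build_segment_map(
    blk(c("chr1", "chr2"), 0, 5e6, "s1", c(0, 5e6), c(5e6, 10e6)))
  ff2 <- count_fusions_fissions(fused, exclude = character())
  expect_equal(c(ff2$n_fusions, ff2$n_fissions), c(1L, 0L))

  # X excluded by default
  withx <- build_segment_map(
    blk(c("chr1", "X"), 0, 5e6, c("s1", "sX"), 0, 5e6))
  expect_equal(count_fusions_fissions(withx)$n_segments, 1L)
})

test_that("inversions are maximal minority-orientation runs within a segment", {
  b <- blk("chrA", (0:4) * 1e6, (1:5) * 1e6, "s1", (0:4) * 1e6, (1:5) * 1e6,
           orientation = c("+", "+", "-", "-", "+"))
  ev <- detect_inversions(b, species = "sp")
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$ref_start, ev$ref_end), c(2e6, 4e6))
  expect_equal(ev$size, 2e6)

  expect_equal(nrow(detect_inversions(
    blk("chrA", c(0, 1e6), c(1e6, 2e6), "s1", c(0, 1e6), c(1e6, 2e6)))), 0)

  # whole segment minus: a strand assignment, not an inversion
  allm <- blk("chrA", (0:2) * 1e6, (1:3) * 1e6, "s1", (0:2) * 1e6,
              (1:3) * 1e6, orientation = "-")
  expect_equal(nrow(detect_inversions(allm)), 0)
})

test_that("inversion detection is orientation-symmetric", {
  cfg <- sim_config(chrom_lengths = c(22e6, 16e6), seed = 9)
  g <- sim_genome(cfg)
  for (s in 1:5) {
    ev <- sim_events_random(g, n_inversions = 3, seed = s)
    asm <- sim_rearrange(g, ev)
    h <- chain_blocks(asm$truth_blocks, 500e3)
    flipped <- h
    flipped$orientation <- ifelse(h$orientation == "+", "-", "+")
    expect_equal(nrow(detect_inversions(flipped)),
                 nrow(detect_inversions(h)))
  }
})

test_that("shared inversions collapse at 50% reciprocal overlap", {
  same <- tibble::tibble(
    kind = "inversion", species = c("a", "b"), ref_chrom = "chr1",
    ref_start = 1e6, ref_end = 2e6, tgt_scaffold = "s", tgt_start = 0,
    tgt_end = 1e6, size = 1e6)
  d <- dedupe_shared_inversions(same)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_carriers, 2L)
  expect_equal(d$carriers, "a,b")

  disjoint <- same
  disjoint$ref_start <- c(1e6, 5e6); disjoint$ref_end <- c(2e6, 6e6)
  expect_equal(nrow(dedupe_shared_inversions(disjoint)), 2)

  # 60% reciprocal overlap -> collapsed; verified against a direct
  # pairwise-overlap computation
  part <- same
  part$ref_start <- c(0, 0.4e6); part$ref_end <- c(1e6, 1.4e6)
  ov <- min((1e6 - 0.4e6) / 1e6, (1e6 - 0.4e6) / 1e6)
  expect_equal(ov, 0.6)
  expect_equal(nrow(dedupe_shared_inversions(part)), 1)

  # just under the threshold stays separate
  under <- same
  under$ref_start <- c(0, 0.6e6); under$ref_end <- c(1e6, 1.6e6)
  expect_equal(nrow(dedupe_shared_inversions(under)), 2)
})

test_that("summaries report planted counts, size classes and accounting", {
  cfg <- sim_config(chrom_lengths = c(30e6, 24e6, 18e6, 15e6), seed = 21)
  g <- sim_genome(cfg)
  ev <- sim_events_random(g, n_inversions = 3, n_fusions = 2, n_fissions = 1,
                          seed = 2)
  asm <- sim_rearrange(g, ev)
  h <- chain_blocks(asm$truth_blocks, 500e3)
  seg <- build_segment_map(h)
  seg$species <- "sim"
  events <- detect_inversions(h, species = "sim")
  summ <- summarize_rearrangements(events, seg, exclude = character())
  expect_equal(summ$per_species$n_inversions, 3L)
  expect_equal(summ$per_species$n_fusions, 2L)
  expect_equal(summ$per_species$n_fissions, 1L)
  expect_true(summ$accounting_ok)
  expect_s3_class(tidy(summ), "tbl_df")
  expect_equal(glance(summ)$n_inversions_total, 3L)

  # a single 1.5-Mb inversion does not enter the sub-1-Mb class
  one <- tibble::tibble(kind = "inversion", species = "z", ref_chrom = "c",
                        ref_start = 0, ref_end = 1.5e6, tgt_scaffold = "s",
                        tgt_start = 0, tgt_end = 1.5e6, size = 1.5e6)
  segz <- build_segment_map(blk("c", 0, 5e6, "s", 0, 5e6))
  segz$species <- "z"
  s2 <- summarize_rearrangements(one, segz, exclude = character())
  expect_equal(s2$per_species$n_inversions, 1L)
  expect_equal(s2$per_species$n_inversions_lt_1Mb, 0L)

  # no events -> all-zero summary
  s3 <- summarize_rearrangements(one[0, ], segz, exclude = character())
  expect_equal(s3$per_species$n_inversions, 0L)
})

test_that("an insertion translocation is flagged from non-colinear segments", {
  cfg <- sim_config(chrom_lengths = c(20e6, 16e6), seed = 13)
  g <- sim_genome(cfg)
  ev <- list(list(kind = "translocation", chrom = "chr1", start = 4e6,
                  end = 6e6, to_chrom = "chr2", to_pos = 8e6))
  asm <- sim_rearrange(g, ev)
  h <- chain_blocks(asm$truth_blocks, 500e3)
  seg <- build_segment_map(h)
  tr <- detect_translocations(seg, species = "sim")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$ref_chrom, "chr2")
})
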