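#' Lift a compartment profile onto reference coordinates
#'
#' Maps a target-species compartment profile onto the reference genome
#' through homologous synteny blocks. Each reference bin takes the value of
#' the target bin its midpoint maps to; a bin is lifted only when an HSB
#' covers at least half of it. Within minus-orientation HSBs the bin order is
#' reversed — values are reordered, not negated, because the A/B identity of
#' a locus does not depend on strand.
#'
#' @param profile `eigen_profile` for one target scaffold.
#' @param hsbs HSB tibble mapping that scaffold to the reference.
#' @param ref_lengths Named numeric vector of reference chromosome lengths
#'   (bp); defaults to the maximum HSB end per chromosome, rounded up to a
#'   whole bin.
#' @return A tibble (`lifted_profile`): `ref_chrom`, `bin`, `start`, `end`,
#'   `value`, `tgt_scaffold`, `tgt_bin`, `was_inverted`. Uncovered bins carry
#'   `NA` value.
#' @export
liftover_profile <- function(profile, hsbs, ref_lengths = NULL) {
  stopifnot(inherits(profile, "eigen_profile"))
  validate_blocks(hsbs, what = "synteny blocks")
  bs <- profile$bin_size
  hs <- filter(hsbs, .data$tgt_scaffold == profile$scaffold)
  if (nrow(hs) == 0) {
    warn(sprintf("no HSBs map scaffold %s to the reference", profile$scaffold))
    return(empty_lifted())
  }
  chroms <- unique(hs$ref_chrom)
  if (is.null(ref_lengths)) {
    ref_lengths <- vapply(chroms, function(ch) {
      ceiling(max(hs$ref_end[hs$ref_chrom == ch]) / bs) * bs
    }, double(1))
  }
  out <- purrr::map(chroms, function(ch) {
    nb <- ceiling(ref_lengths[[ch]] / bs)
    g <- tibble(ref_chrom = ch, bin = seq_len(nb) - 1L,
                start = (seq_len(nb) - 1) * bs,
                end = pmin(seq_len(nb) * bs, ref_lengths[[ch]]),
                value = NA_real_, tgt_scaffold = NA_character_,
                tgt_bin = NA_integer_, was_inverted = NA)
    hc <- filter(hs, .data$ref_chrom == ch)
    for (k in seq_len(nrow(hc))) {
      h <- hc[k, ]
      mid <- (g$start + g$end) / 2
      cover <- pmin(g$end, h$ref_end) - pmax(g$start, h$ref_start)
      hit <- which(mid >= h$ref_start & mid < h$ref_end &
                     cover >= 0.5 * (g$end - g$start))
      if (length(hit) == 0) next
      offs <- mid[hit] - h$ref_start
      tpos <- if (h$orientation == "+") h$tgt_start + offs
              else h$tgt_end - offs
      tbin <- pmin(pmax(floor(tpos / bs), 0), length(profile$values) - 1)
      g$value[hit] <- profile$values[tbin + 1L]
      g$tgt_scaffold[hit] <- profile$scaffold
      g$tgt_bin[hit] <- as.integer(tbin)
      g$was_inverted[hit] <- h$orientation == "-"
    }
    g
  }) |> bind_rows()
  class(out) <- c("lifted_profile", class(out))
  out
}

empty_lifted <- function() {
  out <- tibble(ref_chrom = character(), bin = integer(), start = double(),
                end = double(), value = double(), tgt_scaffold = character(),
                tgt_bin = integer(), was_inverted = logical())
  class(out) <- c("lifted_profile", class(out))
  out
}

#' Per-segment similarity of compartment profiles
#'
#' Pearson correlation between a reference profile and a lifted target
#' profile within each orthologous segment. Segments with fewer than
#' `min_bins` overlapping valid bins are reported but not assessed
#' (`r = NA`).
#'
#' @param ref_profile Tibble of per-bin reference values (`ref_chrom`, `bin`,
#'   `value`), e.g. `tidy()` of the reference `eigen_profile` renamed, or a
#'   lifted profile of the reference itself.
#' @param lifted_profile Lifted target profile from [liftover_profile()].
#' @param segments Segment tibble from [build_segment_map()] (reference
#'   coordinates in `ref_chrom`, `ref_start`, `ref_end`).
#' @param min_bins Minimum overlapping valid bins (default 10).
#' @return A tibble: segment columns plus `n_bins_compared`, `r`, `assessed`.
#' @export
segment_similarity <- function(ref_profile, lifted_profile, segments,
                               min_bins = 10) {
  joined <- dplyr::inner_join(
    select(as_tibble(ref_profile), "ref_chrom", "bin", ref_value = "value"),
    select(as_tibble(lifted_profile), "ref_chrom", "bin", tgt_value = "value"),
    by = c("ref_chrom", "bin"))
  purrr::map(seq_len(nrow(segments)), function(k) {
    seg <- segments[k, ]
    sub <- filter(joined, .data$ref_chrom == seg$ref_chrom,
                  .data$bin * bin_width(lifted_profile) >= seg$ref_start,
                  .data$bin * bin_width(lifted_profile) < seg$ref_end,
                  is.finite(.data$ref_value), is.finite(.data$tgt_value))
    nb <- nrow(sub)
    r <- if (nb >= min_bins) suppressWarnings(cor(sub$ref_value, sub$tgt_value))
         else NA_real_
    tibble(segment_id = seg$segment_id, tgt_scaffold = seg$tgt_scaffold,
           ref_chrom = seg$ref_chrom, ref_start = seg$ref_start,
           ref_end = seg$ref_end, n_bins_compared = nb, r = r,
           assessed = nb >= min_bins)
  }) |> bind_rows()
}

bin_width <- function(lifted) {
  w <- (lifted$end - lifted$start)
  if (length(w) == 0) return(1)
  max(w)
}

#' Call compartment shifts between two species
#'
#' Finds maximal runs of at least `min_run` consecutive reference bins where
#' the two sign-oriented profiles disagree in compartment sign. The shift
#' direction is read off the reference sign (positive = A by convention): a
#' bin that is A in the reference and B in the target is an `A->B` shift.
#'
#' @param ref_profile Per-bin reference tibble (`ref_chrom`, `bin`, `start`,
#'   `end`, `value`).
#' @param lifted_profile Lifted target tibble on the same bins.
#' @param min_run Minimum run length in bins (default 2, i.e. 1 Mb at 500-kb
#'   bins).
#' @param species Optional species label.
#' @return A tibble of shifts: `ref_chrom`, `ref_start`, `ref_end`,
#'   `species`, `direction`, `n_bins`.
#' @export
call_compartment_shifts <- function(ref_profile, lifted_profile, min_run = 2,
                                    species = NA_character_) {
  joined <- dplyr::inner_join(
    select(as_tibble(ref_profile), "ref_chrom", "bin", "start", "end",
           ref_value = "value"),
    select(as_tibble(lifted_profile), "ref_chrom", "bin", tgt_value = "value"),
    by = c("ref_chrom", "bin")) |>
    arrange(.data$ref_chrom, .data$bin)
  out <- list()
  for (ch in unique(joined$ref_chrom)) {
    g <- filter(joined, .data$ref_chrom == ch)
    disagree <- is.finite(g$ref_value) & is.finite(g$tgt_value) &
      sign(g$ref_value) != sign(g$tgt_value) &
      g$ref_value != 0 & g$tgt_value != 0
    runs <- true_runs(disagree)
    runs <- filter(runs, .data$end - .data$start + 1 >= min_run)
    for (r in seq_len(nrow(runs))) {
      i0 <- runs$start[r]; i1 <- runs$end[r]
      # contiguity in bin index required within a run
      bins <- g$bin[i0:i1]
      if (any(diff(bins) != 1)) next
      out[[length(out) + 1L]] <- tibble(
        ref_chrom = ch, ref_start = g$start[i0], ref_end = g$end[i1],
        species = species,
        direction = if (g$ref_value[i0] > 0) "A->B" else "B->A",
        n_bins = i1 - i0 + 1L)
    }
  }
  if (length(out) == 0) {
    return(tibble(ref_chrom = character(), ref_start = double(),
                  ref_end = double(), species = character(),
                  direction = character(), n_bins = integer()))
  }
  bind_rows(out)
}

#' Orient a lifted profile against the reference
#'
#' A compartment profile's sign is arbitrary until anchored; after liftover
#' the natural anchor is the reference profile over the shared bins. Flips
#' the lifted values when their Pearson correlation with the reference is
#' negative; a zero or undefined correlation leaves the profile unchanged.
#'
#' @param lifted_profile Lifted tibble from [liftover_profile()].
#' @param ref_profile Per-bin reference tibble (`ref_chrom`, `bin`, `value`).
#' @return The lifted tibble, sign-anchored to the reference.
#' @export
orient_to_reference <- function(lifted_profile, ref_profile) {
  joined <- dplyr::inner_join(
    select(as_tibble(ref_profile), "ref_chrom", "bin", ref_value = "value"),
    select(as_tibble(lifted_profile), "ref_chrom", "bin",
           tgt_value = "value"),
    by = c("ref_chrom", "bin"))
  ok <- is.finite(joined$ref_value) & is.finite(joined$tgt_value)
  if (sum(ok) >= 2) {
    r <- suppressWarnings(cor(joined$ref_value[ok], joined$tgt_value[ok]))
    if (is.finite(r) && r < 0) lifted_profile$value <- -lifted_profile$value
  }
  lifted_profile
}
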