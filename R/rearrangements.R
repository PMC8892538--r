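#' Group synteny blocks into segments along each target scaffold
#'
#' Orders HSBs along each target scaffold and merges consecutive runs that
#' share a reference chromosome (regardless of orientation) into segments —
#' the orthologous subchromosomal fragments that the orthology table is built
#' from. The majority orientation of each segment is the orientation carrying
#' the larger total reference span.
#'
#' @param hsbs HSB tibble from [chain_blocks()] (one species pair).
#' @return A tibble of segments with columns `segment_id`, `tgt_scaffold`,
#'   `order_index` (position along the target), `ref_chrom`, `ref_start`,
#'   `ref_end`, `tgt_start`, `tgt_end`, `orientation_majority`, `n_hsbs`.
#' @export
build_segment_map <- function(hsbs) {
  validate_blocks(hsbs, what = "synteny blocks")
  if (nrow(hsbs) == 0) {
    return(tibble(segment_id = integer(), tgt_scaffold = character(),
                  order_index = integer(), ref_chrom = character(),
                  ref_start = double(), ref_end = double(),
                  tgt_start = double(), tgt_end = double(),
                  orientation_majority = character(), n_hsbs = integer()))
  }
  hsbs |>
    arrange(.data$tgt_scaffold, .data$tgt_start) |>
    group_by(.data$tgt_scaffold) |>
    mutate(.run = cumsum(c(TRUE, .data$ref_chrom[-1] !=
                             .data$ref_chrom[-n()]))) |>
    group_by(.data$tgt_scaffold, .data$.run) |>
    summarise(
      ref_chrom = first(.data$ref_chrom),
      orientation_majority = majority_orientation(.data$orientation,
                                                  .data$ref_end - .data$ref_start),
      ref_start = min(.data$ref_start), ref_end = max(.data$ref_end),
      tgt_start = min(.data$tgt_start), tgt_end = max(.data$tgt_end),
      n_hsbs = n(), .groups = "drop_last"
    ) |>
    mutate(order_index = row_number()) |>
    ungroup() |>
    mutate(segment_id = row_number()) |>
    select("segment_id", "tgt_scaffold", "order_index", "ref_chrom",
           "ref_start", "ref_end", "tgt_start", "tgt_end",
           "orientation_majority", "n_hsbs")
}

majority_orientation <- function(orientation, weight) {
  plus <- sum(weight[orientation == "+"])
  minus <- sum(weight[orientation == "-"])
  if (plus >= minus) "+" else "-"
}

#' Count chromosome fusions and fissions from a segment map
#'
#' With `N_seg` segments spanning `N_tgt` distinct target scaffolds and
#' `N_ref` distinct reference chromosomes, the number of fusion junctions is
#' `N_seg - N_tgt` and the number of fissions is `N_seg - N_ref`. Restrict
#' the segment map to autosomes before calling when the sex chromosome is
#' handled separately (see `exclude`).
#'
#' The chromosome-count identity `N_tgt = N_ref - n_fusions + n_fissions`
#' holds by construction; for the red fox versus dog the printed accounting
#' is 38 autosomes - 26 fusions + 4 fissions = 16 autosomal scaffolds.
#'
#' @param segments Segment tibble from [build_segment_map()].
#' @param exclude Reference chromosomes to drop before counting
#'   (default `"X"`).
#' @return A tibble with one row: `n_fusions`, `n_fissions`, `n_segments`,
#'   `n_tgt_scaffolds`, `n_ref_chroms`.
#' @export
count_fusions_fissions <- function(segments, exclude = "X") {
  seg <- filter(segments, !(.data$ref_chrom %in% exclude))
  n_seg <- nrow(seg)
  n_tgt <- dplyr::n_distinct(seg$tgt_scaffold)
  n_ref <- dplyr::n_distinct(seg$ref_chrom)
  fus <- n_seg - n_tgt
  fis <- n_seg - n_ref
  if (n_seg > 0 && (fus < 0 || fis < 0)) {
    abort("segment map malformed: negative fusion/fission count")
  }
  tibble(n_fusions = fus, n_fissions = fis, n_segments = n_seg,
         n_tgt_scaffolds = n_tgt, n_ref_chroms = n_ref)
}

#' Detect inversions within segments
#'
#' Within each segment, a maximal run of HSBs whose orientation is opposite
#' to the segment's majority orientation is called as one inversion; its size
#' is the reference span of the run. A segment whose every HSB is `-`
#' oriented is a whole-fragment strand assignment, not an inversion.
#'
#' @param hsbs HSB tibble for one species pair.
#' @param min_size Minimum inversion size in bp (default 0; the sub-1-Mb size
#'   class is computed in [summarize_rearrangements()]).
#' @param species Optional species label stamped on the events.
#' @return A tibble of inversion events: `kind`, `species`, `ref_chrom`,
#'   `ref_start`, `ref_end`, `tgt_scaffold`, `tgt_start`, `tgt_end`, `size`.
#' @export
detect_inversions <- function(hsbs, min_size = 0, species = NA_character_) {
  validate_blocks(hsbs, what = "synteny blocks")
  segments <- build_segment_map(hsbs)
  if (nrow(segments) == 0) return(empty_events())
  hs <- arrange(hsbs, .data$tgt_scaffold, .data$tgt_start)
  out <- list()
  for (k in seq_len(nrow(segments))) {
    seg <- segments[k, ]
    in_seg <- hs$tgt_scaffold == seg$tgt_scaffold &
      hs$tgt_start >= seg$tgt_start & hs$tgt_end <= seg$tgt_end &
      hs$ref_chrom == seg$ref_chrom
    blocks <- hs[in_seg, ]
    if (nrow(blocks) == 0) next
    runs <- true_runs(blocks$orientation != seg$orientation_majority)
    for (r in seq_len(nrow(runs))) {
      rb <- blocks[runs$start[r]:runs$end[r], ]
      size <- max(rb$ref_end) - min(rb$ref_start)
      if (size < min_size) next
      out[[length(out) + 1L]] <- tibble(
        kind = "inversion", species = species,
        ref_chrom = seg$ref_chrom,
        ref_start = min(rb$ref_start), ref_end = max(rb$ref_end),
        tgt_scaffold = seg$tgt_scaffold,
        tgt_start = min(rb$tgt_start), tgt_end = max(rb$tgt_end),
        size = size)
    }
  }
  if (length(out) == 0) return(empty_events())
  bind_rows(out)
}

#' Detect intra-scaffold translocations
#'
#' Flags reference chromosomes whose segments appear non-colinearly within a
#' single target scaffold — i.e. one reference chromosome contributes two or
#' more separate segments to the same scaffold, interleaved with material
#' from other chromosomes (as in the internal rearrangement of one red fox
#' scaffold reported relative to dog).
#'
#' @param segments Segment tibble from [build_segment_map()].
#' @param species Optional species label.
#' @return A tibble of translocation events (one per extra segment beyond the
#'   first per `(tgt_scaffold, ref_chrom)` pair), same columns as
#'   [detect_inversions()].
#' @export
detect_translocations <- function(segments, species = NA_character_) {
  if (nrow(segments) == 0) return(empty_events())
  dup <- segments |>
    group_by(.data$tgt_scaffold, .data$ref_chrom) |>
    filter(n() > 1) |>
    arrange(.data$tgt_start, .by_group = TRUE) |>
    slice(-1) |>
    ungroup()
  if (nrow(dup) == 0) return(empty_events())
  tibble(kind = "translocation", species = species,
         ref_chrom = dup$ref_chrom, ref_start = dup$ref_start,
         ref_end = dup$ref_end, tgt_scaffold = dup$tgt_scaffold,
         tgt_start = dup$tgt_start, tgt_end = dup$tgt_end,
         size = dup$ref_end - dup$ref_start)
}

empty_events <- function() {
  tibble(kind = character(), species = character(), ref_chrom = character(),
         ref_start = double(), ref_end = double(), tgt_scaffold = character(),
         tgt_start = double(), tgt_end = double(), size = double())
}

#' Collapse inversions shared between species
#'
#' Inversions from different species whose reference intervals reciprocally
#' overlap by at least `min_reciprocal` are collapsed into one shared event
#' listing all carrier species. Collapsing is transitive (connected
#' components of the overlap graph).
#'
#' @param events Inversion-event tibble pooled across species (reference
#'   coordinates must be comparable).
#' @param min_reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return A tibble with one row per deduplicated event: reference interval
#'   (union over members), `carriers` (comma-separated species),
#'   `n_carriers`, `size`.
#' @export
dedupe_shared_inversions <- function(events, min_reciprocal = 0.5) {
  ev <- filter(events, .data$kind == "inversion")
  m <- nrow(ev)
  if (m == 0) {
    return(tibble(ref_chrom = character(), ref_start = double(),
                  ref_end = double(), carriers = character(),
                  n_carriers = integer(), size = double()))
  }
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (ev$ref_chrom[i] != ev$ref_chrom[j]) next
      ov <- reciprocal_overlap(ev$ref_start[i], ev$ref_end[i],
                               ev$ref_start[j], ev$ref_end[j])
      if (ov >= min_reciprocal) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  ev$.comp <- vapply(seq_len(m), find, integer(1))
  ev |>
    group_by(.data$.comp) |>
    summarise(ref_chrom = first(.data$ref_chrom),
              ref_start = min(.data$ref_start),
              ref_end = max(.data$ref_end),
              carriers = paste(sort(unique(.data$species)), collapse = ","),
              n_carriers = dplyr::n_distinct(.data$species),
              .groups = "drop") |>
    mutate(size = .data$ref_end - .data$ref_start) |>
    select(-".comp")
}

#' Summarise rearrangements per species
#'
#' Per-species inversion / fusion / fission / translocation counts with the
#' sub-1-Mb inversion size class, the pooled deduplicated inversion count,
#' and the karyotype accounting check
#' `N_tgt = N_ref - n_fusions + n_fissions`.
#'
#' @param events Pooled event tibble (all species, reference coordinates).
#' @param segments Either one segment tibble with a `species` column or a
#'   named list of per-species segment tibbles.
#' @param exclude Reference chromosomes excluded from fusion/fission
#'   accounting (default `"X"`).
#' @return An object of class `rearrangement_summary`: a list with
#'   `per_species` (tibble), `n_shared_dedup` (deduplicated inversion count)
#'   and `accounting_ok` (logical).
#' @export
summarize_rearrangements <- function(events, segments, exclude = "X") {
  if (is.data.frame(segments)) {
    if (!"species" %in% names(segments)) {
      abort("segments must carry a species column or be a named list")
    }
    segments <- split(segments, segments$species)
  }
  per <- purrr::imap(segments, function(seg, sp) {
    ff <- count_fusions_fissions(seg, exclude = exclude)
    ev <- filter(events, .data$species == sp)
    inv <- filter(ev, .data$kind == "inversion")
    tibble(species = sp,
           n_inversions = nrow(inv),
           n_inversions_lt_1Mb = sum(inv$size < 1e6),
           n_fusions = ff$n_fusions, n_fissions = ff$n_fissions,
           n_translocations = sum(ev$kind == "translocation"),
           n_tgt_scaffolds = ff$n_tgt_scaffolds,
           n_ref_chroms = ff$n_ref_chroms)
  }) |> bind_rows()
  ok <- all(per$n_tgt_scaffolds ==
              per$n_ref_chroms - per$n_fusions + per$n_fissions)
  if (!ok) warn("karyotype accounting identity violated")
  out <- list(per_species = per,
              n_shared_dedup = nrow(dedupe_shared_inversions(events)),
              accounting_ok = ok)
  class(out) <- "rearrangement_summary"
  out
}

#' @export
print.rearrangement_summary <- function(x, ...) {
  cat("Rearrangement summary (", nrow(x$per_species), " species)\n", sep = "")
  print(x$per_species)
  cat("Deduplicated shared inversions:", x$n_shared_dedup, "\n")
  cat("Karyotype accounting:", if (x$accounting_ok) "OK" else "VIOLATED", "\n")
  invisible(x)
}

#' @rdname summarize_rearrangements
#' @param x A `rearrangement_summary`.
#' @param ... Unused.
#' @method tidy rearrangement_summary
#' @export
tidy.rearrangement_summary <- function(x, ...) x$per_species

#' @rdname summarize_rearrangements
#' @method glance rearrangement_summary
#' @export
glance.rearrangement_summary <- function(x, ...) {
  tibble(n_species = nrow(x$per_species),
         n_inversions_total = sum(x$per_species$n_inversions),
         n_shared_dedup = x$n_shared_dedup,
         accounting_ok = x$accounting_ok)
}
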