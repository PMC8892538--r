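#' Chain alignment blocks into homologous synteny blocks
#'
#' Greedy colinear chaining at a configurable resolution. Blocks sharing
#' `(ref_chrom, tgt_scaffold, orientation)` are merged into one homologous
#' synteny block (HSB) when they are consistent with the diagonal order on
#' both genomes (target coordinates increase with reference coordinates for
#' `+` blocks, decrease for `-` blocks) and the inter-block gap is smaller
#' than `resolution` on both genomes. Merged blocks whose span is below
#' `resolution` on either genome are discarded. Where surviving HSBs overlap
#' on the reference, the block with the longer reference span wins and the
#' other is trimmed.
#'
#' When a block could extend more than one open chain, the chain with the
#' larger accumulated reference span is extended; ties go to the chain with
#' the smaller reference start.
#'
#' @param blocks Alignment-block tibble (see [read_blocks()]).
#' @param resolution Minimum HSB span and maximum chaining gap, in bp.
#' @return A tibble of HSBs sorted by `(ref_chrom, ref_start)` with columns
#'   `id`, the seven block columns, `resolution` and `n_source_blocks`.
#' @examples
#' b <- tibble::tibble(
#'   ref_chrom = "chr1", ref_start = c(0, 150e3), ref_end = c(100e3, 400e3),
#'   tgt_scaffold = "s1", tgt_start = c(0, 150e3), tgt_end = c(100e3, 400e3),
#'   orientation = "+"
#' )
#' chain_blocks(b, resolution = 300e3)
#' @export
chain_blocks <- function(blocks, resolution = 300000) {
  validate_blocks(blocks)
  if (resolution <= 0) abort("resolution must be positive")
  if (nrow(blocks) == 0) return(empty_hsbs(resolution))

  groups <- blocks |>
    mutate(.grp = paste(.data$ref_chrom, .data$tgt_scaffold,
                        .data$orientation, sep = "\r")) |>
    dplyr::group_split(.data$.grp, .keep = FALSE)

  chains <- purrr::map(groups, chain_group, resolution = resolution) |>
    bind_rows()
  if (nrow(chains) == 0) return(empty_hsbs(resolution))

  # min-span filter on both genomes
  chains <- filter(chains,
                   .data$ref_end - .data$ref_start >= resolution,
                   .data$tgt_end - .data$tgt_start >= resolution)
  if (nrow(chains) == 0) return(empty_hsbs(resolution))

  chains <- resolve_ref_overlaps(chains, resolution)

  chains |>
    arrange(.data$ref_chrom, .data$ref_start) |>
    mutate(id = row_number(), resolution = resolution) |>
    select("id", dplyr::all_of(block_cols), "resolution", "n_source_blocks")
}

# Chain one (ref_chrom, tgt_scaffold, orientation) group. Multiple chains may
# be open at once (e.g. interleaved copies); each block extends the best
# compatible open chain or starts a new one.
chain_group <- function(g, resolution) {
  g <- arrange(g, .data$ref_start, .data$tgt_start)
  plus <- g$orientation[1] == "+"
  chains <- list()  # each: list(ref_start, ref_end, tgt_start, tgt_end, n)
  for (k in seq_len(nrow(g))) {
    b <- g[k, ]
    compat <- which(vapply(chains, function(ch) {
      ref_gap <- b$ref_start - ch$ref_end
      if (ref_gap >= resolution || b$ref_start < ch$ref_start) return(FALSE)
      if (plus) {
        tgt_gap <- b$tgt_start - ch$tgt_end
        tgt_gap < resolution && b$tgt_end > ch$tgt_end && b$tgt_start >= ch$tgt_start
      } else {
        tgt_gap <- ch$tgt_start - b$tgt_end
        tgt_gap < resolution && b$tgt_start < ch$tgt_start && b$tgt_end <= ch$tgt_end
      }
    }, logical(1)))
    if (length(compat) == 0) {
      chains[[length(chains) + 1L]] <- list(
        ref_start = b$ref_start, ref_end = b$ref_end,
        tgt_start = b$tgt_start, tgt_end = b$tgt_end, n = 1L)
    } else {
      spans <- vapply(chains[compat],
                      function(ch) ch$ref_end - ch$ref_start, double(1))
      starts <- vapply(chains[compat], function(ch) ch$ref_start, double(1))
      pick <- compat[order(-spans, starts)[1]]
      ch <- chains[[pick]]
      ch$ref_end <- max(ch$ref_end, b$ref_end)
      ch$tgt_start <- min(ch$tgt_start, b$tgt_start)
      ch$tgt_end <- max(ch$tgt_end, b$tgt_end)
      ch$n <- ch$n + 1L
      chains[[pick]] <- ch
    }
  }
  purrr::map(chains, \(ch) tibble(
    ref_chrom = g$ref_chrom[1], ref_start = ch$ref_start, ref_end = ch$ref_end,
    tgt_scaffold = g$tgt_scaffold[1], tgt_start = ch$tgt_start,
    tgt_end = ch$tgt_end, orientation = g$orientation[1],
    n_source_blocks = ch$n)) |>
    bind_rows()
}

# Keep the longer ref-span block where two HSBs overlap on the reference;
# trim the shorter against every kept interval, dropping it if nothing is left.
resolve_ref_overlaps <- function(chains, resolution) {
  out <- list()
  for (chrom in unique(chains$ref_chrom)) {
    cc <- chains |>
      filter(.data$ref_chrom == chrom) |>
      arrange(desc(.data$ref_end - .data$ref_start), .data$ref_start)
    kept <- list()
    for (k in seq_len(nrow(cc))) {
      b <- cc[k, ]
      for (kb in kept) {
        if (b$ref_start >= kb$ref_end || b$ref_end <= kb$ref_start) next
        # overlap: trim the side that intrudes
        if (b$ref_start >= kb$ref_start && b$ref_end <= kb$ref_end) {
          b$ref_end <- b$ref_start  # fully contained -> dropped
        } else if (b$ref_start < kb$ref_start) {
          b$ref_end <- min(b$ref_end, kb$ref_start)
        } else {
          b$ref_start <- max(b$ref_start, kb$ref_end)
        }
        if (b$ref_end <= b$ref_start) break
      }
      if (b$ref_end > b$ref_start) kept[[length(kept) + 1L]] <- b
    }
    out <- c(out, kept)
  }
  bind_rows(out)
}

empty_hsbs <- function(resolution) {
  tibble(id = integer(), ref_chrom = character(), ref_start = double(),
         ref_end = double(), tgt_scaffold = character(), tgt_start = double(),
         tgt_end = double(), orientation = character(),
         resolution = double(), n_source_blocks = integer())
}
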