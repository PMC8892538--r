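with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic genome and Hi-C generator. Defaults emulate
#' the data regime the package targets: 500-kb compartment bins, generic
#' polymer contact decay (exponent 1), a moderate checkerboard strength and
#' enough reads on the diagonal band for reliable compartment recovery.
#'
#' @param chrom_lengths Chromosome lengths in bp (each at least
#'   `4 * bin_size`).
#' @param bin_size Compartment bin size in bp (default 500 kb).
#' @param decay_exponent Power-law contact decay exponent (default 1.0).
#' @param compartment_strength Checkerboard strength `c` in `[0, 1)`
#'   (default 0.3).
#' @param reads_per_bin Expected read count per bin pair at distance one bin
#'   (default 50).
#' @param mean_block_bins Mean compartment block length in bins (default 8).
#' @param seed Integer seed; every draw is reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(30e6, 24e6, 18e6),
                       bin_size = 500000, decay_exponent = 1.0,
                       compartment_strength = 0.3, reads_per_bin = 50,
                       mean_block_bins = 8, seed = 1) {
  if (any(chrom_lengths < 4 * bin_size)) {
    abort("chromosome lengths must be at least 4 * bin_size")
  }
  if (compartment_strength < 0 || compartment_strength >= 1) {
    abort("compartment_strength must be in [0, 1)")
  }
  structure(list(chrom_lengths = chrom_lengths, bin_size = bin_size,
                 decay_exponent = decay_exponent,
                 compartment_strength = compartment_strength,
                 reads_per_bin = reads_per_bin,
                 mean_block_bins = mean_block_bins, seed = seed),
            class = "sim_config")
}

#' Simulate an ancestral genome with a planted compartment profile
#'
#' Chromosomes are tiled with bins of `bin_size`; the planted two-state
#' compartment profile alternates sign in blocks whose lengths are geometric
#' with mean `mean_block_bins`.
#'
#' @param config A [sim_config()].
#' @return A `sim_genome` list: `chroms` (tibble `chrom`, `length`,
#'   `n_bins`), `profile` (tibble `chrom`, `bin`, `start`, `end`, `sign`),
#'   and the config.
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    chroms <- tibble(chrom = paste0("chr", seq_along(config$chrom_lengths)),
                     length = as.numeric(config$chrom_lengths),
                     n_bins = ceiling(config$chrom_lengths / config$bin_size))
    profile <- purrr::pmap(chroms, function(chrom, length, n_bins) {
      signs <- numeric(n_bins)
      cur <- sample(c(-1, 1), 1)
      i <- 1
      while (i <= n_bins) {
        len <- 1 + rgeom(1, 1 / config$mean_block_bins)
        j <- min(i + len - 1, n_bins)
        signs[i:j] <- cur
        cur <- -cur
        i <- j + 1
      }
      tibble(chrom = chrom, bin = seq_len(n_bins) - 1L,
             start = (seq_len(n_bins) - 1) * config$bin_size,
             end = pmin(seq_len(n_bins) * config$bin_size, length),
             sign = signs)
    }) |> bind_rows()
    structure(list(chroms = chroms, profile = profile, config = config),
              class = "sim_genome")
  })
}

# ---- rearrangement machinery -------------------------------------------------
# A scaffold is a list of pieces; each piece is (chrom, start, end, strand)
# in ancestor coordinates. Events operate on the evolving scaffold list.

genome_to_scaffolds <- function(genome) {
  purrr::pmap(genome$chroms, function(chrom, length, n_bins) {
    list(pieces = tibble(chrom = chrom, start = 0, end = length,
                         strand = "+"))
  })
}

piece_lengths <- function(pieces) pieces$end - pieces$start

# locate ancestor position pos of chrom inside a scaffold list; returns
# (scaffold index, piece index, offset from piece start in ancestor coords)
locate <- function(scaffolds, chrom, pos) {
  for (si in seq_along(scaffolds)) {
    p <- scaffolds[[si]]$pieces
    hit <- which(p$chrom == chrom & p$start <= pos & pos < p$end)
    if (length(hit) == 1) return(list(si = si, pi = hit))
    if (length(hit) > 1) abort("ambiguous locate: duplicated ancestor material")
  }
  abort(sprintf("position %s:%g not found in any scaffold", chrom, pos))
}

# split the piece containing (chrom, pos) so pos becomes a piece boundary
split_at <- function(scaffolds, chrom, pos) {
  loc <- locate(scaffolds, chrom, pos)
  p <- scaffolds[[loc$si]]$pieces
  pc <- p[loc$pi, ]
  if (pos == pc$start || pos == pc$end) return(scaffolds)
  left <- pc; right <- pc
  left$end <- pos; right$start <- pos
  parts <- if (pc$strand == "+") bind_rows(left, right)
           else bind_rows(right, left)
  scaffolds[[loc$si]]$pieces <- bind_rows(
    if (loc$pi > 1) p[seq_len(loc$pi - 1), ],
    parts,
    if (loc$pi < nrow(p)) p[seq(loc$pi + 1, nrow(p)), ])
  scaffolds
}

rev_pieces <- function(pieces) {
  out <- pieces[rev(seq_len(nrow(pieces))), ]
  out$strand <- ifelse(out$strand == "+", "-", "+")
  out
}

#' Apply a rearrangement history to a simulated genome
#'
#' Events are applied sequentially to the evolving scaffold set. Supported
#' kinds (ancestor coordinates):
#'
#' * `inversion`: `list(kind, chrom, start, end)` — reverse the interval.
#' * `fission`: `list(kind, chrom, pos)` — split the scaffold carrying
#'   `chrom:pos` at that point.
#' * `fusion`: `list(kind, chrom_a, chrom_b, reverse_b = FALSE)` — join the
#'   scaffold whose first piece starts chromosome `chrom_a` material to the
#'   one carrying `chrom_b` (optionally flipped).
#' * `translocation`: `list(kind, chrom, start, end, to_chrom, to_pos)` —
#'   excise the interval and insert it at `to_chrom:to_pos`.
#'
#' Breakpoints closer than `2 * bin_size` to each other or to a chromosome
#' end are rejected, which guarantees that every conserved segment spans at
#' least two compartment bins.
#'
#' @param genome A [sim_genome()].
#' @param events List of event lists (see above), e.g. from
#'   [sim_events_random()].
#' @return A `sim_assembly` list: `scaffolds` (tibble `scaffold`, `length`),
#'   `truth_blocks` (alignment-block tibble, target vs ancestor),
#'   `events_applied` (tibble of the planted events), `pieces`, `genome`.
#' @export
sim_rearrange <- function(genome, events = list()) {
  stopifnot(inherits(genome, "sim_genome"))
  check_event_spacing(genome, events)
  scaffolds <- genome_to_scaffolds(genome)
  for (ev in events) {
    kind <- ev$kind
    if (kind == "inversion") {
      scaffolds <- split_at(scaffolds, ev$chrom, ev$start)
      scaffolds <- split_at(scaffolds, ev$chrom, ev$end)
      si <- locate(scaffolds, ev$chrom, ev$start)$si
      p <- scaffolds[[si]]$pieces
      inside <- which(p$chrom == ev$chrom & p$start >= ev$start &
                        p$end <= ev$end)
      if (length(inside) == 0) abort("inversion interval not found intact")
      rng <- range(inside)
      scaffolds[[si]]$pieces <- bind_rows(
        if (rng[1] > 1) p[seq_len(rng[1] - 1), ],
        rev_pieces(p[rng[1]:rng[2], ]),
        if (rng[2] < nrow(p)) p[seq(rng[2] + 1, nrow(p)), ])
    } else if (kind == "fission") {
      scaffolds <- split_at(scaffolds, ev$chrom, ev$pos)
      loc <- locate(scaffolds, ev$chrom, ev$pos)
      p <- scaffolds[[loc$si]]$pieces
      cut <- if (p$strand[loc$pi] == "+") loc$pi - 1 else loc$pi
      if (cut < 1 || cut >= nrow(p)) abort("fission at scaffold end")
      left <- p[seq_len(cut), ]
      right <- p[seq(cut + 1, nrow(p)), ]
      scaffolds[[loc$si]]$pieces <- left
      scaffolds[[length(scaffolds) + 1L]] <- list(pieces = right)
    } else if (kind == "fusion") {
      sa <- find_scaffold_with(scaffolds, ev$chrom_a)
      sb <- find_scaffold_with(scaffolds, ev$chrom_b)
      if (sa == sb) abort("fusion partners are already on one scaffold")
      pb <- scaffolds[[sb]]$pieces
      if (isTRUE(ev$reverse_b)) pb <- rev_pieces(pb)
      scaffolds[[sa]]$pieces <- bind_rows(scaffolds[[sa]]$pieces, pb)
      scaffolds[[sb]] <- NULL
    } else if (kind == "translocation") {
      scaffolds <- split_at(scaffolds, ev$chrom, ev$start)
      scaffolds <- split_at(scaffolds, ev$chrom, ev$end)
      si <- locate(scaffolds, ev$chrom, ev$start)$si
      p <- scaffolds[[si]]$pieces
      inside <- which(p$chrom == ev$chrom & p$start >= ev$start &
                        p$end <= ev$end)
      rng <- range(inside)
      moved <- p[rng[1]:rng[2], ]
      scaffolds[[si]]$pieces <- bind_rows(
        if (rng[1] > 1) p[seq_len(rng[1] - 1), ],
        if (rng[2] < nrow(p)) p[seq(rng[2] + 1, nrow(p)), ])
      scaffolds <- split_at(scaffolds, ev$to_chrom, ev$to_pos)
      loc <- locate(scaffolds, ev$to_chrom, ev$to_pos)
      q <- scaffolds[[loc$si]]$pieces
      at <- if (q$strand[loc$pi] == "+") loc$pi - 1 else loc$pi
      scaffolds[[loc$si]]$pieces <- bind_rows(
        if (at >= 1) q[seq_len(at), ],
        moved,
        if (at < nrow(q)) q[seq(at + 1, nrow(q)), ])
    } else {
      abort(sprintf("unknown event kind '%s'", kind))
    }
  }
  finalize_assembly(genome, scaffolds, events)
}

find_scaffold_with <- function(scaffolds, chrom) {
  hits <- which(vapply(scaffolds,
                       function(s) chrom %in% s$pieces$chrom, logical(1)))
  if (length(hits) == 0) abort(sprintf("no scaffold carries %s", chrom))
  hits[1]
}

# Spacing guards the classifier's preconditions: breakpoints of *different*
# events must be >= 2 bins apart (and from chromosome ends); the two
# breakpoints delimiting a single inversion may be closer (a 1-bin inversion
# is legitimate).
check_event_spacing <- function(genome, events) {
  min_gap <- 2 * genome$config$bin_size
  bps <- list()
  for (k in seq_along(events)) {
    ev <- events[[k]]
    pts <- switch(ev$kind,
      inversion = tibble(chrom = ev$chrom, pos = c(ev$start, ev$end)),
      fission = tibble(chrom = ev$chrom, pos = ev$pos),
      fusion = NULL,
      translocation = tibble(chrom = c(ev$chrom, ev$chrom, ev$to_chrom),
                             pos = c(ev$start, ev$end, ev$to_pos)),
      abort(sprintf("unknown event kind '%s'", ev$kind)))
    if (!is.null(pts)) {
      pts$event <- k
      bps[[length(bps) + 1L]] <- pts
    }
  }
  if (length(bps) == 0) return(invisible(TRUE))
  bps <- bind_rows(bps)
  lens <- setNames(genome$chroms$length, genome$chroms$chrom)
  if (any(bps$pos < min_gap | bps$pos > lens[bps$chrom] - min_gap)) {
    abort("event breakpoints must be at least 2 bins from chromosome ends")
  }
  for (ch in unique(bps$chrom)) {
    v <- bps[bps$chrom == ch, ]
    v <- v[order(v$pos), ]
    if (nrow(v) > 1) {
      close_other <- diff(v$pos) < min_gap &
        v$event[-1] != v$event[-nrow(v)]
      if (any(close_other)) {
        abort("event breakpoints closer than 2 bins; histories this dense are rejected")
      }
    }
  }
  invisible(TRUE)
}

finalize_assembly <- function(genome, scaffolds, events) {
  blocks <- list()
  scaff_tab <- list()
  for (si in seq_along(scaffolds)) {
    name <- paste0("s", si)
    p <- scaffolds[[si]]$pieces
    # merge adjacent colinear same-strand pieces into maximal segments
    merged <- list(p[1, ])
    for (k in seq_len(nrow(p))[-1]) {
      lastp <- merged[[length(merged)]]
      b <- p[k, ]
      joinable <- lastp$chrom == b$chrom && lastp$strand == b$strand &&
        ((b$strand == "+" && b$start == lastp$end) ||
         (b$strand == "-" && b$end == lastp$start))
      if (joinable) {
        lastp$start <- min(lastp$start, b$start)
        lastp$end <- max(lastp$end, b$end)
        merged[[length(merged)]] <- lastp
      } else {
        merged[[length(merged) + 1L]] <- b
      }
    }
    p <- bind_rows(merged)
    offs <- cumsum(c(0, head(piece_lengths(p), -1)))
    blocks[[si]] <- tibble(
      ref_chrom = p$chrom, ref_start = p$start, ref_end = p$end,
      tgt_scaffold = name, tgt_start = offs,
      tgt_end = offs + piece_lengths(p), orientation = p$strand)
    scaff_tab[[si]] <- tibble(scaffold = name,
                              length = sum(piece_lengths(p)))
  }
  ev_tab <- purrr::map(events, function(ev) {
    tibble(kind = ev$kind,
           chrom = ev$chrom %||% ev$chrom_a,
           start = ev$start %||% ev$pos %||% NA_real_,
           end = ev$end %||% ev$pos %||% NA_real_,
           partner = ev$to_chrom %||% ev$chrom_b %||% NA_character_)
  }) |> bind_rows()
  structure(list(scaffolds = bind_rows(scaff_tab),
                 truth_blocks = bind_rows(blocks),
                 events_applied = ev_tab,
                 pieces = scaffolds, genome = genome),
            class = "sim_assembly")
}

#' Draw a random rearrangement history
#'
#' Samples the requested numbers of inversions, fissions and fusions with
#' bin-aligned breakpoints spaced at least `2 * bin_size` apart (and from
#' chromosome ends), so every conserved segment is recoverable at the
#' chaining resolution. Histories that cannot satisfy the spacing are
#' rejected with an error.
#'
#' @param genome A [sim_genome()].
#' @param n_inversions,n_fissions,n_fusions Event counts.
#' @param inv_size_bins Inversion sizes are drawn uniformly from this range
#'   of bins (default 2 to 6).
#' @param inv_sizes Optional explicit vector of inversion sizes in bins,
#'   overriding `n_inversions` and `inv_size_bins`.
#' @param seed Integer seed.
#' @return A list of event lists for [sim_rearrange()].
#' @export
sim_events_random <- function(genome, n_inversions = 0, n_fissions = 0,
                              n_fusions = 0, inv_size_bins = c(2, 6),
                              inv_sizes = NULL, seed = 1) {
  stopifnot(inherits(genome, "sim_genome"))
  bs <- genome$config$bin_size
  with_seed(seed, {
    # margins scale with the inversion length so a planted inversion can
    # never become the majority orientation of the segment it sits in
    taken <- tibble(chrom = character(), lo = double(), hi = double(),
                    margin = double())
    claim <- function(chrom, lo, hi, margin_bins) {
      m <- margin_bins * bs
      sub <- filter(taken, .data$chrom == !!chrom)
      gap <- pmax(m, sub$margin)
      if (any(pmax(sub$lo, lo - gap) < pmin(sub$hi, hi + gap))) {
        return(FALSE)
      }
      taken <<- bind_rows(taken, tibble(chrom = chrom, lo = lo, hi = hi,
                                        margin = m))
      TRUE
    }
    draw_interval <- function(n_bins_len) {
      margin <- max(2, n_bins_len)
      for (try in 1:200) {
        ci <- sample(nrow(genome$chroms), 1)
        ch <- genome$chroms$chrom[ci]
        nb <- floor(genome$chroms$length[ci] / bs)
        span <- nb - n_bins_len - 2 * margin
        if (span < 1) next
        lo <- (margin + sample(span, 1)) * bs
        hi <- lo + n_bins_len * bs
        if (hi > genome$chroms$length[ci] - margin * bs) next
        if (claim(ch, lo, hi, margin)) {
          return(list(chrom = ch, start = lo, end = hi))
        }
      }
      abort("could not place event with required breakpoint spacing")
    }
    events <- list()
    if (is.null(inv_sizes)) {
      inv_sizes <- vapply(seq_len(n_inversions), function(k)
        sample(seq(inv_size_bins[1], inv_size_bins[2]), 1), double(1))
    }
    for (len in inv_sizes) {
      iv <- draw_interval(len)
      events[[length(events) + 1L]] <- list(kind = "inversion",
                                            chrom = iv$chrom,
                                            start = iv$start, end = iv$end)
    }
    for (k in seq_len(n_fissions)) {
      iv <- draw_interval(1)
      events[[length(events) + 1L]] <- list(kind = "fission",
                                            chrom = iv$chrom, pos = iv$start)
    }
    # fusions reference ancestor chromosomes; partners must live on distinct
    # scaffolds at application time, which sequential sampling ensures by
    # tracking a scaffold-membership partition
    membership <- as.list(genome$chroms$chrom)
    for (k in seq_len(n_fusions)) {
      if (length(membership) < 2) {
        abort("not enough scaffolds left to fuse; reduce n_fusions")
      }
      pick <- sample(length(membership), 2)
      a <- membership[[pick[1]]][1]
      b <- membership[[pick[2]]][1]
      events[[length(events) + 1L]] <- list(kind = "fusion", chrom_a = a,
                                            chrom_b = b,
                                            reverse_b = runif(1) < 0.5)
      membership[[pick[1]]] <- c(membership[[pick[1]]],
                                 membership[[pick[2]]])
      membership[[pick[2]]] <- NULL
    }
    events
  })
}

#' Simulate Hi-C contact matrices with a planted compartment checkerboard
#'
#' For each scaffold, the expected count between bins `i` and `j` at
#' distance `s = max(|i - j|, 1)` bins is
#' `lambda = R * s^(-alpha) * (1 + c * a_i * a_j)` with `R = reads_per_bin`,
#' `alpha` the decay exponent, `c` the compartment strength and `a` the
#' planted sign profile carried over from the ancestor through the
#' rearrangement history. Counts are symmetric Poisson draws, deterministic
#' given the seed.
#'
#' @param assembly A `sim_assembly` (or a `sim_genome`, treated as an
#'   unrearranged assembly).
#' @param seed Integer seed (defaults to the config seed).
#' @return A named list of [contact_matrix()] objects (one per scaffold)
#'   with the per-scaffold planted profile attached as attribute
#'   `planted_sign`.
#' @export
sim_hic <- function(assembly, seed = NULL) {
  if (inherits(assembly, "sim_genome")) {
    assembly <- sim_rearrange(assembly, list())
  }
  stopifnot(inherits(assembly, "sim_assembly"))
  genome <- assembly$genome
  cfg <- genome$config
  seed <- seed %||% cfg$seed
  planted <- sim_target_profile(assembly)
  with_seed(seed, {
    out <- list()
    for (sc in assembly$scaffolds$scaffold) {
      a <- planted$sign[planted$scaffold == sc]
      nb <- length(a)
      s <- pmax(abs(outer(seq_len(nb), seq_len(nb), "-")), 1)
      lam <- cfg$reads_per_bin * s^(-cfg$decay_exponent) *
        (1 + cfg$compartment_strength * outer(a, a))
      m <- matrix(0, nb, nb)
      ut <- upper.tri(m, diag = TRUE)
      m[ut] <- rpois(sum(ut), lam[ut])
      m <- m + t(m) - diag(diag(m))
      cm <- contact_matrix(m, scaffold = sc, bin_size = cfg$bin_size,
                           scaffold_length =
                             assembly$scaffolds$length[
                               assembly$scaffolds$scaffold == sc])
      attr(cm, "planted_sign") <- a
      out[[sc]] <- cm
    }
    out
  })
}

#' Planted compartment profile on target coordinates
#'
#' Maps the ancestor's planted sign profile onto the rearranged scaffolds by
#' bin midpoints through the truth blocks.
#'
#' @param assembly A `sim_assembly`.
#' @return A tibble: `scaffold`, `bin`, `start`, `end`, `sign`.
#' @export
sim_target_profile <- function(assembly) {
  stopifnot(inherits(assembly, "sim_assembly"))
  genome <- assembly$genome
  bs <- genome$config$bin_size
  prof <- genome$profile
  purrr::pmap(assembly$scaffolds, function(scaffold, length) {
    nb <- ceiling(length / bs)
    mids <- (seq_len(nb) - 1) * bs + pmin(bs, length - (seq_len(nb) - 1) * bs) / 2
    tb <- filter(assembly$truth_blocks, .data$tgt_scaffold == scaffold)
    sgn <- vapply(mids, function(mid) {
      hit <- which(tb$tgt_start <= mid & mid < tb$tgt_end)
      if (length(hit) == 0) return(NA_real_)
      h <- tb[hit[1], ]
      anc <- if (h$orientation == "+") h$ref_start + (mid - h$tgt_start)
             else h$ref_end - (mid - h$tgt_start)
      abin <- floor(anc / bs)
      val <- prof$sign[prof$chrom == h$ref_chrom & prof$bin == abin]
      if (length(val) == 0) NA_real_ else val[1]
    }, double(1))
    tibble(scaffold = scaffold, bin = seq_len(nb) - 1L,
           start = (seq_len(nb) - 1) * bs,
           end = pmin(seq_len(nb) * bs, length), sign = sgn)
  }) |> bind_rows()
}

#' Write a simulated run to disk
#'
#' Emits the truth-block BED-pair TSV (the same dialect [read_blocks()]
#' consumes), one contact-triplet TSV and bin-table TSV per scaffold, the
#' truth-events TSV, the planted-profile bedGraph and a manifest JSON
#' recording seed and configuration.
#'
#' @param assembly A `sim_assembly`.
#' @param dir Output directory (created if needed).
#' @param contacts Optional result of [sim_hic()]; simulated if omitted.
#' @return `dir`, invisibly.
#' @export
sim_write_run <- function(assembly, dir, contacts = NULL) {
  stopifnot(inherits(assembly, "sim_assembly"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_blocks(assembly$truth_blocks, file.path(dir, "truth_blocks.tsv"))
  readr::write_tsv(assembly$events_applied, file.path(dir, "truth_events.tsv"))
  contacts <- contacts %||% sim_hic(assembly)
  for (sc in names(contacts)) {
    cm <- contacts[[sc]]
    ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts > 0,
                arr.ind = TRUE)
    readr::write_tsv(tibble(bin_i = ut[, 1] - 1L, bin_j = ut[, 2] - 1L,
                            count = cm$counts[ut]),
                     file.path(dir, paste0("contacts_", sc, ".tsv")),
                     col_names = FALSE)
    readr::write_tsv(cm$bins, file.path(dir, paste0("bins_", sc, ".tsv")))
  }
  prof <- sim_target_profile(assembly)
  readr::write_tsv(prof[c("scaffold", "start", "end", "sign")],
                   file.path(dir, "planted_profile.bedgraph"),
                   col_names = FALSE)
  cfg <- assembly$genome$config
  jsonlite::write_json(
    list(seed = cfg$seed, bin_size = cfg$bin_size,
         decay_exponent = cfg$decay_exponent,
         compartment_strength = cfg$compartment_strength,
         reads_per_bin = cfg$reads_per_bin,
         chrom_lengths = cfg$chrom_lengths,
         n_scaffolds = nrow(assembly$scaffolds)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
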