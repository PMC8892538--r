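#' Read pairwise alignment blocks
#'
#' Reads the gap-free aligned intervals between a target assembly and a
#' reference assembly that downstream synteny-block chaining consumes.
#' Two dialects are supported:
#'
#' * `"bedpair_tsv"` — seven whitespace-separated columns
#'   (`ref_chrom ref_start ref_end tgt_scaffold tgt_start tgt_end strand`),
#'   `#` comment lines ignored; coordinates 0-based half-open.
#' * `"ucsc_chain"` — UCSC chain files as emitted by axtChain. Each chain is
#'   decomposed into its gap-free aligned segments; minus-strand query
#'   coordinates are converted to forward-strand 0-based half-open intervals
#'   (`start' = L - end`, `end' = L - start` with `L` the scaffold length
#'   from the chain header).
#'
#' @param path Path to the file.
#' @param format One of `"bedpair_tsv"` or `"ucsc_chain"`.
#' @return A tibble of alignment blocks with columns `ref_chrom`, `ref_start`,
#'   `ref_end`, `tgt_scaffold`, `tgt_start`, `tgt_end`, `orientation`.
#' @examples
#' tf <- tempfile()
#' writeLines("chrA1\t0\t1000\ts7\t0\t1000\t+", tf)
#' read_blocks(tf)
#' @export
read_blocks <- function(path, format = c("bedpair_tsv", "ucsc_chain")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  blocks <- switch(format,
    bedpair_tsv = read_bedpair(path),
    ucsc_chain  = read_chain(path)
  )
  validate_blocks(blocks)
  blocks
}

read_bedpair <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(empty_blocks())
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 7)) {
    abort(sprintf("malformed BED-pair line %d: expected 7 fields, got %d",
                  idx[which(nf < 7)[1]], nf[nf < 7][1]))
  }
  # trailing columns (id, n_source_blocks in HSB dumps) are ignored
  m <- do.call(rbind, lapply(fields, `[`, 1:7))
  coords <- suppressWarnings(apply(m[, c(2, 3, 5, 6), drop = FALSE], 2,
                                   as.numeric))
  coords <- matrix(coords, ncol = 4)
  if (anyNA(coords) || any(coords < 0) || any(coords != floor(coords))) {
    bad <- idx[which(rowSums(is.na(coords) | coords < 0) > 0)[1]]
    abort(sprintf("malformed BED-pair line %d: coordinates must be non-negative integers",
                  bad))
  }
  tibble(
    ref_chrom = m[, 1], ref_start = coords[, 1], ref_end = coords[, 2],
    tgt_scaffold = m[, 4], tgt_start = coords[, 3], tgt_end = coords[, 4],
    orientation = m[, 7]
  )
}

read_chain <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    f <- strsplit(line, "\\s+")[[1]]
    if (f[1] != "chain" || length(f) < 12) {
      abort(sprintf("malformed chain header at line %d", i))
    }
    t_name <- f[3]; t_start <- as.numeric(f[6])
    q_name <- f[8]; q_size <- as.numeric(f[9])
    q_strand <- f[10]; q_start <- as.numeric(f[11])
    if (anyNA(c(t_start, q_size, q_start))) {
      abort(sprintf("malformed chain header at line %d", i))
    }
    t_off <- t_start; q_off <- q_start
    i <- i + 1L
    repeat {
      if (i > n) abort(sprintf("truncated chain block at line %d", i))
      row <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      sz <- as.numeric(row[1])
      if (is.na(sz)) abort(sprintf("malformed chain data at line %d", i))
      qs <- q_off; qe <- q_off + sz
      if (q_strand == "-") { tmp <- qs; qs <- q_size - qe; qe <- q_size - tmp }
      out[[length(out) + 1L]] <- tibble(
        ref_chrom = t_name, ref_start = t_off, ref_end = t_off + sz,
        tgt_scaffold = q_name, tgt_start = qs, tgt_end = qe,
        orientation = q_strand
      )
      if (length(row) == 1) { i <- i + 1L; break }
      dt <- as.numeric(row[2]); dq <- as.numeric(row[3])
      if (anyNA(c(dt, dq))) abort(sprintf("malformed chain data at line %d", i))
      t_off <- t_off + sz + dt
      q_off <- q_off + sz + dq
      i <- i + 1L
    }
  }
  if (length(out) == 0) return(empty_blocks())
  bind_rows(out)
}

empty_blocks <- function() {
  tibble(ref_chrom = character(), ref_start = double(), ref_end = double(),
         tgt_scaffold = character(), tgt_start = double(), tgt_end = double(),
         orientation = character())
}

#' Build an assembly index
#'
#' A minimal per-scaffold length table used to drop scaffolds too short for
#' synteny analysis (the default keeps scaffolds of at least 50 kb, i.e.
#' scaffolds shorter than 50 kb are excluded).
#'
#' @param scaffold Character vector of scaffold identifiers.
#' @param length Numeric vector of scaffold lengths (bp), all positive.
#' @param min_scaffold_len Minimum scaffold length retained downstream (bp).
#' @return A tibble with columns `scaffold`, `length` and attribute
#'   `min_scaffold_len`.
#' @export
assembly_index <- function(scaffold, length, min_scaffold_len = 50000) {
  if (any(length <= 0)) abort("scaffold lengths must be positive")
  if (anyDuplicated(scaffold)) abort("duplicate scaffold identifiers in index")
  idx <- tibble(scaffold = as.character(scaffold), length = as.numeric(length))
  attr(idx, "min_scaffold_len") <- min_scaffold_len
  idx
}

#' Drop alignment blocks on short scaffolds
#'
#' Removes blocks whose target scaffold is shorter than the index's
#' `min_scaffold_len` (strictly shorter; a scaffold exactly at the threshold
#' is kept). Every scaffold mentioned by the blocks must be present in the
#' index.
#'
#' @param blocks Alignment-block tibble (see [read_blocks()]).
#' @param index An [assembly_index()] for the target assembly.
#' @return The filtered block tibble.
#' @export
filter_scaffolds <- function(blocks, index) {
  validate_blocks(blocks)
  min_len <- attr(index, "min_scaffold_len") %||% 50000
  missing <- setdiff(unique(blocks$tgt_scaffold), index$scaffold)
  if (length(missing) > 0) {
    abort(sprintf("scaffold(s) absent from assembly index: %s",
                  paste(missing, collapse = ", ")))
  }
  keep_ids <- index$scaffold[index$length >= min_len]
  filter(blocks, .data$tgt_scaffold %in% keep_ids)
}

#' Write alignment or synteny blocks as BED-pair TSV
#'
#' @param blocks Block tibble; extra columns (`id`, `n_source_blocks`) are
#'   appended after the seven standard columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  cols <- c(block_cols, intersect(c("id", "n_source_blocks"), names(blocks)))
  readr::write_tsv(blocks[cols], path, col_names = FALSE)
  invisible(path)
}
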