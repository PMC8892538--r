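block_cols <- c("ref_chrom", "ref_start", "ref_end",
                "tgt_scaffold", "tgt_start", "tgt_end", "orientation")

#' Validate a table of pairwise alignment blocks
#'
#' Checks the column contract shared by alignment blocks and synteny blocks:
#' 0-based half-open intervals with positive length on both genomes and an
#' orientation of `"+"` or `"-"`.
#'
#' @param blocks A data frame with columns `ref_chrom`, `ref_start`, `ref_end`,
#'   `tgt_scaffold`, `tgt_start`, `tgt_end`, `orientation`.
#' @param what Label used in error messages.
#' @return `blocks`, invisibly, as a tibble.
#' @export
validate_blocks <- function(blocks, what = "alignment blocks") {
  blocks <- as_tibble(blocks)
  missing <- setdiff(block_cols, names(blocks))
  if (length(missing) > 0) {
    abort(sprintf("%s are missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(blocks) == 0) return(invisible(blocks))
  bad <- which(!(blocks$ref_start < blocks$ref_end) |
                 !(blocks$tgt_start < blocks$tgt_end))
  if (length(bad) > 0) {
    abort(sprintf("%s: interval end <= start at row(s) %s", what,
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (any(blocks$ref_start < 0) || any(blocks$tgt_start < 0)) {
    abort(sprintf("%s: negative coordinates", what))
  }
  if (!all(blocks$orientation %in% c("+", "-"))) {
    abort(sprintf("%s: orientation must be '+' or '-'", what))
  }
  invisible(blocks)
}

# reciprocal overlap fraction of [a1,a2) and [b1,b2): min over both intervals
reciprocal_overlap <- function(a1, a2, b1, b2) {
  ov <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
  pmin(ov / (a2 - a1), ov / (b2 - b1))
}

# maximal runs of TRUE in a logical vector -> tibble(start, end) of indices
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

# spreadsheet-style letters: 1 -> a, 26 -> z, 27 -> aa, ...
index_to_letters <- function(i) {
  vapply(i, function(k) {
    out <- character(0)
    while (k > 0) {
      r <- (k - 1) %% 26
      out <- c(letters[r + 1], out)
      k <- (k - 1) %/% 26
    }
    paste(out, collapse = "")
  }, character(1))
}
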