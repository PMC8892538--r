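# Independent oracles used to freeze expected values. Each reimplements the
# operation it checks from first principles, by brute force where feasible,
# and must stay independent of the package code paths.

# forward-strand flip of a reversed-strand interval on a scaffold of length L
oracle_flip_minus <- function(start, end, L) c(L - end, L - start)

# Brute-force chaining: within each (ref_chrom, tgt_scaffold, orientation)
# group, enumerate every assignment of blocks (in ref order) to open chains
# subject to the gap/colinearity rules, evaluate total reference coverage of
# chains surviving the min-span filter, and return the maximum coverage.
oracle_chain_coverage <- function(blocks, resolution) {
  key <- paste(blocks$ref_chrom, blocks$tgt_scaffold, blocks$orientation)
  total <- 0
  for (k in unique(key)) {
    g <- blocks[key == k, ]
    g <- g[order(g$ref_start, g$tgt_start), ]
    plus <- g$orientation[1] == "+"
    best <- 0
    compatible <- function(ch, b) {
      if (b$ref_start - ch$ref_end >= resolution) return(FALSE)
      if (b$ref_start < ch$ref_start) return(FALSE)
      if (plus) {
        b$tgt_start - ch$tgt_end < resolution && b$tgt_end > ch$tgt_end &&
          b$tgt_start >= ch$tgt_start
      } else {
        ch$tgt_start - b$tgt_end < resolution && b$tgt_start < ch$tgt_start &&
          b$tgt_end <= ch$tgt_end
      }
    }
    evaluate <- function(chains) {
      spans <- vapply(chains, function(ch) {
        if (ch$ref_end - ch$ref_start >= resolution &&
            ch$tgt_end - ch$tgt_start >= resolution) {
          ch$ref_end - ch$ref_start
        } else 0
      }, double(1))
      sum(spans)
    }
    recurse <- function(i, chains) {
      if (i > nrow(g)) {
        cov <- evaluate(chains)
        if (cov > best) best <<- cov
        return(invisible(NULL))
      }
      b <- g[i, ]
      nb <- list(ref_start = b$ref_start, ref_end = b$ref_end,
                 tgt_start = b$tgt_start, tgt_end = b$tgt_end)
      for (ci in seq_along(chains)) {
        if (compatible(chains[[ci]], b)) {
          ext <- chains
          ch <- ext[[ci]]
          ch$ref_end <- max(ch$ref_end, b$ref_end)
          ch$tgt_start <- min(ch$tgt_start, b$tgt_start)
          ch$tgt_end <- max(ch$tgt_end, b$tgt_end)
          ext[[ci]] <- ch
          recurse(i + 1, ext)
        }
      }
      recurse(i + 1, c(chains, list(nb)))
    }
    recurse(1, list())
    total <- total + best
  }
  total
}

# classic alternating Sinkhorn to a doubly stochastic limit, run to 1e-10
oracle_sinkhorn <- function(m, tol = 1e-10, max_iter = 50000) {
  x <- m
  for (it in seq_len(max_iter)) {
    x <- x / rowSums(x)
    x <- t(t(x) / colSums(x))
    if (max(abs(rowSums(x) - 1)) < tol && max(abs(colSums(x) - 1)) < tol) {
      break
    }
  }
  x
}

# textbook Pearson correlation of two vectors
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# dense full-spectrum PC1 of a correlation matrix: eigendecomposition of the
# crossproduct of the column-centred matrix, scores normalised to unit norm
oracle_pc1 <- function(corr) {
  cc <- sweep(corr, 2, colMeans(corr))
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  scores <- as.vector(cc %*% ev$vectors[, 1])
  scores / sqrt(sum(scores^2))
}

# align sign of b to a before elementwise comparison
sign_align <- function(a, b) if (sum(a * b) < 0) -b else b

# quick builder for block tibbles
blk <- function(ref_chrom, ref_start, ref_end, tgt_scaffold, tgt_start,
                tgt_end, orientation = "+") {
  tibble::tibble(ref_chrom = ref_chrom, ref_start = ref_start,
                 ref_end = ref_end, tgt_scaffold = tgt_scaffold,
                 tgt_start = tgt_start, tgt_end = tgt_end,
                 orientation = orientation)
}
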