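#' Construct a contact matrix object
#'
#' Container for one scaffold's intrachromosomal Hi-C contact matrix at a
#' fixed bin size: a dense symmetric count matrix, a bin table and a validity
#' mask. Low-coverage bins (raw marginal below the 5th percentile of the
#' nonzero marginals by default) are masked out of all downstream analysis.
#'
#' @param counts Symmetric non-negative numeric matrix.
#' @param scaffold Scaffold identifier.
#' @param bin_size Bin size in bp (default 500 kb).
#' @param scaffold_length Scaffold length in bp; defaults to
#'   `nrow(counts) * bin_size`.
#' @param mask_quantile Quantile of the nonzero marginals below which bins
#'   are masked (default 0.05). Zero-marginal bins are always masked.
#' @return An object of class `contact_matrix` with elements `counts`,
#'   `bins` (tibble: `bin`, `start`, `end`, `valid`), `scaffold`, `bin_size`.
#' @export
contact_matrix <- function(counts, scaffold = "scaffold", bin_size = 500000,
                           scaffold_length = NULL, mask_quantile = 0.05) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) abort("contact matrix must be square")
  if (any(counts < 0)) abort("contact matrix has negative entries")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8))) {
    abort("contact matrix must be symmetric")
  }
  nb <- nrow(counts)
  scaffold_length <- scaffold_length %||% (nb * bin_size)
  marg <- rowSums(counts)
  nz <- marg[marg > 0]
  thr <- if (length(nz) > 0) quantile(nz, mask_quantile, names = FALSE) else 0
  valid <- marg > 0 & marg >= thr
  bins <- tibble(bin = seq_len(nb) - 1L,
                 start = (seq_len(nb) - 1) * bin_size,
                 end = pmin(seq_len(nb) * bin_size, scaffold_length),
                 valid = valid)
  structure(list(counts = counts, bins = bins, scaffold = scaffold,
                 bin_size = bin_size),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %g bp (%d valid)\n",
              x$scaffold, nrow(x$counts), x$bin_size, sum(x$bins$valid)))
  invisible(x)
}

#' Load a contact matrix from sparse triplet text
#'
#' Reads `(bin_i, bin_j, count)` triplets (TSV, `#` comments allowed) for one
#' scaffold and builds the symmetric dense matrix. Each pair should be stored
#' once (either triangle); duplicated `(i, j)` / `(j, i)` entries are summed
#' with a warning. Only this plain-text dialect is supported as input;
#' matrices in binary containers should be exported to triplets upstream.
#'
#' @param path Path to the triplet TSV.
#' @param n_bins Number of bins on the scaffold (triplet indices must be in
#'   `[0, n_bins)`).
#' @param format Only `"triplet_tsv"` is supported.
#' @inheritParams contact_matrix
#' @return A [contact_matrix()].
#' @export
load_contacts <- function(path, n_bins, format = "triplet_tsv",
                          scaffold = "scaffold", bin_size = 500000,
                          scaffold_length = NULL, mask_quantile = 0.05) {
  if (!identical(format, "triplet_tsv")) {
    abort(sprintf("unsupported contact format '%s': only triplet_tsv is implemented",
                  format))
  }
  tr <- readr::read_tsv(path, comment = "#",
                        col_names = c("bin_i", "bin_j", "count"),
                        col_types = "ddd", progress = FALSE)
  if (nrow(tr) > 0 && (max(tr$bin_i, tr$bin_j) >= n_bins ||
                       min(tr$bin_i, tr$bin_j) < 0)) {
    abort("triplet bin index out of range for the bin table")
  }
  m <- matrix(0, n_bins, n_bins)
  seen <- matrix(FALSE, n_bins, n_bins)
  dup <- FALSE
  for (k in seq_len(nrow(tr))) {
    i <- tr$bin_i[k] + 1L; j <- tr$bin_j[k] + 1L
    if (seen[i, j]) dup <- TRUE
    m[i, j] <- m[i, j] + tr$count[k]
    seen[i, j] <- TRUE; seen[j, i] <- TRUE
    if (i != j) m[j, i] <- m[j, i] + tr$count[k]
  }
  if (dup) warn("duplicate triplets for the same bin pair were summed")
  contact_matrix(m, scaffold = scaffold, bin_size = bin_size,
                 scaffold_length = scaffold_length,
                 mask_quantile = mask_quantile)
}

#' Balance a contact matrix to equal row sums
#'
#' Symmetric Sinkhorn iteration to the matrix-scaling fixed point (equal row
#' and column sums over valid bins), the same fixed point the Knight–Ruiz
#' "KR" normalisation converges to. Returns `M' = D M D` with `D` diagonal.
#' Rows that fail to converge within `max_iter` are masked with a warning.
#'
#' @param cm A [contact_matrix()].
#' @param tol Relative row-sum tolerance (default `1e-6`).
#' @param max_iter Iteration cap (default 3000).
#' @return A list with `cm` (balanced `contact_matrix`, masked bins zeroed)
#'   and `scaling` (per-bin scaling vector, `NA` for masked bins).
#' @export
kr_balance <- function(cm, tol = 1e-6, max_iter = 3000) {
  stopifnot(inherits(cm, "contact_matrix"))
  valid <- cm$bins$valid
  m <- cm$counts[valid, valid, drop = FALSE]
  nv <- nrow(m)
  d <- rep(1, nv)
  converged <- FALSE
  if (nv > 0) {
    for (it in seq_len(max_iter)) {
      r <- as.vector(m %*% d) * d
      mu <- mean(r[r > 0])
      if (all(r > 0) && max(abs(r / mu - 1)) < tol) { converged <- TRUE; break }
      adj <- ifelse(r > 0, sqrt(r / mu), 1)
      d <- d / adj
    }
  } else {
    converged <- TRUE
  }
  bal <- m * outer(d, d)
  keep_v <- rep(TRUE, nv)
  if (!converged) {
    r <- rowSums(bal)
    mu <- mean(r[r > 0])
    keep_v <- r > 0 & abs(r / mu - 1) <= 10 * tol
    warn(sprintf("KR balancing did not converge for %d bin(s); masking them",
                 sum(!keep_v)))
  }
  out <- cm
  full <- matrix(0, nrow(cm$counts), ncol(cm$counts))
  scaling <- rep(NA_real_, nrow(cm$counts))
  vidx <- which(valid)[keep_v]
  full[vidx, vidx] <- bal[keep_v, keep_v, drop = FALSE]
  scaling[which(valid)[keep_v]] <- d[keep_v]
  out$counts <- full
  out$bins$valid[setdiff(which(valid), vidx)] <- FALSE
  list(cm = out, scaling = scaling)
}

#' Distance-normalise a balanced contact matrix
#'
#' Divides each entry by the mean of all valid entries at the same bin
#' distance `|i - j|` (the expected contact at that distance), yielding the
#' observed/expected matrix whose block structure carries the compartment
#' signal. Distances with no valid entries yield `NA`.
#'
#' @param cm A balanced [contact_matrix()] (from [kr_balance()]).
#' @return A numeric matrix (`NA` on masked rows/columns), with the bin
#'   table attached as attribute `bins`.
#' @export
observed_expected <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  valid <- cm$bins$valid
  n <- nrow(cm$counts)
  oe <- matrix(NA_real_, n, n)
  vi <- which(valid)
  if (length(vi) > 0) {
    sub <- cm$counts[vi, vi, drop = FALSE]
    dmat <- abs(outer(vi, vi, "-"))
    for (s in sort(unique(as.vector(dmat)))) {
      sel <- dmat == s
      mu <- mean(sub[sel])
      oe_val <- if (mu > 0) sub[sel] / mu else NA_real_
      tmp <- oe[vi, vi, drop = FALSE]
      tmp[sel] <- oe_val
      oe[vi, vi] <- tmp
    }
  }
  attr(oe, "bins") <- cm$bins
  attr(oe, "scaffold") <- cm$scaffold
  attr(oe, "bin_size") <- cm$bin_size
  oe
}

#' Pearson correlation of the observed/expected matrix
#'
#' Correlates the O/E profiles of every pair of valid bins. Bins whose O/E
#' row is constant (zero variance) are masked. Requires at least three valid
#' bins.
#'
#' @param oe O/E matrix from [observed_expected()].
#' @return Symmetric correlation matrix with unit diagonal over valid bins,
#'   `NA` elsewhere; bin table carried in attribute `bins`.
#' @export
pearson_correlation <- function(oe) {
  bins <- attr(oe, "bins")
  valid <- if (!is.null(bins)) bins$valid else rep(TRUE, nrow(oe))
  vi <- which(valid)
  if (length(vi) < 3) abort("scaffold too short for compartment analysis")
  sub <- oe[vi, vi, drop = FALSE]
  sds <- apply(sub, 1, stats::sd, na.rm = TRUE)
  ok <- is.finite(sds) & sds > 0
  vi <- vi[ok]
  if (length(vi) < 3) abort("scaffold too short for compartment analysis")
  sub <- oe[vi, vi, drop = FALSE]
  cc <- suppressWarnings(cor(t(sub), use = "pairwise.complete.obs"))
  diag(cc) <- 1
  out <- matrix(NA_real_, nrow(oe), ncol(oe))
  out[vi, vi] <- cc
  if (!is.null(bins)) bins$valid <- seq_len(nrow(oe)) %in% vi
  attr(out, "bins") <- bins
  attr(out, "scaffold") <- attr(oe, "scaffold")
  attr(out, "bin_size") <- attr(oe, "bin_size")
  out
}

#' Leading principal component of the correlation matrix
#'
#' Computes principal component 1 of the Pearson correlation matrix (rows as
#' observations, columns centred), the per-bin compartment eigenvector whose
#' sign partitions bins into A and B compartments. The profile is normalised
#' to unit Euclidean norm over valid bins; `explained_fraction` is the share
#' of total variance carried by the first component.
#'
#' @param corr Correlation matrix from [pearson_correlation()].
#' @return An object of class `eigen_profile`: list with `values` (one per
#'   bin, `NA` on masked bins), `bins`, `scaffold`, `bin_size`,
#'   `explained_fraction`, `sign_anchor`.
#' @export
leading_eigenvector <- function(corr) {
  bins <- attr(corr, "bins")
  valid <- if (!is.null(bins)) bins$valid else rep(TRUE, nrow(corr))
  vi <- which(valid)
  if (length(vi) < 3) abort("scaffold too short for compartment analysis")
  sub <- corr[vi, vi, drop = FALSE]
  cc <- sweep(sub, 2, colMeans(sub))
  sv <- tryCatch(svd(cc), error = function(e) abort("eigendecomposition failed"))
  if (sv$d[1] < 1e-12) {
    warn("degenerate correlation matrix; compartment profile masked")
    vals <- rep(NA_real_, nrow(corr))
    expl <- NA_real_
  } else {
    scores <- as.vector(cc %*% sv$v[, 1])
    scores <- scores / sqrt(sum(scores^2))
    vals <- rep(NA_real_, nrow(corr))
    vals[vi] <- scores
    expl <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(values = vals,
                 bins = bins %||% tibble(bin = seq_along(vals) - 1L,
                                         start = NA_real_, end = NA_real_,
                                         valid = valid),
                 scaffold = attr(corr, "scaffold") %||% "scaffold",
                 bin_size = attr(corr, "bin_size") %||% NA_real_,
                 explained_fraction = expl,
                 sign_anchor = "none"),
            class = "eigen_profile")
}

#' Orient the sign of a compartment profile
#'
#' The sign of a principal component is arbitrary; for cross-species
#' comparison all profiles must share one orientation. With an anchor profile
#' (same coordinates), the sign is chosen so the Pearson correlation with the
#' anchor is non-negative; without one (or when the correlation is exactly
#' zero or no bins overlap), the first valid bin is made non-negative.
#'
#' @param profile An `eigen_profile`.
#' @param anchor Optional anchoring `eigen_profile` (or bare numeric vector
#'   of equal length).
#' @return The profile with `values` possibly negated and `sign_anchor` set.
#' @export
orient_sign <- function(profile, anchor = NULL) {
  stopifnot(inherits(profile, "eigen_profile"))
  v <- profile$values
  anchor_vals <- if (inherits(anchor, "eigen_profile")) anchor$values else anchor
  flip <- NULL
  if (!is.null(anchor_vals)) {
    ok <- is.finite(v) & is.finite(anchor_vals)
    if (!any(ok)) {
      warn("no overlap with anchor profile; falling back to first-bin rule")
    } else {
      r <- suppressWarnings(cor(v[ok], anchor_vals[ok]))
      if (is.finite(r) && r != 0) flip <- r < 0
      profile$sign_anchor <- "reference-correlation"
    }
  }
  if (is.null(flip)) {
    first <- v[which(is.finite(v))[1]]
    flip <- isTRUE(first < 0)
    profile$sign_anchor <- if (is.null(anchor_vals)) "first-bin-positive"
                           else profile$sign_anchor
  }
  if (flip) profile$values <- -profile$values
  profile
}

#' Full compartment-eigenvector pipeline for one scaffold
#'
#' Convenience wrapper: [kr_balance()] then [observed_expected()],
#' [pearson_correlation()], [leading_eigenvector()] and [orient_sign()].
#'
#' @inheritParams kr_balance
#' @inheritParams orient_sign
#' @return An `eigen_profile`.
#' @export
hic_eigenvector <- function(cm, anchor = NULL, tol = 1e-6, max_iter = 3000) {
  bal <- kr_balance(cm, tol = tol, max_iter = max_iter)
  prof <- leading_eigenvector(pearson_correlation(observed_expected(bal$cm)))
  orient_sign(prof, anchor)
}

#' @export
print.eigen_profile <- function(x, ...) {
  cat(sprintf("<eigen_profile> %s: %d bins @ %g bp, %d valid, explained %.2f\n",
              x$scaffold, length(x$values), x$bin_size,
              sum(is.finite(x$values)),
              x$explained_fraction %||% NA_real_))
  invisible(x)
}

#' Tidy a compartment profile into a per-bin tibble
#'
#' @param x An `eigen_profile`.
#' @param ... Unused.
#' @return A tibble with `scaffold`, `bin`, `start`, `end`, `value`,
#'   `compartment` (`"A"` for positive sign, `"B"` for negative, `NA` masked).
#' @method tidy eigen_profile
#' @export
tidy.eigen_profile <- function(x, ...) {
  tibble(scaffold = x$scaffold, bin = x$bins$bin, start = x$bins$start,
         end = x$bins$end, value = x$values,
         compartment = dplyr::case_when(
           !is.finite(x$values) ~ NA_character_,
           x$values >= 0 ~ "A", TRUE ~ "B"))
}

#' @rdname tidy.eigen_profile
#' @method glance eigen_profile
#' @export
glance.eigen_profile <- function(x, ...) {
  tibble(scaffold = x$scaffold, n_bins = length(x$values),
         n_valid = sum(is.finite(x$values)),
         explained_fraction = x$explained_fraction,
         sign_anchor = x$sign_anchor)
}

#' Write a compartment profile as bedGraph
#'
#' Masked bins are omitted.
#'
#' @param profile An `eigen_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  td <- tidy(profile) |> filter(is.finite(.data$value))
  readr::write_tsv(td[c("scaffold", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}
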