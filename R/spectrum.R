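#' Site frequency spectrum container
#'
#' A spectrum holds per-bin SNP counts (or expected counts) indexed by
#' derived-allele count `0..n` in one population (1D) or jointly
#' `(0..n1, 0..n2)` in two populations (2D), together with a logical mask of
#' entries that carry no weight in any likelihood or total. The absent and
#' fixed corners are always masked; folded spectra additionally mask the
#' major-allele half.
#'
#' @param counts numeric vector (1D) or matrix (2D) of non-negative values;
#'   entry `i` (or `(i, j)`) counts sites with `i` derived copies.
#' @param sample_sizes integer vector of chromosome counts, length 1 or 2.
#'   Defaults to `length(counts) - 1` (or `dim(counts) - 1`).
#' @param folded logical; is the spectrum indexed by minor-allele count?
#' @param mask logical array of the same shape as `counts`; `TRUE` entries are
#'   excluded. Corner (and, when folded, major-half) masking is always added.
#' @return an object of class `"sfs"`.
#' @export
spectrum <- function(counts, sample_sizes = NULL, folded = FALSE, mask = NULL) {
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    sizes <- dim(counts) - 1L
  } else {
    counts <- as.numeric(counts)
    sizes <- length(counts) - 1L
  }
  if (is.null(sample_sizes)) sample_sizes <- sizes
  sample_sizes <- as.integer(sample_sizes)
  if (!identical(as.integer(sizes), sample_sizes))
    stop("counts shape does not match sample_sizes + 1")
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts in spectrum")
  m <- default_mask(sample_sizes, folded)
  if (!is.null(mask)) {
    if (!identical(dim2(mask), dim2(counts)))
      stop("mask shape does not match counts")
    m <- m | mask
  }
  structure(list(counts = counts, sample_sizes = sample_sizes,
                 folded = folded, mask = m),
            class = "sfs")
}

dim2 <- function(x) if (is.matrix(x)) dim(x) else length(x)

#' @export
is_spectrum <- function(x) inherits(x, "sfs")

stopifnot_spectrum <- function(x) {
  if (!is_spectrum(x)) stop("not a spectrum ('sfs') object")
}

# corner + (optionally) fold-line mask for given chromosome counts
default_mask <- function(sizes, folded) {
  if (length(sizes) == 1L) {
    n <- sizes
    m <- rep(FALSE, n + 1L)
    m[c(1L, n + 1L)] <- TRUE
    if (folded) m[seq_len(n + 1L) - 1L > floor(n / 2)] <- TRUE
  } else {
    n1 <- sizes[1]; n2 <- sizes[2]
    m <- matrix(FALSE, n1 + 1L, n2 + 1L)
    m[1L, 1L] <- TRUE
    m[n1 + 1L, n2 + 1L] <- TRUE
    if (folded) {
      tot <- outer(0:n1, 0:n2, "+")
      m[tot > (n1 + n2) / 2] <- TRUE
    }
  }
  m
}

#' Total number of segregating sites in a spectrum
#'
#' Sum of all unmasked entries.
#' @param spec an `"sfs"` object.
#' @export
segregating_total <- function(spec) {
  stopifnot_spectrum(spec)
  sum(spec$counts[!spec$mask])
}

#' @export
print.sfs <- function(x, ...) {
  kind <- if (length(x$sample_sizes) == 1L) "1D" else "2D"
  cat(sprintf("%s site frequency spectrum (%s), n = %s\n",
              kind, if (x$folded) "folded" else "unfolded",
              paste(x$sample_sizes, collapse = " x ")))
  cat(sprintf("  segregating total: %.4g over %d unmasked entries\n",
              segregating_total(x), sum(!x$mask)))
  invisible(x)
}

#' Fold a spectrum onto minor-allele counts
#'
#' Each minor-allele configuration receives the sum of itself and its mirror
#' (derived <-> ancestral swap); mirrored entries are masked. For a 2D
#' spectrum the fold is taken on the total minor-allele count across both
#' populations; cells lying exactly on the fold line are split, i.e. each of
#' the pair keeps half of the pair sum, so the unmasked total is conserved.
#'
#' @param spec an unfolded `"sfs"`.
#' @return the folded spectrum.
#' @export
fold <- function(spec) {
  stopifnot_spectrum(spec)
  if (spec$folded) stop("spectrum is already folded")
  cnt <- spec$counts
  if (length(spec$sample_sizes) == 1L) {
    n <- spec$sample_sizes
    mir <- rev(cnt)
    mirm <- rev(spec$mask)
    tot <- 0:n
    line <- n / 2
  } else {
    n1 <- spec$sample_sizes[1]; n2 <- spec$sample_sizes[2]
    mir <- cnt[(n1 + 1L):1L, (n2 + 1L):1L, drop = FALSE]
    mirm <- spec$mask[(n1 + 1L):1L, (n2 + 1L):1L, drop = FALSE]
    tot <- outer(0:n1, 0:n2, "+")
    line <- (n1 + n2) / 2
  }
  out <- cnt + mir
  out[tot == line] <- out[tot == line] / 2
  out[tot > line] <- 0
  newmask <- spec$mask | mirm
  spectrum(out, spec$sample_sizes, folded = TRUE, mask = newmask)
}

# hypergeometric projection matrix: rows 0..n (source derived count),
# cols 0..np (projected derived count)
projection_matrix <- function(n, np) {
  if (np > n) stop("cannot project up: new size exceeds current size")
  i <- 0:n
  out <- sapply(0:np, function(ip) {
    exp(lchoose(i, ip) + lchoose(n - i, np - ip) - lchoose(n, np))
  })
  out[is.nan(out)] <- 0
  matrix(out, nrow = n + 1L)
}

#' Project a spectrum to smaller sample sizes
#'
#' Redistributes every entry by the hypergeometric distribution of drawing
#' `new_sizes` chromosomes without replacement from the current sample. Mass
#' landing on the absent/fixed corners is masked, so the expected segregating
#' total never increases. A folded spectrum is projected by treating the
#' stored minor-configuration masses as unfolded, projecting, and re-folding
#' (projection commutes with the derived/ancestral mirror, so this is exact).
#'
#' @param spec an `"sfs"`.
#' @param new_sizes target chromosome counts, componentwise `<= sample_sizes`
#'   and each `>= 2`.
#' @export
project <- function(spec, new_sizes) {
  stopifnot_spectrum(spec)
  new_sizes <- as.integer(new_sizes)
  if (length(new_sizes) != length(spec$sample_sizes))
    stop("new_sizes has wrong length")
  if (any(new_sizes > spec$sample_sizes))
    stop("cannot project up: new size exceeds current size")
  if (any(new_sizes < 2L)) stop("projected sizes must be >= 2")
  if (identical(new_sizes, spec$sample_sizes)) return(spec)
  refold <- spec$folded
  cnt <- spec$counts
  cnt[spec$mask] <- 0
  if (length(spec$sample_sizes) == 1L) {
    P <- projection_matrix(spec$sample_sizes, new_sizes)
    out <- as.numeric(crossprod(P, cnt))
  } else {
    P1 <- projection_matrix(spec$sample_sizes[1], new_sizes[1])
    P2 <- projection_matrix(spec$sample_sizes[2], new_sizes[2])
    out <- crossprod(P1, cnt %*% P2)
  }
  res <- spectrum(out, new_sizes, folded = FALSE)
  if (refold) res <- fold(res) else res
}

#' Rescale a spectrum to a target segregating total
#'
#' Multiplies all unmasked entries by `target_total / segregating_total(spec)`
#' so that, e.g., synonymous and non-synonymous spectra can be drawn on a
#' common scale.
#'
#' @param spec an `"sfs"` with positive segregating total.
#' @param target_total the desired total.
#' @export
rescale_to_segregating <- function(spec, target_total) {
  stopifnot_spectrum(spec)
  tot <- segregating_total(spec)
  if (tot <= 0) stop("zero segregating total: cannot rescale")
  out <- spec
  out$counts[!out$mask] <- out$counts[!out$mask] * (target_total / tot)
  out
}

#' Symmetrised Poisson residuals between two spectra
#'
#' Per-entry residual `(a_i - b_i) / sqrt((a_i + b_i) / 2)`, defined as 0 when
#' both entries are 0; positive where the first spectrum has more SNPs. The
#' second spectrum should already be rescaled to the first one's segregating
#' total.
#'
#' @param a,b `"sfs"` objects of equal shape and folding.
#' @return numeric array of residuals, `NA` on masked entries.
#' @export
residual_spectrum <- function(a, b) {
  stopifnot_spectrum(a); stopifnot_spectrum(b)
  if (!identical(dim2(a$counts), dim2(b$counts)))
    stop("spectra have different shapes")
  if (!identical(a$folded, b$folded))
    stop("spectra have different folding status")
  s <- a$counts + b$counts
  r <- ifelse(s == 0, 0, (a$counts - b$counts) / sqrt(s / 2))
  r[a$mask | b$mask] <- NA_real_
  r
}

#' Write a spectrum as plain text
#'
#' Format: a header line `n1 [n2] folded_flag`, then the counts (one row per
#' line, full precision), then the 0/1 mask rows. Round-trips bit-exactly via
#' [read_spectrum()].
#'
#' @param spec an `"sfs"`.
#' @param path output file path.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot_spectrum(spec)
  hdr <- paste(c(spec$sample_sizes, as.integer(spec$folded)), collapse = " ")
  cm <- spec$counts
  if (!is.matrix(cm)) cm <- matrix(cm, nrow = 1L)
  mm <- spec$mask
  if (!is.matrix(mm)) mm <- matrix(mm, nrow = 1L)
  lines <- c(hdr,
             apply(cm, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             apply(mm, 1L, function(r) paste(as.integer(r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#' @param path file path.
#' @return an `"sfs"`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  folded <- as.logical(hdr[length(hdr)])
  sizes <- as.integer(hdr[-length(hdr)])
  nrows <- if (length(sizes) == 1L) 1L else sizes[1] + 1L
  parse_rows <- function(idx) {
    do.call(rbind, lapply(lines[idx], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  }
  cm <- parse_rows(1L + seq_len(nrows))
  mm <- parse_rows(1L + nrows + seq_len(nrows)) > 0
  if (length(sizes) == 1L) {
    cm <- as.numeric(cm); mm <- as.logical(mm)
  }
  spectrum(cm, sizes, folded = folded, mask = mm)
}

#' One-population marginal of a 2D spectrum
#'
#' Sums the joint expected counts over the other population's index
#' (including its fixed classes), giving the single-population spectrum.
#' @param spec an unfolded 2D `"sfs"`.
#' @param pop 1 or 2.
#' @export
marginal_1d <- function(spec, pop = 1) {
  stopifnot_spectrum(spec)
  if (!is.matrix(spec$counts)) stop("marginal_1d needs a 2D spectrum")
  if (spec$folded) stop("marginal_1d needs an unfolded spectrum")
  cnt <- if (pop == 1) rowSums(spec$counts) else colSums(spec$counts)
  spectrum(cnt, spec$sample_sizes[pop], folded = FALSE)
}
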