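#' Genotype matrix with population labels
#'
#' Individuals-by-sites allele-dosage calls for two populations: diploid
#' autosomal dosages in `{0, 1, 2}` or haploid (mtDNA) dosages in `{0, 1}`,
#' with `NA` marking missing calls and an optional per-call posterior
#' probability used for quality filtering.
#'
#' @param calls integer matrix, individuals in rows, sites in columns;
#'   `NA` = missing.
#' @param pop_labels character/factor of length `nrow(calls)` assigning each
#'   individual to one of exactly two populations.
#' @param quality optional numeric matrix in `[0, 1]`, same shape as `calls`;
#'   defaults to 1 everywhere (no filtering).
#' @param site_ids optional unique site keys; default taken from column names
#'   or generated.
#' @param ploidy 2 (autosomal) or 1 (mtDNA). A single matrix must be all one
#'   ploidy; calls exceeding the ploidy are an error.
#' @param individuals optional sample identifiers; default row names.
#' @return an object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(calls, pop_labels, quality = NULL, site_ids = NULL,
                            ploidy = 2L, individuals = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > ploidy)))
    stop(sprintf("calls must lie in 0..%d or be NA (mixed ploidy?)", ploidy))
  pop_labels <- as.factor(pop_labels)
  if (length(pop_labels) != nrow(calls))
    stop("pop_labels length does not match number of individuals")
  pop_labels <- droplevels(pop_labels)
  if (nlevels(pop_labels) != 2L)
    stop("pop_labels must partition individuals into exactly two non-empty populations")
  if (is.null(individuals)) {
    individuals <- rownames(calls)
    if (is.null(individuals)) individuals <- sprintf("ind%d", seq_len(nrow(calls)))
  }
  if (is.null(site_ids)) {
    site_ids <- colnames(calls)
    if (is.null(site_ids)) site_ids <- sprintf("site%d", seq_len(ncol(calls)))
  }
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids)) stop("site_ids must be unique")
  if (is.null(quality)) {
    quality <- matrix(1, nrow(calls), ncol(calls))
  } else {
    quality <- as.matrix(quality)
    if (!identical(dim(quality), dim(calls)))
      stop("quality shape does not match calls")
    if (any(quality < 0 | quality > 1, na.rm = TRUE))
      stop("quality must lie in [0, 1]")
  }
  structure(list(calls = calls, pop_labels = pop_labels, quality = quality,
                 site_ids = site_ids, individuals = as.character(individuals),
                 ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
is_genotype_matrix <- function(x) inherits(x, "genotype_matrix")

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites, ploidy %d\n",
              nrow(x$calls), ncol(x$calls), x$ploidy))
  print(table(x$pop_labels))
  invisible(x)
}

#' Build a two-population site frequency spectrum from genotypes
#'
#' Tallies per-site derived-allele dosages in each population into a joint
#' spectrum. Calls with posterior probability `<= min_quality` are treated as
#' missing (the default 0.95 keeps only calls with probability strictly above
#' 0.95). Sites left with missing calls are, by default, projected down
#' per-site by the hypergeometric sampling distribution to the largest size at
#' which every retained site is fully called (`missing = "project"`); in
#' strict mode (`missing = "drop"`) any site with a missing call is dropped.
#' Monomorphic sites land in the masked absent/fixed corners.
#'
#' @param geno a [genotype_matrix()] (two populations).
#' @param min_quality calls at or below this posterior probability are
#'   excluded; in `[0, 1]`.
#' @param fold fold the resulting spectrum?
#' @param missing `"project"` (default) or `"drop"`; see above.
#' @param proj_sizes optional explicit target chromosome counts per population
#'   for `missing = "project"`; sites with fewer called chromosomes than the
#'   target are dropped.
#' @return an `"sfs"` object. Attribute `"n_sites_dropped"` records attrition.
#' @export
build_spectrum <- function(geno, min_quality = 0.95, fold = FALSE,
                           missing = c("project", "drop"), proj_sizes = NULL) {
  if (!is_genotype_matrix(geno)) stop("geno must be a genotype_matrix")
  missing <- match.arg(missing)
  if (min_quality < 0 || min_quality > 1) stop("min_quality must be in [0, 1]")
  pops <- levels(geno$pop_labels)
  calls <- geno$calls
  calls[geno$quality <= min_quality] <- NA_integer_
  idx1 <- geno$pop_labels == pops[1]
  idx2 <- geno$pop_labels == pops[2]
  full <- geno$ploidy * c(sum(idx1), sum(idx2))
  # per-site derived totals and called chromosome counts per population
  d1 <- colSums(calls[idx1, , drop = FALSE], na.rm = TRUE)
  d2 <- colSums(calls[idx2, , drop = FALSE], na.rm = TRUE)
  m1 <- geno$ploidy * colSums(!is.na(calls[idx1, , drop = FALSE]))
  m2 <- geno$ploidy * colSums(!is.na(calls[idx2, , drop = FALSE]))

  if (missing == "drop") {
    keep <- m1 == full[1] & m2 == full[2]
    sizes <- full
  } else {
    if (is.null(proj_sizes)) {
      sizes <- c(max(2L, min(m1)), max(2L, min(m2)))
      if (!length(m1)) sizes <- full
    } else {
      sizes <- as.integer(proj_sizes)
    }
    sizes <- pmin(sizes, full)
    keep <- m1 >= sizes[1] & m2 >= sizes[2]
  }
  cnt <- matrix(0, sizes[1] + 1L, sizes[2] + 1L)
  for (s in which(keep)) {
    w1 <- if (m1[s] == sizes[1]) {
      v <- numeric(sizes[1] + 1L); v[d1[s] + 1L] <- 1; v
    } else projection_matrix(m1[s], sizes[1])[d1[s] + 1L, ]
    w2 <- if (m2[s] == sizes[2]) {
      v <- numeric(sizes[2] + 1L); v[d2[s] + 1L] <- 1; v
    } else projection_matrix(m2[s], sizes[2])[d2[s] + 1L, ]
    cnt <- cnt + outer(w1, w2)
  }
  out <- spectrum(cnt, sizes, folded = FALSE)
  if (fold) out <- fold(out)
  attr(out, "n_sites_dropped") <- sum(!keep)
  out
}
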