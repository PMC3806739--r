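#' Identity-by-state allele-sharing matrix
#'
#' For every pair of individuals, the proportion of sites (with both calls
#' non-missing) at which the two carry the same genotype: diploid genotypes
#' compared as dosages in `{0, 1, 2}`, haploid as alleles. Pairs are computed
#' over the pairwise intersection of called sites, with `n_sites_used`
#' reported per pair. An allele-sharing mode (half credit for sharing one of
#' two alleles) is available but off by default, because the statistic of
#' interest is full genotype identity.
#'
#' @param geno a [genotype_matrix()] (>= 2 individuals).
#' @param mode `"genotype"` (default) or `"allele_sharing"`.
#' @return an object of class `"ibs_matrix"`: list with symmetric `values`
#'   (diagonal 1; `NA` and flagged if a pair shares no called sites) and
#'   `n_sites_used`.
#' @export
ibs_matrix <- function(geno, mode = c("genotype", "allele_sharing")) {
  mode <- match.arg(mode)
  if (!is_genotype_matrix(geno)) stop("geno must be a genotype_matrix")
  n <- nrow(geno$calls)
  if (n < 2) stop("need at least two individuals")
  ids <- geno$individuals
  vals <- diag(1, n)
  used <- matrix(0L, n, n)
  diag(used) <- as.integer(rowSums(!is.na(geno$calls)))
  undefined <- character(0)
  for (i in seq_len(n - 1)) {
    gi <- geno$calls[i, ]
    for (j in (i + 1):n) {
      gj <- geno$calls[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      m <- sum(ok)
      used[i, j] <- used[j, i] <- m
      if (m == 0) {
        vals[i, j] <- vals[j, i] <- NA_real_
        undefined <- c(undefined, paste(ids[i], ids[j], sep = "/"))
        next
      }
      v <- if (mode == "genotype") {
        mean(gi[ok] == gj[ok])
      } else {
        mean(1 - abs(gi[ok] - gj[ok]) / geno$ploidy)
      }
      vals[i, j] <- vals[j, i] <- v
    }
  }
  dimnames(vals) <- dimnames(used) <- list(ids, ids)
  if (length(undefined))
    warning("no co-called sites for pair(s): ", paste(undefined, collapse = ", "))
  structure(list(sample_ids = ids, values = vals, n_sites_used = used,
                 undefined_pairs = undefined),
            class = "ibs_matrix")
}

#' @export
print.ibs_matrix <- function(x, ...) {
  cat(sprintf("IBS matrix over %d individuals\n", length(x$sample_ids)))
  print(round(x$values, 4))
  invisible(x)
}

#' Write an IBS matrix as TSV (sample header row/column, both triangles)
#' @param ibs an `"ibs_matrix"`.
#' @param path file path.
#' @export
write_ibs <- function(ibs, path) {
  df <- data.frame(sample = ibs$sample_ids,
                   formatC(ibs$values, format = "f", digits = 6),
                   check.names = FALSE)
  names(df) <- c("sample", ibs$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop sites with heterozygous calls from an mtDNA matrix
#'
#' Raw mtDNA calls come through diploid-style (hom-ref 0, het 1, hom-alt 2);
#' a heterozygous call on the haploid mitochondrion indicates a likely
#' false-positive site. Any site with one or more heterozygous calls is
#' removed genome-wide and the remaining calls are collapsed to haploid
#' alleles (0/2 -> 0/1). The removed fraction is reported as an attribute.
#'
#' @param geno a diploid-encoded [genotype_matrix()] of mtDNA calls.
#' @return a haploid [genotype_matrix()] with attribute
#'   `"fraction_removed"` (in percent of sites).
#' @export
drop_heteroplasmic_sites <- function(geno) {
  if (!is_genotype_matrix(geno)) stop("geno must be a genotype_matrix")
  if (geno$ploidy != 2)
    stop("expects diploid-encoded raw calls (het = 1)")
  het <- colSums(geno$calls == 1L, na.rm = TRUE) > 0
  keep <- which(!het)
  calls <- geno$calls[, keep, drop = FALSE] / 2L
  out <- genotype_matrix(calls, geno$pop_labels,
                         quality = geno$quality[, keep, drop = FALSE],
                         site_ids = geno$site_ids[keep], ploidy = 1L,
                         individuals = geno$individuals)
  attr(out, "fraction_removed") <- 100 * mean(het)
  out
}

#' SNP density as bases per SNP
#'
#' `n_callable / n_snps`: e.g. 1,090 SNPs among 13,648 callable sites is one
#' SNP every 12.5 bases.
#'
#' @param n_snps number of SNPs (> 0).
#' @param n_callable number of callable sites.
#' @export
snp_density <- function(n_snps, n_callable) {
  if (any(n_snps <= 0)) stop("n_snps must be positive")
  n_callable / n_snps
}
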