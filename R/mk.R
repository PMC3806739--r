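#' McDonald-Kreitman tables
#'
#' A McDonald-Kreitman (MK) table holds, per gene (or genome-wide), the
#' counts of fixed non-synonymous (`D_n`) and synonymous (`D_s`) differences
#' to the outgroup, the non-synonymous (`P_n`) and synonymous (`P_s`)
#' polymorphisms, and the aligned non-synonymous (`L_n`) and synonymous
#' (`L_s`) lengths in bases.
#'
#' @param gene_id character identifiers.
#' @param D_n,D_s,P_n,P_s non-negative integer counts.
#' @param L_n,L_s aligned lengths in bases (positive when rates are wanted).
#' @return a `data.frame` with class `"mk_table"` prepended.
#' @export
mk_table <- function(gene_id, D_n, D_s, P_n, P_s, L_n = NA, L_s = NA) {
  df <- data.frame(gene_id = as.character(gene_id),
                   D_n = D_n, D_s = D_s, P_n = P_n, P_s = P_s,
                   L_n = L_n, L_s = L_s, stringsAsFactors = FALSE)
  if (any(df[c("D_n", "D_s", "P_n", "P_s")] < 0, na.rm = TRUE))
    stop("MK counts must be non-negative")
  class(df) <- c("mk_table", class(df))
  df
}

#' Read / write MK tables as TSV
#'
#' Columns: `gene_id`, `D_n`, `D_s`, `P_n`, `P_s`, `L_n`, `L_s`.
#' @param path file path.
#' @export
read_mk_tables <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "D_n", "D_s", "P_n", "P_s", "L_n", "L_s")
  if (!all(need %in% names(df)))
    stop("MK table file must have columns: ", paste(need, collapse = ", "))
  do.call(mk_table, df[need])
}

#' @rdname read_mk_tables
#' @param tables an `"mk_table"`.
#' @export
write_mk_tables <- function(tables, path) {
  utils::write.table(as.data.frame(tables), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-site substitution or polymorphism rate, in percent
#'
#' `100 * count / length_bases`.
#' @param count number of differences or SNPs.
#' @param length_bases aligned length in bases (> 0).
#' @export
per_site_rate <- function(count, length_bases) {
  if (any(length_bases <= 0)) stop("length must be positive")
  100 * count / length_bases
}

#' Non-synonymous / synonymous per-site rate ratio, in percent
#'
#' `100 * (column_n / L_n) / (column_s / L_s)` for the fixed (divergence) or
#' polymorphic column of an MK table.
#'
#' @param table an [mk_table()] row (or genome-wide summary row).
#' @param column `"fixed"` or `"polymorphic"`.
#' @export
ns_s_rate_ratio <- function(table, column = c("fixed", "polymorphic")) {
  column <- match.arg(column)
  cn <- if (column == "fixed") table$D_n else table$P_n
  cs <- if (column == "fixed") table$D_s else table$P_s
  rs <- per_site_rate(cs, table$L_s)
  if (any(rs == 0)) stop("zero synonymous rate")
  100 * per_site_rate(cn, table$L_n) / rs
}

#' McDonald-Kreitman chi-square test of independence
#'
#' Pearson chi-square on the 2x2 table (D_s, P_s; D_n, P_n), with the Yates
#' continuity correction by default (the correction is clamped at zero
#' difference). One degree of freedom.
#'
#' @param table an [mk_table()] row.
#' @param continuity_correction apply the Yates correction?
#' @return list with `statistic` and `p_value`.
#' @export
mk_chi2 <- function(table, continuity_correction = TRUE) {
  # genome-scale cross products overflow integer arithmetic
  a <- as.numeric(table$D_s); b <- as.numeric(table$P_s)
  c <- as.numeric(table$D_n); d <- as.numeric(table$P_n)
  N <- a + b + c + d
  R1 <- a + b; R2 <- c + d; C1 <- a + c; C2 <- b + d
  if (any(c(R1, R2, C1, C2) == 0)) stop("zero margin in MK 2x2 table")
  dev <- abs(a * d - b * c)
  if (continuity_correction) dev <- max(dev - N / 2, 0)
  stat <- N * dev^2 / (R1 * R2 * C1 * C2)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Filter genes for selection analysis
#'
#' Keeps genes with at least two non-synonymous mutations in either the
#' fixed or the polymorphic column: `max(D_n, P_n) >= 2` (default), or
#' `D_n + P_n >= 2` under `rule = "sum"`.
#'
#' @param tables an [mk_table()].
#' @param rule `"max"` (default) or `"sum"`.
#' @export
filter_genes <- function(tables, rule = c("max", "sum")) {
  rule <- match.arg(rule)
  keep <- if (rule == "max") pmax(tables$D_n, tables$P_n) >= 2
          else tables$D_n + tables$P_n >= 2
  tables[keep, , drop = FALSE]
}

#' Genome-wide MK summary table from printed study counts
#'
#' The fixed worked-example inputs for the two orang-utan populations
#' (Bornean, Sumatran) versus the human outgroup: fixed synonymous and
#' non-synonymous differences, polymorphism counts, and total aligned
#' synonymous (1.73 Mb) and non-synonymous (5.03 Mb) lengths.
#'
#' @return an [mk_table()] with two rows (`bornean`, `sumatran`).
#' @export
orangutan_mk_summary <- function() {
  mk_table(gene_id = c("bornean", "sumatran"),
           D_n = c(33701, 33198), D_s = c(50177, 50011),
           P_n = c(4042, 4847), P_s = c(5302, 7076),
           L_n = c(5.03e6, 5.03e6), L_s = c(1.73e6, 1.73e6))
}

#' Summarise gene classifications
#'
#' @param estimates a data.frame from [fit_random_effects_mk()] with a
#'   `classification` column.
#' @return named integer vector of counts (negative, neutral, positive).
#' @export
classify_genes <- function(estimates) {
  lv <- c("negative", "neutral", "positive")
  cl <- factor(estimates$classification, levels = lv)
  out <- table(cl)
  stats::setNames(as.integer(out), lv)
}
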