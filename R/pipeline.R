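#' Read a VCF into a genotype matrix
#'
#' Keeps biallelic SNPs only (multi-allelic records are skipped with a
#' logged count); genotypes become allele dosages, missing calls `NA`.
#' Phred-scaled `GQ`, when present, is mapped to a posterior probability
#' `1 - 10^(-GQ/10)`; otherwise quality is 1. Site ids preserve the 1-based
#' VCF coordinates as `CHROM:POS`.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param pop_map named character vector mapping every sample to one of two
#'   populations.
#' @param ploidy 2 (autosomes) or 1-as-diploid-encoded mtDNA (keep 2 and use
#'   [drop_heteroplasmic_sites()]).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, pop_map, ploidy = 2L) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  ref1 <- nchar(as.character(VariantAnnotation::ref(vcf))) == 1L
  altl <- VariantAnnotation::alt(vcf)
  bi <- lengths(altl) == 1L
  alt1 <- rep(FALSE, length(vcf))
  alt1[bi] <- nchar(as.character(unlist(altl[bi]))) == 1L
  keep <- ref1 & bi & alt1
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP records", n_skipped))
  vcf <- vcf[keep]
  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  if (!all(samples %in% names(pop_map)))
    stop("samples missing from pop_map: ",
         paste(setdiff(samples, names(pop_map)), collapse = ", "))
  dosage <- function(g) {
    if (g %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  }
  calls <- t(apply(gt, c(1, 2), dosage)[, , drop = FALSE])
  qual <- matrix(1, nrow(calls), ncol(calls))
  gq <- tryCatch(VariantAnnotation::geno(vcf)$GQ, error = function(e) NULL)
  if (!is.null(gq)) {
    q <- 1 - 10^(-t(gq) / 10)
    q[is.na(q)] <- 1
    qual <- q
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  site_ids <- sprintf("%s:%d", as.character(GenomicRanges::seqnames(rr)),
                      GenomicRanges::start(rr))
  genotype_matrix(calls, pop_labels = unname(pop_map[samples]),
                  quality = qual, site_ids = site_ids, ploidy = ploidy,
                  individuals = samples)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Site ids of the form `CHROM:POS` are used for coordinates; alleles are
#' written as placeholder `A`/`T` (the container does not track nucleotides).
#' Genotype fields round-trip through [read_vcf()].
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(geno, path) {
  parts <- strsplit(geno$site_ids, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  pos <- vapply(parts, function(p)
    if (length(p) > 1) p[2] else "0", character(1))
  gt_of <- function(d) {
    if (is.na(d)) return("./.")
    c("0/0", "0/1", "1/1")[d + 1L]
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geno$individuals), collapse = "\t"))
  rows <- vapply(seq_along(geno$site_ids), function(s) {
    paste(c(chrom[s], pos[s], geno$site_ids[s], "A", "T", ".", "PASS", ".",
            "GT", vapply(geno$calls[, s], gt_of, character(1))),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Partition sites by functional annotation
#'
#' @param geno a [genotype_matrix()].
#' @param annotation data.frame with columns `site_id` and `class` in
#'   `synonymous` / `non_synonymous` / `non_coding`. Unannotated sites
#'   default to non-coding (logged); duplicate conflicting annotations are
#'   an error.
#' @return named list of three genotype matrices (possibly with zero sites):
#'   `synonymous`, `non_synonymous`, `non_coding`.
#' @export
annotate_sites <- function(geno, annotation) {
  stopifnot(all(c("site_id", "class") %in% names(annotation)))
  dup <- annotation$site_id[duplicated(annotation$site_id)]
  if (length(dup)) {
    conf <- vapply(unique(dup), function(s)
      length(unique(annotation$class[annotation$site_id == s])) > 1,
      logical(1))
    if (any(conf))
      stop("conflicting duplicate annotations for: ",
           paste(unique(dup)[conf], collapse = ", "))
    annotation <- annotation[!duplicated(annotation$site_id), ]
  }
  cls <- annotation$class[match(geno$site_ids, annotation$site_id)]
  n_un <- sum(is.na(cls))
  if (n_un > 0)
    message(sprintf("annotate_sites: %d unannotated sites -> non_coding", n_un))
  cls[is.na(cls)] <- "non_coding"
  bad <- setdiff(unique(cls), c("synonymous", "non_synonymous", "non_coding"))
  if (length(bad)) stop("unknown annotation classes: ", paste(bad, collapse = ", "))
  subset_sites <- function(keep) {
    idx <- which(keep)
    genotype_matrix(geno$calls[, idx, drop = FALSE], geno$pop_labels,
                    quality = geno$quality[, idx, drop = FALSE],
                    site_ids = geno$site_ids[idx], ploidy = geno$ploidy,
                    individuals = geno$individuals)
  }
  list(synonymous = subset_sites(cls == "synonymous"),
       non_synonymous = subset_sites(cls == "non_synonymous"),
       non_coding = subset_sites(cls == "non_coding"))
}

# small dependency-free polynomial content hash for provenance logging
# (double arithmetic mod a Mersenne prime: stays exact below 2^53)
content_hash <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param vcf,annotation,mk_tables input file paths (VCF; site-annotation
#'   TSV with `site_id`, `class`; MK-table TSV). `NULL` stages are skipped.
#' @param pop_map named vector sample -> population.
#' @param out_dir output directory.
#' @param seed integer seed covering every stochastic stage.
#' @param demography,grid,solver,fit,filters,mcmc stage-parameter lists;
#'   missing entries take the package defaults.
#' @export
run_config <- function(vcf = NULL, annotation = NULL, mk_tables = NULL,
                       pop_map = NULL, out_dir = "popgensel_out", seed = 1L,
                       demography = list(), grid = list(), solver = list(),
                       fit = list(), filters = list(), mcmc = list()) {
  cfg <- list(
    vcf = vcf, annotation = annotation, mk_tables = mk_tables,
    pop_map = pop_map, out_dir = out_dir, seed = as.integer(seed),
    demography = utils::modifyList(as.list(formals(demographic_model))[
      c("N_anc", "T_split", "nu1_0", "nu1", "nu2_0", "nu2", "m12", "m21")],
      demography),
    grid = utils::modifyList(list(n_negative = 44, n_positive = 15), grid),
    solver = utils::modifyList(sfs_solver_control(), solver),
    fit = utils::modifyList(list(families = c("point_lethal", "expon_lethal",
                                              "norm_lethal", "gamma"),
                                 theta_ratio = 2.5, n_restarts = 3), fit),
    filters = utils::modifyList(list(min_quality = 0.95, gene_rule = "max",
                                     project_sizes = c(8, 8)), filters),
    mcmc = utils::modifyList(mk_mcmc_settings(), mcmc))
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' Top-level keys mirror the arguments of [run_config()]. Referenced input
#' files must exist.
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$pop_map)) y$pop_map <- unlist(y$pop_map)
  cfg <- do.call(run_config, y)
  for (f in c("vcf", "annotation", "mk_tables"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(sprintf("input file for '%s' does not exist: %s", f, cfg[[f]]))
  cfg
}

log_stage <- function(log_path, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Executes: VCF ingest, annotation partition, spectrum build, projection to
#' the configured sizes, folding, spectra-cache construction, DFE fits per
#' family, MK summary statistics and chi-square, gene filtering, the
#' random-effects gene classifier, and IBS -- writing a summary-table bundle
#' (MK rates/ratios table, DFE class-mass table, classified-gene list,
#' spectra and residual data files, cumulative-DFE data files, IBS matrix)
#' plus a structured run log with every parameter, seed and input hash.
#' Any stage failure aborts with the stage name; outputs written so far
#' persist.
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @return invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run_log.jsonl")
  paths <- list(log = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  log_stage(log_path, "config", config = config[setdiff(names(config),
                                                        c("pop_map"))],
            seed = config$seed)

  dem <- do.call(demographic_model, config$demography)
  grid <- selection_grid(n_negative = config$grid$n_negative,
                         n_positive = config$grid$n_positive)
  ctl <- do.call(sfs_solver_control, config$solver)
  psz <- config$filters$project_sizes

  spectra <- NULL
  if (!is.null(config$vcf)) {
    geno <- stage("read_vcf", read_vcf(config$vcf, config$pop_map))
    log_stage(log_path, "read_vcf", n_sites = length(geno$site_ids),
              hash = content_hash(config$vcf))
    ann <- stage("annotate", {
      a <- utils::read.delim(config$annotation, stringsAsFactors = FALSE)
      annotate_sites(geno, a)
    })
    spectra <- stage("build_spectra", lapply(ann, function(g) {
      if (!length(g$site_ids)) return(NULL)
      # build directly at the projection target: fully-called sites project
      # down hypergeometrically, sites below the target are dropped
      s <- build_spectrum(g, min_quality = config$filters$min_quality,
                          missing = "project", proj_sizes = psz)
      fold(s)
    }))
    for (nm in names(spectra)) {
      if (is.null(spectra[[nm]])) next
      p <- file.path(out, sprintf("sfs_%s.txt", nm))
      write_spectrum(spectra[[nm]], p)
      paths[[paste0("sfs_", nm)]] <- p
      log_stage(log_path, "spectrum", category = nm,
                segregating = segregating_total(spectra[[nm]]))
    }
    # residual comparison data files (second spectrum rescaled to the first)
    resid_pairs <- list(c("non_synonymous", "synonymous"),
                        c("synonymous", "non_coding"))
    for (pr in resid_pairs) {
      a <- spectra[[pr[1]]]; b <- spectra[[pr[2]]]
      if (is.null(a) || is.null(b)) next
      r <- residual_spectrum(a, rescale_to_segregating(b, segregating_total(a)))
      p <- file.path(out, sprintf("residuals_%s_vs_%s.tsv", pr[1], pr[2]))
      utils::write.table(r, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      paths[[basename(p)]] <- p
    }
  }

  if (!is.null(spectra) && !is.null(spectra$non_synonymous)) {
    cache <- stage("cache", build_cache(dem, grid, psz, control = ctl))
    log_stage(log_path, "cache", n_gamma = length(grid$gamma_values))
    syn_tot <- segregating_total(spectra$synonymous)
    th_syn <- syn_tot / segregating_total(cache_spectrum_at(cache, 0))
    th_non <- config$fit$theta_ratio * th_syn
    fits <- list()
    for (fam in config$fit$families) {
      fits[[fam]] <- stage(paste0("fit_", fam),
        fit_dfe(spectra$non_synonymous, cache, fam, theta_non = th_non,
                n_restarts = config$fit$n_restarts, seed = config$seed))
      rp <- file.path(out, sprintf("dfe_fit_%s.txt", fam))
      write_fit_report(fits[[fam]], rp)
      paths[[basename(rp)]] <- rp
      log_stage(log_path, "fit_dfe", family = fam,
                loglik = fits[[fam]]$loglik, theta_non = th_non)
    }
    ct <- dfe_class_table(fits, N_anc = dem$N_anc)
    p <- file.path(out, "dfe_class_table.tsv")
    utils::write.table(ct, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$dfe_class_table <- p
    # cumulative distribution of s data file per family
    svals <- -10^seq(log10(2000 / (2 * dem$N_anc)), -8, length.out = 200)
    cum <- data.frame(s = svals)
    for (fam in names(fits)) {
      dfe <- fits[[fam]]$dfe; pr <- dfe$params
      cum[[fam]] <- switch(fam,
        point_lethal = (1 - pr$p_point) +
          pr$p_point * (pr$gamma_point / (2 * dem$N_anc) <= svals),
        expon_lethal = pr$p_lethal + (1 - pr$p_lethal) *
          stats::pexp(-svals * 2 * dem$N_anc, rate = 1 / pr$mean,
                      lower.tail = FALSE),
        norm_lethal = pr$p_lethal + (1 - pr$p_lethal) *
          stats::pnorm(svals * 2 * dem$N_anc, pr$mean, pr$sd),
        gamma = stats::pgamma(-svals * 2 * dem$N_anc, shape = pr$shape,
                              scale = pr$scale, lower.tail = FALSE))
    }
    p <- file.path(out, "dfe_cumulative.tsv")
    utils::write.table(cum, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$dfe_cumulative <- p
  }

  if (!is.null(config$mk_tables)) {
    tabs <- stage("mk_tables", read_mk_tables(config$mk_tables))
    log_stage(log_path, "mk_tables", n_genes = nrow(tabs),
              hash = content_hash(config$mk_tables))
    tot <- mk_table("genome",
                    D_n = sum(tabs$D_n), D_s = sum(tabs$D_s),
                    P_n = sum(tabs$P_n), P_s = sum(tabs$P_s),
                    L_n = sum(tabs$L_n), L_s = sum(tabs$L_s))
    chi <- mk_chi2(tot)
    summ <- data.frame(
      category = c("Syn", "Non-Syn"),
      divergence = c(tot$D_s, tot$D_n),
      divergence_pct = c(per_site_rate(tot$D_s, tot$L_s),
                         per_site_rate(tot$D_n, tot$L_n)),
      polymorphism = c(tot$P_s, tot$P_n),
      polymorphism_pct = c(per_site_rate(tot$P_s, tot$L_s),
                           per_site_rate(tot$P_n, tot$L_n)))
    p <- file.path(out, "mk_summary.tsv")
    utils::write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("Non-Syn/Syn divergence ratio: %.2f%%\n",
                ns_s_rate_ratio(tot, "fixed")),
        sprintf("Non-Syn/Syn polymorphism ratio: %.2f%%\n",
                ns_s_rate_ratio(tot, "polymorphic")),
        sprintf("chi2 = %.2f, p = %.3g\n", chi$statistic, chi$p_value),
        file = p, append = TRUE, sep = "")
    paths$mk_summary <- p
    filt <- filter_genes(tabs, rule = config$filters$gene_rule)
    log_stage(log_path, "filter_genes", kept = nrow(filt),
              dropped = nrow(tabs) - nrow(filt))
    est <- stage("classify",
      fit_random_effects_mk(filt, mcmc = config$mcmc, seed = config$seed))
    p <- file.path(out, "gene_classification.tsv")
    write_gene_report(est, p)
    paths$gene_classification <- p
    log_stage(log_path, "classify",
              counts = as.list(classify_genes(est)),
              rhat = as.list(round(attr(est, "rhat"), 4)))
  }

  if (!is.null(config$vcf)) {
    ibs <- stage("ibs", ibs_matrix(geno))
    p <- file.path(out, "ibs_matrix.tsv")
    write_ibs(ibs, p)
    paths$ibs <- p
  }
  log_stage(log_path, "done")
  invisible(paths)
}
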