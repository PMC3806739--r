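#' Simulation configuration
#'
#' Bundles everything the synthetic-data generators need. Defaults mirror the
#' scale of the two-population orang-utan study this package emulates:
#' folded 8+8-chromosome spectra with roughly 6,900 synonymous and 4,900
#' non-synonymous segregating sites, a non-synonymous-to-synonymous mutation
#' influx ratio of 2.5, and MK tables for ~500 genes at genome-average
#' per-base rates.
#'
#' @param model a [demographic_model()].
#' @param dfe a [dfe_model()], or `NULL` to use the fixed `gamma`.
#' @param gamma fixed scaled selection coefficient (used when `dfe` is NULL).
#' @param sizes chromosome counts per population.
#' @param theta_syn synonymous mutation influx; `NULL` derives it so the
#'   expected neutral (synonymous) spectrum has `target_syn_segregating`
#'   segregating sites.
#' @param theta_ratio `theta_non / theta_syn` (study constraint: 2.5).
#' @param target_syn_segregating see `theta_syn`.
#' @param n_genes,mean_L_n,mean_L_s,length_sdlog per-gene MK model: number of
#'   genes and log-normal aligned-length distributions.
#' @param mk_beta fixed effects `(b0, bR, bF, bRF)` of the log-linear MK
#'   model; defaults are the genome-wide per-base rates implied by the
#'   study's printed summary table.
#' @param sigma_u,sigma_v standard deviations of the gene-level constraint
#'   and selection effects.
#' @param missingness,low_quality_rate per-call rates used by
#'   [simulate_genotypes()] to exercise the missing-data and quality filters.
#' @param seed integer seed (mandatory).
#' @export
simulation_config <- function(model = demographic_model(), dfe = NULL,
                              gamma = 0, sizes = c(8, 8),
                              theta_syn = NULL, theta_ratio = 2.5,
                              target_syn_segregating = 6938,
                              n_genes = 500, mean_L_n = 750, mean_L_s = 250,
                              length_sdlog = 0.5,
                              mk_beta = c(b0 = log(0.0031),
                                          bR = log(0.08 / 0.31),
                                          bF = log(2.90 / 0.31),
                                          bRF = log((0.67 / 0.08) / (2.90 / 0.31))),
                              sigma_u = 0.3, sigma_v = 0,
                              missingness = 0, low_quality_rate = 0,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(model = model, dfe = dfe, gamma = gamma,
                 sizes = as.integer(sizes), theta_syn = theta_syn,
                 theta_ratio = theta_ratio,
                 target_syn_segregating = target_syn_segregating,
                 n_genes = n_genes, mean_L_n = mean_L_n, mean_L_s = mean_L_s,
                 length_sdlog = length_sdlog, mk_beta = mk_beta,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 missingness = missingness,
                 low_quality_rate = low_quality_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# expected (noise-free) spectrum implied by a config; theta_syn resolved
# against the neutral segregating target if not given
config_expected_sfs <- function(config, cache = NULL,
                                control = sfs_solver_control(),
                                category = c("non", "syn")) {
  category <- match.arg(category)
  neutral <- if (!is.null(cache)) cache_spectrum_at(cache, 0)
  else expected_sfs(config$model, 0, config$sizes, control = control)
  th_syn <- config$theta_syn
  if (is.null(th_syn))
    th_syn <- config$target_syn_segregating / segregating_total(neutral)
  if (category == "syn") {
    out <- neutral
    out$counts <- th_syn * out$counts
    return(out)
  }
  th_non <- config$theta_ratio * th_syn
  if (!is.null(config$dfe)) {
    if (is.null(cache))
      stop("a spectra cache is required to simulate under a DFE")
    expected_sfs_under_dfe(cache, config$dfe, th_non)
  } else {
    s <- if (!is.null(cache)) cache_spectrum_at(cache, config$gamma)
    else expected_sfs(config$model, config$gamma, config$sizes,
                      control = control)
    s$counts <- th_non * s$counts
    s
  }
}

#' Simulate an observed spectrum
#'
#' Independent Poisson draws around the expected spectrum implied by the
#' configuration (fixed-gamma, or mixture-DFE when `config$dfe` is set) --
#' the exact generative model of the Poisson random field likelihood.
#' Bit-reproducible given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param cache optional `"sfs_cache"` (required for DFE simulation; avoids
#'   re-solving the diffusion otherwise).
#' @param category `"non"` (non-synonymous, selected) or `"syn"`
#'   (synonymous, neutral).
#' @param control solver settings when no cache is supplied.
#' @return an unfolded 2D `"sfs"` of integer counts.
#' @export
simulate_sfs <- function(config, cache = NULL, category = c("non", "syn"),
                         control = sfs_solver_control()) {
  mu <- config_expected_sfs(config, cache, control, match.arg(category))
  set.seed(config$seed)
  out <- mu
  i <- !mu$mask
  out$counts[i] <- stats::rpois(sum(i), mu$counts[i])
  out$counts[mu$mask] <- 0
  out
}

#' Simulate a two-population genotype matrix
#'
#' Draws site frequency bins from the normalised expected spectrum, assigns
#' each population a true allele frequency at the bin's frequency, and
#' samples individual dosages binomially. Injects missing calls and
#' sub-threshold genotype qualities at the configured rates so the
#' spectrum-building filters can be exercised. Bit-reproducible given
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param n_sites number of segregating sites to draw.
#' @param n_ind individuals per population (default `sizes / 2`).
#' @param cache,control as in [simulate_sfs()].
#' @return a [genotype_matrix()] with populations `"pop1"`, `"pop2"`.
#' @export
simulate_genotypes <- function(config, n_sites, n_ind = NULL, cache = NULL,
                               control = sfs_solver_control()) {
  if (n_sites <= 0) stop("n_sites must be positive")
  mu <- config_expected_sfs(config, cache, control, "non")
  set.seed(config$seed + 1L)
  n1 <- mu$sample_sizes[1]; n2 <- mu$sample_sizes[2]
  if (is.null(n_ind)) n_ind <- c(n1, n2) %/% 2L
  pr <- mu$counts
  pr[mu$mask] <- 0
  bins <- sample.int(length(pr), n_sites, replace = TRUE, prob = as.numeric(pr))
  ij <- arrayInd(bins, dim(pr)) - 1L
  p1 <- ij[, 1] / n1; p2 <- ij[, 2] / n2
  calls <- rbind(
    matrix(stats::rbinom(n_ind[1] * n_sites, 2, rep(p1, each = n_ind[1])),
           n_ind[1], n_sites),
    matrix(stats::rbinom(n_ind[2] * n_sites, 2, rep(p2, each = n_ind[2])),
           n_ind[2], n_sites))
  if (config$missingness > 0)
    calls[stats::runif(length(calls)) < config$missingness] <- NA_integer_
  qual <- matrix(1, nrow(calls), ncol(calls))
  if (config$low_quality_rate > 0) {
    low <- stats::runif(length(qual)) < config$low_quality_rate
    qual[low] <- stats::runif(sum(low), 0.5, 0.95)
  }
  genotype_matrix(calls,
                  pop_labels = rep(c("pop1", "pop2"), n_ind),
                  quality = qual,
                  site_ids = sprintf("chr1:%d", seq_len(n_sites) * 100L),
                  ploidy = 2L)
}

#' Simulate per-gene MK tables with known selection effects
#'
#' Generates Poisson counts from the same log-linear structure assumed by
#' [fit_random_effects_mk()]: aligned lengths log-normal, gene-level
#' constraint effects `u ~ N(0, sigma_u^2)` and selection effects
#' `v ~ N(0, sigma_v^2)` (or supplied explicitly via `v_effects`).
#'
#' @param config a [simulation_config()].
#' @param v_effects optional explicit vector of per-gene selection effects
#'   (length `n_genes`), overriding `sigma_v`.
#' @return list with `tables` (an [mk_table()]) and `truth`
#'   (`gene_id`, `u`, `v`, `label` in negative/neutral/positive).
#' @export
simulate_mk_tables <- function(config, v_effects = NULL) {
  set.seed(config$seed + 2L)
  G <- config$n_genes
  if (G < 1) stop("need at least one gene")
  sdl <- config$length_sdlog
  Ln <- round(stats::rlnorm(G, log(config$mean_L_n) - sdl^2 / 2, sdl))
  Ls <- round(stats::rlnorm(G, log(config$mean_L_s) - sdl^2 / 2, sdl))
  Ln <- pmax(Ln, 30L); Ls <- pmax(Ls, 30L)
  u <- stats::rnorm(G, 0, config$sigma_u)
  v <- if (is.null(v_effects)) stats::rnorm(G, 0, config$sigma_v)
  else {
    stopifnot(length(v_effects) == G)
    v_effects
  }
  b <- config$mk_beta
  lam_Ps <- Ls * exp(b[1])
  lam_Pn <- Ln * exp(b[1] + b[2] + u)
  lam_Ds <- Ls * exp(b[1] + b[3])
  lam_Dn <- Ln * exp(b[1] + b[2] + b[3] + b[4] + u + v)
  tab <- mk_table(gene_id = sprintf("gene%04d", seq_len(G)),
                  D_n = stats::rpois(G, lam_Dn), D_s = stats::rpois(G, lam_Ds),
                  P_n = stats::rpois(G, lam_Pn), P_s = stats::rpois(G, lam_Ps),
                  L_n = Ln, L_s = Ls)
  truth <- data.frame(gene_id = tab$gene_id, u = u, v = v,
                      label = ifelse(v > 0, "positive",
                                     ifelse(v < 0, "negative", "neutral")),
                      stringsAsFactors = FALSE)
  list(tables = tab, truth = truth)
}

#' Simulate haploid mtDNA haplotypes with heteroplasmy artifacts
#'
#' Haplotypes evolve on a random coalescent genealogy (two root clades define
#' the population labels); mutations are Poisson with expected count
#' `n_sites * density` and are placed on branches proportionally to branch
#' length, so every variant is a clean clade-defining biallelic site.
#' Spurious heterozygous calls are injected at rate `het_rate` per site (one
#' random carrier each), emulating the <1 percent heteroplasmy-like artifact
#' of real mtDNA calling. Calls are returned diploid-encoded (0/1/2) for
#' [drop_heteroplasmic_sites()].
#'
#' @param n_samples number of haploid samples (>= 4).
#' @param n_sites number of callable sites.
#' @param density expected SNPs per callable site, in (0, 1].
#' @param het_rate per-site probability of a spurious heterozygous call.
#' @param seed integer seed.
#' @return a diploid-encoded [genotype_matrix()] with clade pop labels.
#' @export
simulate_mtdna <- function(n_samples, n_sites, density = 1 / 12.5,
                           het_rate = 0.01, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (n_samples < 4) stop("need at least 4 samples")
  set.seed(seed)
  tree <- ape::rcoal(n_samples)
  n_snps <- stats::rpois(1, n_sites * density)
  n_snps <- min(n_snps, n_sites)
  edge_len <- tree$edge.length
  mut_edges <- sample.int(nrow(tree$edge), n_snps, replace = TRUE,
                          prob = edge_len)
  # carriers of each mutation: tips descending from the mutated edge
  desc <- function(node) {
    if (node <= n_samples) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  calls <- matrix(0L, n_samples, n_snps)
  for (k in seq_len(n_snps)) {
    tips <- desc(tree$edge[mut_edges[k], 2])
    if (length(tips) == n_samples) tips <- tips[-1]  # keep site polymorphic
    calls[tips, k] <- 2L
  }
  # spurious heterozygous calls
  het_sites <- which(stats::runif(n_snps) < het_rate)
  for (k in het_sites) calls[sample.int(n_samples, 1), k] <- 1L
  # clade labels from the two children of the root
  root <- n_samples + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  cladeA <- desc(kids[1])
  labels <- ifelse(seq_len(n_samples) %in% cladeA, "cladeA", "cladeB")
  if (length(unique(labels)) == 1L) labels[1] <- "cladeB"
  positions <- sort(sample.int(n_sites, n_snps))
  genotype_matrix(calls, pop_labels = labels,
                  site_ids = sprintf("mt:%d", positions), ploidy = 2L,
                  individuals = tree$tip.label)
}
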