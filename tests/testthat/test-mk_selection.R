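# McDonald-Kreitman statistics and the gene filter/classifier plumbing.

test_that("per-site rates reproduce the genome-wide summary values", {
  expect_equal(round(per_site_rate(50177, 1.73e6), 2), 2.90)
  expect_equal(round(per_site_rate(33701, 5.03e6), 2), 0.67)
  expect_equal(per_site_rate(0, 1000), 0)
  expect_error(per_site_rate(10, 0), "positive")
})

test_that("NS/S rate ratios reproduce the published polymorphism ratios", {
  tab <- orangutan_mk_summary()
  expect_equal(round(ns_s_rate_ratio(tab[1, ], "polymorphic"), 2), 26.22)
  expect_equal(round(ns_s_rate_ratio(tab[2, ], "polymorphic"), 2), 23.56)
  equal <- mk_table("x", 10, 10, 10, 10, 100, 100)
  expect_equal(ns_s_rate_ratio(equal, "fixed"), 100)
  # scale invariance: doubling all counts and lengths changes nothing
  tab2 <- tab[1, ]
  for (cl in c("D_n", "D_s", "P_n", "P_s", "L_n", "L_s"))
    tab2[[cl]] <- 2 * tab2[[cl]]
  expect_equal(ns_s_rate_ratio(tab2, "polymorphic"),
               ns_s_rate_ratio(tab[1, ], "polymorphic"))
})

test_that("mk_chi2 reproduces the corrected statistic and hand formulas", {
  tab <- orangutan_mk_summary()
  chi <- mk_chi2(tab[1, ], continuity_correction = TRUE)
  expect_equal(round(chi$statistic, 2), 32.95)
  expect_lt(chi$p_value, 1e-7)
  # proportional table: statistic 0, p 1
  prop <- mk_table("p", D_n = 20, D_s = 10, P_n = 10, P_s = 5, L_n = 1, L_s = 1)
  chi0 <- mk_chi2(prop, continuity_correction = FALSE)
  expect_equal(chi0$statistic, 0)
  expect_equal(chi0$p_value, 1)
  # hand-computed uncorrected Pearson for (10,5;5,10)
  hand <- mk_table("h", D_s = 10, P_s = 5, D_n = 5, P_n = 10, L_n = 1, L_s = 1)
  expect_equal(mk_chi2(hand, continuity_correction = FALSE)$statistic,
               30 * (10 * 10 - 5 * 5)^2 / (15 * 15 * 15 * 15),
               tolerance = 1e-12)
  # transpose symmetry (swap rows with columns)
  tr <- mk_table("t", D_s = 10, P_n = 7, P_s = 5, D_n = 3, L_n = 1, L_s = 1)
  sw <- mk_table("t", D_s = 10, P_n = 7, P_s = 3, D_n = 5, L_n = 1, L_s = 1)
  expect_equal(mk_chi2(tr)$statistic, mk_chi2(sw)$statistic)
  zero <- mk_table("z", 0, 0, 1, 1, 1, 1)
  expect_error(mk_chi2(zero), "margin")
})

test_that("gene filter applies the max rule (and the sum alternative)", {
  tabs <- mk_table(c("a", "b", "c"),
                   D_n = c(2, 1, 0), D_s = c(1, 1, 1),
                   P_n = c(0, 1, 5), P_s = c(1, 1, 1),
                   L_n = 100, L_s = 100)
  kept <- filter_genes(tabs)
  expect_equal(kept$gene_id, c("a", "c"))
  kept_sum <- filter_genes(tabs, rule = "sum")
  expect_equal(kept_sum$gene_id, c("a", "b", "c"))
})

test_that("classify_genes summarises classifications", {
  expect_equal(unname(classify_genes(data.frame(classification = character(0)))),
               c(0L, 0L, 0L))
  est <- data.frame(classification = c("neutral", "neutral", "positive"))
  expect_equal(unname(classify_genes(est)), c(0L, 2L, 1L))
})

test_that("MK tables round-trip through TSV", {
  tabs <- mk_table(c("g1", "g2"), 3, 4, 5, 6, 100, 50)
  path <- tempfile(fileext = ".tsv")
  write_mk_tables(tabs, path)
  r <- read_mk_tables(path)
  expect_equal(as.data.frame(r), as.data.frame(tabs))
})
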