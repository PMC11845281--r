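# contingency counting, hypergeometric tail, BH adjustment, result table

test_that("hypergeometric upper tail matches hand-computed values", {
  # k = 0 always gives P(X >= 0) = 1
  expect_equal(hypergeom_pvalue(0, 5, 3, 10), 1.0)
  # all 5 draws in the 5-member class: 1 / C(10,5)
  expect_equal(hypergeom_pvalue(5, 5, 5, 10), 1 / 252, tolerance = 1e-14)
  # C(3,2)C(3,1) + C(3,3)C(3,0) over C(6,3) = 10/20
  expect_equal(hypergeom_pvalue(2, 3, 3, 6), 0.5, tolerance = 1e-14)
})

test_that("hypergeometric tail equals the enumeration oracle on random counts", {
  set.seed(5)
  for (rep in 1:200) {
    pick <- function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1)
    N <- pick(2, 25)
    K <- pick(0, N)
    n <- pick(1, N)
    k <- pick(max(0, n + K - N), min(n, K))
    expect_equal(hypergeom_pvalue(k, n, K, N), enum_upper_tail(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("invalid contingency counts are rejected", {
  expect_error(hypergeom_pvalue(3, 2, 5, 10), "invalid contingency")
  expect_error(hypergeom_pvalue(0, 5, 11, 10), "n <= N and K <= N")
  expect_error(hypergeom_pvalue(-1, 5, 5, 10), "non-negative")
  expect_error(hypergeom_pvalue(0.5, 5, 5, 10), "integer")
  # k below the support floor max(0, n+K-N)
  expect_error(hypergeom_pvalue(0, 8, 8, 10), "invalid contingency")
})

test_that("p-values strictly decrease in k at fixed (N, K, n)", {
  for (k in 3:9) {
    expect_lt(hypergeom_pvalue(k, 10, 12, 40),
              hypergeom_pvalue(k - 1, 10, 12, 40))
  }
})

test_that("fold enrichment is the ratio of the two fractions", {
  expect_equal(fold_enrichment(4, 10, 8, 100), 5.0)
  expect_equal(fold_enrichment(2, 10, 8, 40), 1.0)  # k/n == K/N
  expect_equal(fold_enrichment(0, 10, 8, 100), 0.0)
  expect_error(fold_enrichment(0, 0, 8, 100), "K >= 1 and n >= 1")
  expect_error(fold_enrichment(0, 10, 0, 100), "K >= 1 and n >= 1")
})

test_that("BH adjustment matches the step-up formula and its examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.5, 0.9)), c(0.9, 0.9))
  expect_error(bh_adjust(numeric()), "non-empty")
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(31)
  for (rep in 1:50) {
    p <- stats::runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(adj >= p) && all(adj <= 1))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-14)
  }
})

test_that("the query derives universe and effective foreground", {
  t2g <- build_term2gene(toy_annotation(), toy_catalog())
  q <- make_query(c("g1"), c("g1", "g2"), t2g)
  expect_identical(q$universe, c("g1", "g2"))
  expect_identical(q$effective_foreground, "g1")

  # gX not in background: dropped with a warning
  expect_warning(q2 <- make_query(c("g1", "gX"), c("g1", "g2"), t2g),
                 "absent from the background")
  expect_identical(unname(q2$dropped["fg_not_in_background"]), 1L)

  # g6 has no pathway annotation: excluded from the universe
  q3 <- make_query("g1", c("g1", "g2", "g6"), t2g)
  expect_false("g6" %in% q3$universe)
  expect_identical(unname(q3$dropped["bg_unannotated"]), 1L)

  expect_error(make_query("g6", c("g1", "g6"), t2g), "no annotated foreground")
})

test_that("foreground == background forces p = 1 and fold = 1 everywhere", {
  fit <- toy_fit(foreground = paste0("g", 1:6), background = paste0("g", 1:6))
  expect_true(all(fit$table$p_value == 1))
  expect_true(all(fit$table$fold_enrichment == 1))
  expect_true(all(fit$table$k == fit$table$K))
})

test_that("a single tested pathway reproduces the enumeration oracle and m = 1", {
  # universe of 20 genes, one 5-member pathway, foreground of 6 with 4 members
  genes <- sprintf("u%02d", 1:20)
  entries <- as.list(rep("K00002", 20))  # filler KO outside any pathway? no:
  names(entries) <- genes
  # first 5 genes carry the pathway KO, the rest carry another catalog KO
  catalog <- pathway_catalog(list(ko00010 = "K00001", ko00099 = "K00002"),
                             c(ko00010 = "Target", ko00099 = "Filler"))
  entries[1:5] <- "K00001"
  ann <- annotation_map(entries)
  t2g <- build_term2gene(ann, catalog)
  fg <- genes[c(1, 2, 3, 4, 6, 7)]   # 4 of 5 members + 2 others
  q <- make_query(fg, genes, t2g)
  fit <- run_enrichment(q, t2g, drop_empty = FALSE)
  row <- fit$table[fit$table$pathway_id == "ko00010", ]
  expect_identical(c(row$k, row$n, row$K, row$N), c(4L, 6L, 5L, 20L))
  expect_equal(row$p_value, enum_upper_tail(4, 6, 5, 20), tolerance = 1e-12)

  # with the family restricted to that pathway alone, BH leaves p unchanged
  fit1 <- run_enrichment(q, build_term2gene(ann, pathway_catalog(
    list(ko00010 = "K00001"), c(ko00010 = "Target"))), drop_empty = FALSE)
  expect_equal(fit1$table$p_adjusted, fit1$table$p_value)
  expect_identical(fit1$m, 1L)
})

test_that("the spiked pathway of a synthetic fixture ranks first", {
  s <- simulate_study(spike_design(n_genes = 1000, n_pathways = 30,
                                   kos_per_pathway = c(8, 15),
                                   fg_size = 120, spiked_pathway_count = 1,
                                   spike_fraction = 0.5, seed = 1))
  t2g <- build_term2gene(s$annotation, s$catalog)
  fit <- run_enrichment(make_query(s$foreground, s$background, t2g), t2g)
  expect_identical(fit$table$pathway_id[1L], s$truth$pathway_id[1L])
})

test_that("enrichment is invariant to input order and duplicate ids", {
  t2g <- build_term2gene(toy_annotation(), toy_catalog())
  fg <- c("g1", "g2", "g4")
  bg <- paste0("g", 1:6)
  f1 <- run_enrichment(make_query(fg, bg, t2g), t2g)
  f2 <- run_enrichment(make_query(rev(c(fg, "g1")), sample(rep(bg, 2)), t2g),
                       t2g)
  expect_identical(f1$table, f2$table)
})

test_that("drop_empty restricts the BH family", {
  fit_all <- toy_fit(foreground = c("g1", "g2"))
  fit_ne <- toy_fit(foreground = c("g1", "g2"), drop_empty = TRUE)
  expect_true(fit_ne$m < fit_all$m)
  expect_true(all(fit_ne$table$k >= 1))
  # same raw p for the shared pathways, different adjusted family size
  shared <- intersect(fit_all$table$pathway_id, fit_ne$table$pathway_id)
  expect_equal(
    fit_all$table$p_value[match(shared, fit_all$table$pathway_id)],
    fit_ne$table$p_value[match(shared, fit_ne$table$pathway_id)])
})

test_that("significance filtering uses strict thresholds", {
  fit <- toy_fit()
  tab <- fit$table
  # synthesise exact-boundary adjusted values through a manual copy
  fit$table$p_adjusted <- c(0.045, 0.05, rep(0.9, nrow(tab) - 2))[seq_len(nrow(tab))]
  kept <- filter_significant(fit, by = "padj", alpha = 0.05)
  expect_identical(nrow(kept$table), 1L)
  expect_equal(kept$table$p_adjusted[1L], 0.045)

  all_kept <- filter_significant(fit, by = "padj", alpha = 1.0)
  expect_identical(nrow(all_kept$table), nrow(fit$table))
  expect_error(filter_significant(fit, by = "padj", alpha = 0), "\\(0, 1\\]")
})

test_that("result tables round-trip through write/read at printed precision", {
  fit <- toy_fit()
  path <- tempfile(fileext = ".tsv")
  n <- write_results(fit, path)
  expect_identical(n, nrow(fit$table))
  lines <- readLines(path)
  expect_match(lines[1L], "^pathway_id\tpathway_name\tgene_ratio")
  back <- read_results(path)
  expect_identical(back$pathway_id, fit$table$pathway_id)
  expect_identical(back$k, fit$table$k)
  expect_identical(back$K, fit$table$K)
  expect_equal(back$p_value, fit$table$p_value, tolerance = 1e-8)
  expect_equal(back$fold_enrichment, fit$table$fold_enrichment,
               tolerance = 1e-8)

  # ratio formatting: k/n and K/N as integer fractions
  expect_match(lines[2L], "\t[0-9]+/[0-9]+\t[0-9]+/[0-9]+\t")

  # empty filtered table -> header-only file
  empty <- filter_significant(fit, alpha = 1e-12)
  p2 <- tempfile()
  expect_identical(write_results(empty, p2), 0L)
  expect_length(readLines(p2), 1L)
})

test_that("result objects print, summarise and coerce", {
  fit <- toy_fit()
  expect_output(print(fit), "pathway")
  s <- summary(fit)
  expect_identical(s$n_tested, nrow(fit$table))
  expect_output(print(s), "significant")
  expect_identical(as.data.frame(fit), fit$table)
})
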