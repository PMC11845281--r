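# plot datasets: contents, invariants, serialization and rendering

test_that("bar/lollipop payload is the head of the ranked table", {
  fit <- fit_from_sets(list(ko00001 = c("a", "b", "c"),
                            ko00002 = c("a", "b"),
                            ko00003 = "c"))
  pd <- bar_lollipop_data(fit, top_n = 2)
  expect_identical(pd$kind, "barplot")
  expect_identical(nrow(pd$payload), 2L)
  expect_identical(pd$payload$pathway_id[1L], fit$table$pathway_id[1L])
  expect_equal(pd$payload$neg_log10_padj,
               -log10(fit$table$p_adjusted[1:2]))
  # top_n beyond the table size clamps to the whole table
  pd_all <- bar_lollipop_data(fit, top_n = 50, kind = "lollipop")
  expect_identical(nrow(pd_all$payload), nrow(fit$table))
  expect_error(bar_lollipop_data(fit, top_n = 0), ">= 1")
})

test_that("a p_adjusted of 0.01 maps to a -log10 score of 2", {
  fit <- fit_from_sets(list(ko00001 = c("a", "b")))
  fit$table$p_adjusted <- 0.01
  pd <- bar_lollipop_data(fit, top_n = 1)
  expect_equal(pd$payload$neg_log10_padj, 2.0)
})

test_that("heatmap matrix is binary membership with recountable margins", {
  fit <- fit_from_sets(list(ko00001 = c("a", "b")))
  pd <- heatmap_matrix(fit)
  m <- do.call(rbind, pd$payload$matrix)
  expect_identical(dim(m), c(2L, 1L))
  expect_true(all(m == 1L))

  fit2 <- fit_from_sets(list(ko00001 = "a", ko00002 = "b"))
  m2 <- do.call(rbind, heatmap_matrix(fit2)$payload$matrix)
  expect_identical(dim(m2), c(2L, 2L))
  expect_equal(sum(m2), 2)              # identity pattern
  expect_true(all(rowSums(m2) == 1))    # one membership per gene

  fit3 <- fit_from_sets(list(ko00001 = c("a", "b", "c"),
                             ko00002 = c("b", "c"),
                             ko00003 = "c"))
  pd3 <- heatmap_matrix(fit3)
  m3 <- do.call(rbind, pd3$payload$matrix)
  counts <- rowSums(m3)
  names(counts) <- pd3$payload$genes
  expect_identical(counts, c(a = 1, b = 2, c = 3))
})

test_that("treeplot distances are 1 - Jaccard with average linkage", {
  # {a,b} vs {b,c}: Jaccard 1/3, distance 2/3 is the only merge height
  fit <- fit_from_sets(list(ko00001 = c("a", "b"), ko00002 = c("b", "c")))
  pd <- treeplot_clustering(fit)
  expect_equal(pd$payload$height, 2 / 3, tolerance = 1e-12)

  # identical sets merge first at distance 0; the disjoint third joins at 1
  fit2 <- fit_from_sets(list(ko00001 = c("a", "b"), ko00002 = c("a", "b"),
                             ko00003 = c("x", "y")))
  pd2 <- treeplot_clustering(fit2)
  expect_equal(min(pd2$payload$height), 0)
  expect_equal(max(pd2$payload$height), 1)
  ids_first_merge <- pd2$payload$merge[[1L]]
  expect_identical(sort(pd2$payload$pathway_ids[-ids_first_merge]),
                   c("ko00001", "ko00002"))

  single <- fit_from_sets(list(ko00001 = c("a", "b")))
  expect_error(treeplot_clustering(single), "not enough terms")
})

test_that("cnet graph has membership edges and a seeded layout", {
  fit <- fit_from_sets(list(ko00001 = c("a", "b")))
  pd <- cnet_graph(fit)
  expect_identical(nrow(pd$payload$edges), 2L)  # star with two genes

  fit2 <- fit_from_sets(list(ko00001 = c("a", "b"), ko00002 = c("b", "c")))
  pd2 <- cnet_graph(fit2)
  deg_b <- sum(pd2$payload$edges$gene == "b")
  expect_identical(deg_b, 2L)
  expect_identical(nrow(pd2$payload$edges), sum(fit2$table$k))
  # same seed -> identical serialization; the layout is part of the payload
  expect_identical(serialize_plotdata(cnet_graph(fit2, seed = 99L)),
                   serialize_plotdata(cnet_graph(fit2, seed = 99L)))
})

test_that("upset patterns are exclusive and partition the union", {
  fit <- fit_from_sets(list(ko00001 = c("a", "b"), ko00002 = c("b", "c")))
  pd <- upset_intersections(fit)
  pats <- pd$payload$patterns
  key <- vapply(pats, function(p) paste(sort(p$sets), collapse = "&"), "")
  counts <- vapply(pats, `[[`, 0L, "count")
  names(counts) <- key
  expect_identical(counts[["ko00001"]], 1L)               # a
  expect_identical(counts[["ko00002"]], 1L)               # c
  expect_identical(counts[["ko00001&ko00002"]], 1L)       # b
  expect_identical(sum(counts), 3L)                       # |union|

  fit2 <- fit_from_sets(list(ko00001 = c("a", "b"), ko00002 = c("a", "b")))
  pats2 <- upset_intersections(fit2)$payload$patterns
  expect_length(pats2, 1L)
  expect_identical(pats2[[1L]]$count, 2L)
  expect_setequal(pats2[[1L]]$sets, c("ko00001", "ko00002"))
})

test_that("heatmap, cnet and upset agree on the gene-pathway edge set", {
  fit <- fit_from_sets(list(ko00001 = c("a", "b", "c"),
                            ko00002 = c("b", "c"),
                            ko00003 = c("c", "d")))
  hm <- heatmap_matrix(fit)$payload
  m <- do.call(rbind, hm$matrix)
  edges_hm <- sort(unlist(lapply(seq_along(hm$pathways), function(j)
    paste(hm$pathways[j], hm$genes[m[, j] == 1L]))))
  cn <- cnet_graph(fit)$payload$edges
  edges_cn <- sort(paste(cn$pathway, cn$gene))
  up <- upset_intersections(fit)$payload$patterns
  edges_up <- sort(unlist(lapply(up, function(p) rep(p$sets, p$count)),
                          use.names = FALSE))
  expect_identical(edges_hm, edges_cn)
  # upset loses gene identity but preserves the edge multiset per pathway
  expect_identical(edges_up, sort(cn$pathway))
})

test_that("trend series sort by year and reject negative counts", {
  pd <- pubmed_trend_data(list(p1 = c(`2021` = 5, `2019` = 3, `2020` = 4)))
  expect_identical(pd$payload[[1L]]$years, c(2019L, 2020L, 2021L))
  expect_identical(pd$payload[[1L]]$counts, c(3, 4, 5))
  expect_length(pubmed_trend_data(list())$payload, 0L)
  expect_error(pubmed_trend_data(list(p1 = c(`2020` = -1))), "negative")
})

test_that("rendering writes the requested formats, self-contained", {
  fit <- fit_from_sets(list(ko00001 = c("a", "b"), ko00002 = c("b", "c")))
  base <- tempfile()
  paths <- render_plotdata(bar_lollipop_data(fit), base)
  expect_identical(basename(paths), paste0(basename(base), c(".png", ".html")))
  expect_true(all(file.exists(paths)))
  html <- readLines(paths[2L], warn = FALSE)
  expect_true(any(grepl("data:image/png;base64", html, fixed = TRUE)))
  expect_false(any(grepl("https?://", html)))

  expect_error(render_plotdata(bar_lollipop_data(fit), base,
                               formats = character()), "at least one")
  expect_error(render_plotdata(bar_lollipop_data(fit), base,
                               formats = "pdf"), "unsupported")
})

test_that("every plot kind renders, and payloads serialize deterministically", {
  fit <- fit_from_sets(list(ko00001 = c("a", "b", "c"),
                            ko00002 = c("b", "c"),
                            ko00003 = c("c", "d")))
  kinds <- list(bar_lollipop_data(fit),
                bar_lollipop_data(fit, kind = "lollipop"),
                heatmap_matrix(fit),
                treeplot_clustering(fit),
                cnet_graph(fit),
                upset_intersections(fit),
                pubmed_trend_data(list(ko00001 = c(`2020` = 2, `2021` = 4))))
  for (pd in kinds) {
    base <- tempfile()
    out <- render_plotdata(pd, base, formats = "png")
    expect_true(file.exists(out[1L]), info = pd$kind)
    expect_gt(file.info(out[1L])$size, 1000)
    expect_identical(serialize_plotdata(pd), serialize_plotdata(pd))
  }
})
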