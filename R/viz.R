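# Plot-ready datasets for the enrichment figures, plus deterministic
# rendering to PNG and self-contained HTML.
#
# Every builder is a pure function of (result table, options, seed) and
# returns a `ko_plotdata` object whose payload serializes to canonical JSON,
# so figures can be golden-tested on text, not pixels.

new_plotdata <- function(kind, payload, by, alpha) {
  structure(list(kind = kind, payload = payload,
                 styling = list(by = by, alpha = alpha)),
            class = "ko_plotdata")
}

#' @export
print.ko_plotdata <- function(x, ...) {
  cat(sprintf("plot dataset '%s' (filtered by %s < %g)\n",
              x$kind, x$styling$by, x$styling$alpha))
  invisible(x)
}

# records passing the active filter, in table order
filtered_table <- function(x, by, alpha) {
  stopifnot(inherits(x, "ko_enrichment"))
  if (is.null(alpha))
    alpha <- if (by == "padj") x$thresholds$alpha_padj else x$thresholds$alpha_p
  check_alpha(alpha)
  stat <- if (by == "padj") x$table$p_adjusted else x$table$p_value
  keep <- if (alpha == 1) rep(TRUE, length(stat)) else stat < alpha
  list(tab = x$table[keep, , drop = FALSE], alpha = alpha)
}

split_genes <- function(s) {
  out <- strsplit(s, ",", fixed = TRUE)
  lapply(out, function(g) g[nzchar(g)])
}

#' Barplot / lollipop dataset
#'
#' The top `top_n` enriched pathways (by the table's ranking) with the
#' quantities the two score plots draw: `-log10` adjusted p-value, fold
#' enrichment and foreground member count.
#'
#' @param x a `ko_enrichment` object.
#' @param top_n maximum number of pathways included.
#' @param kind `"barplot"` or `"lollipop"` (same payload, different glyph).
#' @param by,alpha active significance filter (statistic and threshold);
#'   `alpha = NULL` uses the threshold stored in `x`.
#' @return A `ko_plotdata` object.
#' @export
bar_lollipop_data <- function(x, top_n = 20L, kind = c("barplot", "lollipop"),
                              by = c("padj", "p"), alpha = NULL) {
  kind <- match.arg(kind); by <- match.arg(by)
  if (!is.numeric(top_n) || top_n < 1) stop_fmt("'top_n' must be >= 1")
  f <- filtered_table(x, by, alpha)
  tab <- utils::head(f$tab, top_n)
  payload <- data.frame(pathway_id = tab$pathway_id,
                        pathway_name = tab$pathway_name,
                        neg_log10_padj = -log10(tab$p_adjusted),
                        fold_enrichment = tab$fold_enrichment,
                        count = tab$k,
                        stringsAsFactors = FALSE)
  new_plotdata(kind, payload, by, f$alpha)
}

#' Gene-by-pathway membership heatmap dataset
#'
#' Binary matrix with one row per member gene (sorted union over the
#' filtered records) and one column per pathway (table order); a cell is 1
#' when the gene belongs to that pathway's foreground members.
#'
#' @inheritParams bar_lollipop_data
#' @return A `ko_plotdata` whose payload holds `genes`, `pathways`,
#'   `pathway_names` and the 0/1 `matrix` (row-major list of rows).
#' @export
heatmap_matrix <- function(x, by = c("padj", "p"), alpha = NULL) {
  by <- match.arg(by)
  f <- filtered_table(x, by, alpha)
  tab <- f$tab
  sets <- split_genes(tab$genes)
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  mat <- matrix(0L, nrow = length(genes), ncol = nrow(tab),
                dimnames = list(genes, tab$pathway_id))
  for (j in seq_along(sets)) mat[sets[[j]], j] <- 1L
  payload <- list(genes = genes, pathways = tab$pathway_id,
                  pathway_names = tab$pathway_name,
                  matrix = lapply(seq_len(nrow(mat)), function(i)
                    unname(mat[i, ])))
  new_plotdata("heatmap", payload, by, f$alpha)
}

#' Hierarchical clustering of enriched terms (treeplot dataset)
#'
#' Pairwise distance between two enriched pathways is 1 minus the Jaccard
#' index of their member-gene sets; terms are clustered by average-linkage
#' agglomeration and exported as a rooted binary merge tree with heights.
#'
#' @inheritParams bar_lollipop_data
#' @return A `ko_plotdata` whose payload holds the `labels` (pathway names),
#'   `merge` matrix, `height` vector and leaf `order` of the dendrogram.
#' @export
treeplot_clustering <- function(x, by = c("padj", "p"), alpha = NULL) {
  by <- match.arg(by)
  f <- filtered_table(x, by, alpha)
  tab <- f$tab
  if (nrow(tab) < 2L)
    stop_fmt("not enough terms: treeplot clustering needs at least 2 enriched pathways")
  sets <- split_genes(tab$genes)
  m <- nrow(tab)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    d[i, j] <- d[j, i] <- 1 - jaccard(sets[[i]], sets[[j]])
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  payload <- list(labels = tab$pathway_name,
                  pathway_ids = tab$pathway_id,
                  merge = lapply(seq_len(nrow(hc$merge)), function(i)
                    unname(hc$merge[i, ])),
                  height = hc$height,
                  order = hc$order)
  pd <- new_plotdata("treeplot", payload, by, f$alpha)
  pd$hclust <- hc   # kept for rendering; not part of the serialized payload
  pd
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Pathway-gene network (cnetplot) dataset
#'
#' Bipartite graph linking the top enriched pathways to their member
#' foreground genes. Node coordinates come from a force-directed
#' (Fruchterman-Reingold) layout computed under a fixed seed, so the figure
#' is reproducible.
#'
#' @inheritParams bar_lollipop_data
#' @param seed layout seed.
#' @return A `ko_plotdata` whose payload holds `nodes` (id, label, type,
#'   size, x, y) and `edges` (pathway, gene).
#' @export
cnet_graph <- function(x, top_n = 20L, by = c("padj", "p"), alpha = NULL,
                       seed = 42L) {
  by <- match.arg(by)
  if (!is.numeric(top_n) || top_n < 1) stop_fmt("'top_n' must be >= 1")
  f <- filtered_table(x, by, alpha)
  tab <- utils::head(f$tab, top_n)
  sets <- split_genes(tab$genes)
  edges <- do.call(rbind, lapply(seq_along(sets), function(i) {
    if (!length(sets[[i]])) return(NULL)
    data.frame(pathway = tab$pathway_id[i], gene = sets[[i]],
               stringsAsFactors = FALSE)
  }))
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  nodes <- data.frame(
    id = c(tab$pathway_id, genes),
    label = c(tab$pathway_name, genes),
    type = c(rep("pathway", nrow(tab)), rep("gene", length(genes))),
    size = c(tab$k, rep(1L, length(genes))),
    stringsAsFactors = FALSE)
  if (!is.null(edges) && nrow(nodes) > 0L) {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = nodes[, c("id", "label", "type", "size")])
    xy <- with_seed(seed, igraph::layout_with_fr(g))
    idx <- match(nodes$id, igraph::V(g)$name)
    nodes$x <- round(xy[idx, 1L], 6)
    nodes$y <- round(xy[idx, 2L], 6)
  } else {
    nodes$x <- numeric(nrow(nodes)); nodes$y <- numeric(nrow(nodes))
    edges <- data.frame(pathway = character(), gene = character(),
                        stringsAsFactors = FALSE)
  }
  payload <- list(nodes = nodes, edges = edges, seed = seed)
  new_plotdata("cnet", payload, by, f$alpha)
}

#' Exclusive intersection counts (UpSet dataset)
#'
#' Standard UpSet semantics over the top pathways' member-gene sets: every
#' gene is counted in exactly one pattern — the full combination of sets
#' that contain it — so the pattern counts partition the union.
#'
#' @inheritParams bar_lollipop_data
#' @return A `ko_plotdata` whose payload holds `sets` (pathway ids in table
#'   order, with sizes) and `patterns` (member sets + exclusive count,
#'   sorted by count descending then pattern).
#' @export
upset_intersections <- function(x, top_n = 20L, by = c("padj", "p"),
                                alpha = NULL) {
  by <- match.arg(by)
  if (!is.numeric(top_n) || top_n < 1) stop_fmt("'top_n' must be >= 1")
  f <- filtered_table(x, by, alpha)
  tab <- utils::head(f$tab, top_n)
  sets <- split_genes(tab$genes)
  names(sets) <- tab$pathway_id
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (length(genes) == 1L) membership <- matrix(membership, nrow = 1L,
                                                dimnames = list(genes, names(sets)))
  key <- apply(membership, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  counts <- table(key)
  patterns <- lapply(names(counts), function(k)
    list(sets = strsplit(k, "&", fixed = TRUE)[[1L]],
         count = as.integer(counts[[k]])))
  ord <- order(-vapply(patterns, `[[`, 0L, "count"),
               vapply(patterns, function(p) paste(p$sets, collapse = "&"),
                      ""))
  payload <- list(sets = data.frame(pathway_id = tab$pathway_id,
                                    size = lengths(sets),
                                    stringsAsFactors = FALSE),
                  patterns = patterns[ord])
  new_plotdata("upset", payload, by, f$alpha)
}

#' Literature trend dataset
#'
#' Turns injected per-pathway publication counts by year into sorted plot
#' series. The package performs no literature queries itself: the counts are
#' supplied by the caller, and missing years are rendered as gaps, not
#' zeros.
#'
#' @param term_to_year_counts named list: pathway/term -> named numeric
#'   vector of counts keyed by year.
#' @return A `ko_plotdata` whose payload holds one `{term, years, counts}`
#'   series per input term.
#' @export
pubmed_trend_data <- function(term_to_year_counts) {
  if (!is.list(term_to_year_counts))
    stop_fmt("'term_to_year_counts' must be a named list")
  series <- lapply(names(term_to_year_counts), function(term) {
    counts <- term_to_year_counts[[term]]
    if (length(counts) && (is.null(names(counts)) ||
                           any(!grepl("^[0-9]{4}$", names(counts)))))
      stop_fmt("counts for '%s' must be keyed by 4-digit years", term)
    if (any(counts < 0)) stop_fmt("negative publication count for '%s'", term)
    yrs <- as.integer(names(counts))
    ord <- order(yrs)
    list(term = term, years = yrs[ord], counts = unname(counts[ord]))
  })
  new_plotdata("pubmed_trend", series, by = "p", alpha = 1)
}

#' Canonical text serialization of a plot dataset
#'
#' JSON form of (kind, payload, styling) used for golden tests and embedded
#' in the HTML output; identical datasets serialize to identical bytes.
#'
#' @param pd a `ko_plotdata` object.
#' @return A single JSON string.
#' @export
serialize_plotdata <- function(pd) {
  stopifnot(inherits(pd, "ko_plotdata"))
  as.character(jsonlite::toJSON(
    list(kind = pd$kind, styling = pd$styling, payload = pd$payload),
    auto_unbox = TRUE, digits = I(10), dataframe = "columns", pretty = TRUE))
}

#' Render a plot dataset to files
#'
#' Writes `<out_basename>.png` and/or `<out_basename>.html`. The HTML file
#' is self-contained: it embeds the PNG as a base64 data URI together with
#' the canonical JSON payload (and the layout seed where one applies), so it
#' opens offline and can be diffed on its payload.
#'
#' @param pd a `ko_plotdata` object.
#' @param out_basename output path without extension.
#' @param formats non-empty subset of `c("png", "html")`.
#' @param width,height device size in pixels.
#' @return Character vector of the written paths.
#' @export
render_plotdata <- function(pd, out_basename, formats = c("png", "html"),
                            width = 900, height = 700) {
  stopifnot(inherits(pd, "ko_plotdata"))
  formats <- unique(formats)
  if (length(formats) == 0L)
    stop_fmt("'formats' must contain at least one of 'png', 'html'")
  bad <- setdiff(formats, c("png", "html"))
  if (length(bad)) stop_fmt("unsupported output format '%s'", bad[1L])
  written <- character()
  png_path <- paste0(out_basename, ".png")
  need_png_tmp <- "html" %in% formats && !("png" %in% formats)
  if (need_png_tmp) png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path, width = width, height = height, res = 96)
  ok <- tryCatch({ draw_plotdata(pd); TRUE },
                 finally = grDevices::dev.off())
  if ("png" %in% formats) written <- c(written, paste0(out_basename, ".png"))
  if ("html" %in% formats) {
    html_path <- paste0(out_basename, ".html")
    b64 <- jsonlite::base64_enc(readBin(png_path, "raw",
                                        n = file.info(png_path)$size))
    b64 <- gsub("\n", "", b64, fixed = TRUE)
    json <- serialize_plotdata(pd)
    html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
              sprintf("<title>%s</title></head><body>", pd$kind),
              sprintf("<h2>%s</h2>", pd$kind),
              sprintf("<p>filtered by %s &lt; %g</p>",
                      pd$styling$by, pd$styling$alpha),
              sprintf("<img alt=\"%s\" src=\"data:image/png;base64,%s\"/>",
                      pd$kind, b64),
              "<details><summary>plot data (JSON)</summary>",
              "<pre id=\"koenrich-payload\">",
              gsub("<", "&lt;", json, fixed = TRUE),
              "</pre></details>", "</body></html>")
    writeLines(html, html_path, useBytes = TRUE)
    written <- c(written, html_path)
    if (need_png_tmp) unlink(png_path)
  }
  invisible(written)
}

# --- base-graphics renderers ------------------------------------------------

#' Draw a plot dataset on the current device
#'
#' @param pd a `ko_plotdata` object.
#' @keywords internal
#' @export
draw_plotdata <- function(pd) {
  stopifnot(inherits(pd, "ko_plotdata"))
  switch(pd$kind,
         barplot = draw_scoreplot(pd, bars = TRUE),
         lollipop = draw_scoreplot(pd, bars = FALSE),
         heatmap = draw_heatmap(pd),
         treeplot = draw_treeplot(pd),
         cnet = draw_cnet(pd),
         upset = draw_upset(pd),
         pubmed_trend = draw_trend(pd),
         stop_fmt("no renderer for plot kind '%s'", pd$kind))
  invisible(pd)
}

empty_panel <- function(msg) {
  graphics::plot.new()
  graphics::plot.window(0:1, 0:1)
  graphics::text(0.5, 0.5, msg, col = "grey40")
}

shorten <- function(s, n = 38L) ifelse(nchar(s) > n,
                                       paste0(substr(s, 1L, n - 1L), "…"), s)

draw_scoreplot <- function(pd, bars = TRUE) {
  tab <- pd$payload
  if (NROW(tab) == 0L) return(empty_panel("no enriched pathways"))
  tab <- tab[rev(seq_len(nrow(tab))), ]   # best at the top
  graphics::par(mar = c(5, 16, 3, 2))
  v <- tab$neg_log10_padj
  if (bars) {
    graphics::barplot(v, horiz = TRUE, names.arg = shorten(tab$pathway_name),
                      las = 1, col = "#c23b3b", border = NA,
                      xlab = expression(-log[10] ~ "adjusted p"),
                      cex.names = 0.8)
  } else {
    y <- seq_along(v)
    graphics::plot(v, y, pch = 19, col = "#c23b3b",
                   cex = 0.6 + tab$count / max(c(tab$count, 1)),
                   yaxt = "n", ylab = "", bty = "n",
                   xlab = expression(-log[10] ~ "adjusted p"),
                   xlim = c(0, max(v) * 1.05))
    graphics::segments(0, y, v, y, col = "#c23b3b")
    graphics::axis(2, at = y, labels = shorten(tab$pathway_name), las = 1,
                   cex.axis = 0.8, tick = FALSE)
  }
  graphics::title(main = sprintf("Enriched pathways (%s < %g)",
                                 pd$styling$by, pd$styling$alpha))
}

draw_heatmap <- function(pd) {
  p <- pd$payload
  if (length(p$genes) == 0L) return(empty_panel("no enriched pathways"))
  mat <- do.call(rbind, p$matrix)
  graphics::par(mar = c(12, 8, 3, 2))
  graphics::image(seq_along(p$pathways), seq_along(p$genes), t(mat),
                  col = c("grey95", "#c23b3b"), axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_along(p$pathways),
                 labels = shorten(p$pathway_names, 24L), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_along(p$genes), labels = p$genes, las = 1,
                 cex.axis = 0.5)
  graphics::box()
  graphics::title(main = "Foreground gene membership across enriched pathways")
}

draw_treeplot <- function(pd) {
  hc <- pd$hclust
  if (is.null(hc)) {   # rebuilt from the serialized payload
    hc <- list(merge = do.call(rbind, pd$payload$merge),
               height = pd$payload$height, order = pd$payload$order,
               labels = pd$payload$labels, method = "average")
    class(hc) <- "hclust"
  }
  graphics::par(mar = c(3, 2, 3, 18))
  graphics::plot(stats::as.dendrogram(hc), horiz = TRUE,
                 xlab = "1 - Jaccard distance")
  graphics::title(main = "Hierarchical clustering of enriched terms")
}

draw_cnet <- function(pd) {
  p <- pd$payload
  nodes <- p$nodes
  if (NROW(nodes) == 0L) return(empty_panel("no enriched pathways"))
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot.new()
  rx <- range(nodes$x); ry <- range(nodes$y)
  pad <- function(r) r + c(-1, 1) * (diff(r) + 0.1) * 0.1
  graphics::plot.window(pad(rx), pad(ry), asp = 1)
  e <- p$edges
  if (NROW(e)) {
    i <- match(e$pathway, nodes$id); j <- match(e$gene, nodes$id)
    graphics::segments(nodes$x[i], nodes$y[i], nodes$x[j], nodes$y[j],
                       col = "grey70")
  }
  is_p <- nodes$type == "pathway"
  graphics::points(nodes$x[!is_p], nodes$y[!is_p], pch = 19, cex = 0.8,
                   col = "#4575b4")
  graphics::points(nodes$x[is_p], nodes$y[is_p], pch = 21, bg = "#c23b3b",
                   cex = 1.2 + 2 * nodes$size[is_p] / max(c(nodes$size[is_p], 1)))
  graphics::text(nodes$x[is_p], nodes$y[is_p], shorten(nodes$label[is_p], 24L),
                 pos = 3, cex = 0.7)
  graphics::title(main = "Pathway-gene network")
  graphics::legend("bottomleft", pch = c(21, 19),
                   pt.bg = c("#c23b3b", NA), col = c("black", "#4575b4"),
                   legend = c("pathway", "gene"), bty = "n")
}

draw_upset <- function(pd) {
  p <- pd$payload
  pats <- p$patterns
  if (length(pats) == 0L) return(empty_panel("no enriched pathways"))
  sets <- p$sets$pathway_id
  counts <- vapply(pats, `[[`, 0L, "count")
  graphics::par(mar = c(1, 12, 3, 1), fig = c(0, 1, 0.45, 1))
  bp <- graphics::barplot(counts, col = "grey25", border = NA,
                          ylab = "exclusive intersection size")
  graphics::text(bp, counts, labels = counts, pos = 3, cex = 0.8, xpd = NA)
  graphics::title(main = "Gene overlaps between enriched pathways")
  graphics::par(fig = c(0, 1, 0, 0.45), new = TRUE, mar = c(2, 12, 0, 1))
  graphics::plot.new()
  graphics::plot.window(range(bp) + c(-0.5, 0.5), c(0.5, length(sets) + 0.5))
  for (s in seq_along(sets)) {
    graphics::points(bp, rep(length(sets) - s + 1, length(bp)), pch = 19,
                     col = "grey85", cex = 1.2)
  }
  for (i in seq_along(pats)) {
    rows <- length(sets) - match(pats[[i]]$sets, sets) + 1
    graphics::points(rep(bp[i], length(rows)), rows, pch = 19, cex = 1.2)
    if (length(rows) > 1)
      graphics::segments(bp[i], min(rows), bp[i], max(rows), lwd = 2)
  }
  graphics::axis(2, at = rev(seq_along(sets)), labels = shorten(sets, 20L),
                 las = 1, tick = FALSE, cex.axis = 0.7)
}

draw_trend <- function(pd) {
  series <- pd$payload
  if (length(series) == 0L) return(empty_panel("no trend data"))
  all_years <- unlist(lapply(series, `[[`, "years"), use.names = FALSE)
  all_counts <- unlist(lapply(series, `[[`, "counts"), use.names = FALSE)
  graphics::par(mar = c(4, 4, 3, 2))
  graphics::plot(NA, xlim = range(all_years), ylim = c(0, max(all_counts)),
                 xlab = "year", ylab = "publications", bty = "l")
  cols <- grDevices::rainbow(length(series), v = 0.8)
  for (i in seq_along(series)) {
    s <- series[[i]]
    graphics::lines(s$years, s$counts, col = cols[i], lwd = 2)
    graphics::points(s$years, s$counts, col = cols[i], pch = 19, cex = 0.7)
  }
  graphics::legend("topleft", legend = vapply(series, `[[`, "", "term"),
                   col = cols, lwd = 2, bty = "n", cex = 0.8)
  graphics::title(main = "Literature trend")
}
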