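# KGML (KEGG pathway XML) parsing and diagram highlighting.
#
# KGML files are supplied locally (no KEGG access); entries of type
# "ortholog" carry space-separated "ko:Kxxxxx" tokens in their name
# attribute plus a <graphics> child with canvas coordinates. Matching is
# done at KO level: a node lights up red when any of its KOs is carried by
# an enriched gene.

parse_kgml <- function(kgml_path) {
  doc <- tryCatch(xml2::read_xml(kgml_path),
                  error = function(e) stop_fmt("'%s' is not valid XML: %s",
                                               kgml_path,
                                               conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (root != "pathway")
    stop_fmt("'%s' is not a KGML pathway document (root <%s>)",
             kgml_path, root)
  entries <- xml2::xml_find_all(doc, ".//entry")
  parsed <- lapply(entries, function(e) {
    g <- xml2::xml_find_first(e, "./graphics")
    if (inherits(g, "xml_missing")) return(NULL)
    x <- as.numeric(xml2::xml_attr(g, "x"))
    y <- as.numeric(xml2::xml_attr(g, "y"))
    if (is.na(x) || is.na(y)) return(NULL)
    w <- as.numeric(xml2::xml_attr(g, "width"));  if (is.na(w)) w <- 46
    h <- as.numeric(xml2::xml_attr(g, "height")); if (is.na(h)) h <- 17
    tokens <- strsplit(xml2::xml_attr(e, "name"), "[[:space:]]+")[[1L]]
    kos <- toupper(sub("^ko:", "", tokens[grepl("^ko:K[0-9]{5}$", tokens,
                                                ignore.case = TRUE)]))
    label <- xml2::xml_attr(g, "name")
    if (is.na(label) || !nzchar(label)) label <- tokens[1L]
    label <- sub(",.*$", "", label)   # KGML labels list aliases; keep first
    list(id = xml2::xml_attr(e, "id"),
         type = xml2::xml_attr(e, "type"),
         kos = kos, label = label, x = x, y = y, w = w, h = h)
  })
  parsed <- parsed[!vapply(parsed, is.null, logical(1L))]
  if (length(parsed) == 0L)
    stop_fmt("cannot render '%s': no entry carries a graphics block",
             kgml_path)
  title <- xml2::xml_attr(doc, "title")
  list(title = if (is.na(title)) basename(kgml_path) else title,
       entries = parsed)
}

# KOs carried by a set of enriched genes, read off the term2gene provenance
enriched_kos <- function(enriched_genes, t2g) {
  stopifnot(inherits(t2g, "term2gene"))
  kos <- unlist(lapply(t2g$provenance, function(by_gene)
    unlist(by_gene[intersect(names(by_gene), enriched_genes)],
           use.names = FALSE)), use.names = FALSE)
  sort(unique(kos))
}

#' Highlight enriched nodes on a KEGG pathway diagram
#'
#' Renders the pathway canvas from the KGML graphics records and fills in
#' red every entry whose KO set intersects the KOs carried by the enriched
#' genes (looked up through the term2gene provenance, so matching is
#' KO-level: orthologous nodes light up even when the gene ids are
#' species-specific).
#'
#' @param kgml_path path to a KGML (KEGG pathway XML) file.
#' @param enriched_genes character vector of enriched foreground gene ids.
#' @param t2g the [build_term2gene()] map carrying the gene-to-KO
#'   provenance.
#' @param out_path output image path.
#' @param format `"png"` or `"svg"`.
#' @return Number of highlighted entries (invisibly also attributed with
#'   the highlighted KOs).
#' @export
highlight_kgml <- function(kgml_path, enriched_genes, t2g, out_path,
                           format = c("png", "svg")) {
  format <- match.arg(format)
  kg <- parse_kgml(kgml_path)
  kos <- enriched_kos(enriched_genes, t2g)
  hit <- vapply(kg$entries, function(e) length(intersect(e$kos, kos)) > 0L,
                logical(1L))
  xs <- vapply(kg$entries, `[[`, 0, "x")
  ys <- vapply(kg$entries, `[[`, 0, "y")
  ws <- vapply(kg$entries, `[[`, 0, "w")
  hs <- vapply(kg$entries, `[[`, 0, "h")
  width <- max(xs + ws) + 40
  height <- max(ys + hs) + 40
  if (format == "png") {
    grDevices::png(out_path, width = max(width, 400), height = max(height, 300),
                   res = 96)
  } else {
    grDevices::svg(out_path, width = max(width, 400) / 96,
                   height = max(height, 300) / 96)
  }
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 2, 0))
  graphics::plot.new()
  # KGML y grows downward; flip so the diagram reads like the KEGG map
  graphics::plot.window(c(0, max(width, 400)), c(max(height, 300), 0))
  for (i in seq_along(kg$entries)) {
    e <- kg$entries[[i]]
    fill <- if (hit[i]) "#d62728" else "#bfffbf"
    txtcol <- if (hit[i]) "white" else "black"
    graphics::rect(e$x - e$w / 2, e$y + e$h / 2, e$x + e$w / 2, e$y - e$h / 2,
                   col = fill, border = "grey30")
    graphics::text(e$x, e$y, shorten(e$label, 14L), cex = 0.55, col = txtcol)
  }
  graphics::title(main = kg$title)
  structure(sum(hit), highlighted_kos = sort(unique(unlist(
    lapply(kg$entries[hit], function(e) intersect(e$kos, kos)),
    use.names = FALSE))))
}
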