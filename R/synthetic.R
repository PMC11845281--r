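# Seeded synthetic study generator.
#
# Produces a KO/pathway catalog, a gene annotation, and foreground/
# background lists with controllable spike-in enrichment, in exactly the
# file formats the pipeline consumes, so the whole tool is testable offline
# at any scale — including the demo scale of 437 foreground / 12 134
# background genes.

#' Describe a synthetic enrichment study
#'
#' The defaults reproduce the demo conditions: a 12 134-gene background
#' with a 437-gene foreground over a catalog of 120 pathways carrying 10-40
#' KOs each, genes annotated with 1-3 KOs, and 30% of the foreground drawn
#' from 5 spiked pathways. Set `spike_fraction = 0` for a null study (the
#' foreground is then a uniform sample and no pathway is truly enriched).
#'
#' @param n_genes number of background genes.
#' @param n_pathways number of pathways in the catalog.
#' @param kos_per_pathway integer range `c(lo, hi)`: KOs per pathway.
#' @param kos_per_gene integer range `c(lo, hi)`: KOs per gene.
#' @param fg_size foreground size.
#' @param spiked_pathway_count number of truly enriched pathways.
#' @param spike_fraction fraction of the foreground drawn from spiked
#'   pathways' member genes (0 = null design).
#' @param seed RNG seed; the whole study is a pure function of the design.
#' @return Object of class `spike_design`.
#' @export
spike_design <- function(n_genes = 12134L, n_pathways = 120L,
                         kos_per_pathway = c(10L, 40L),
                         kos_per_gene = c(1L, 3L),
                         fg_size = 437L, spiked_pathway_count = 5L,
                         spike_fraction = 0.3, seed = 1L) {
  d <- list(n_genes = as.integer(n_genes),
            n_pathways = as.integer(n_pathways),
            kos_per_pathway = as.integer(kos_per_pathway),
            kos_per_gene = as.integer(kos_per_gene),
            fg_size = as.integer(fg_size),
            spiked_pathway_count = as.integer(spiked_pathway_count),
            spike_fraction = as.numeric(spike_fraction),
            seed = as.integer(seed))
  with(d, {
    if (n_genes < 1L || n_pathways < 1L || fg_size < 1L)
      stop_fmt("design sizes must be positive")
    if (fg_size > n_genes)
      stop_fmt("foreground size (%d) cannot exceed the gene count (%d)",
               fg_size, n_genes)
    if (spiked_pathway_count > n_pathways)
      stop_fmt("cannot spike %d of %d pathways", spiked_pathway_count,
               n_pathways)
    if (spike_fraction < 0 || spike_fraction > 1)
      stop_fmt("'spike_fraction' must lie in [0, 1]")
    if (length(kos_per_pathway) != 2L || any(kos_per_pathway < 1L) ||
        kos_per_pathway[1L] > kos_per_pathway[2L])
      stop_fmt("'kos_per_pathway' must be an increasing pair of positive integers")
    if (length(kos_per_gene) != 2L || any(kos_per_gene < 1L) ||
        kos_per_gene[1L] > kos_per_gene[2L])
      stop_fmt("'kos_per_gene' must be an increasing pair of positive integers")
    if (n_pathways * kos_per_pathway[2L] > 99999L)
      stop_fmt("catalog would exhaust the K00001-K99999 accession space")
  })
  structure(d, class = "spike_design")
}

#' @export
print.spike_design <- function(x, ...) {
  cat(sprintf(paste0("synthetic study design: %d genes (%d foreground), ",
                     "%d pathways, %d spiked at fraction %g, seed %d\n"),
              x$n_genes, x$fg_size, x$n_pathways,
              if (x$spike_fraction > 0) x$spiked_pathway_count else 0L,
              x$spike_fraction, x$seed))
  invisible(x)
}

#' Simulate a synthetic enrichment study in memory
#'
#' Draws the catalog (disjoint KO blocks per pathway), annotates every gene
#' with KOs sampled uniformly from the catalog, and samples the foreground
#' uniformly from the genes. A `spike_fraction` share of the foreground is
#' then made to preferentially carry spiked-pathway KOs: each spiked
#' foreground gene has one of its uniform KOs replaced by a KO drawn from
#' the spiked pathways, which guarantees membership. The background is the
#' full gene set, so under `spike_fraction = 0` the draw is exactly the
#' hypergeometric null conditional on the lists. The truth manifest records
#' the spiked pathways and their realized contingency counts (k, n, K, N)
#' within the annotated universe.
#'
#' @param design a [spike_design()].
#' @return List with `catalog` ([pathway_catalog()]), `annotation`
#'   ([annotation_map()]), `foreground`, `background` (character vectors),
#'   `truth` (data frame: pathway_id, k, n, K, N) and `design`.
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "spike_design"))
  with_seed(design$seed, {
    n_path <- design$n_pathways
    sizes <- sample(design$kos_per_pathway[1L]:design$kos_per_pathway[2L],
                    n_path, replace = TRUE)
    all_kos <- sprintf("K%05d", seq_len(sum(sizes)))
    path_ids <- sprintf("ko%05d", seq_len(n_path))
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    kos <- lapply(seq_len(n_path), function(i) all_kos[starts[i]:stops[i]])
    names(kos) <- path_ids
    catalog <- pathway_catalog(kos, stats::setNames(
      sprintf("Synthetic pathway %03d", seq_len(n_path)), path_ids))

    genes <- sprintf("g%06d", seq_len(design$n_genes))
    n_per_gene <- sample(design$kos_per_gene[1L]:design$kos_per_gene[2L],
                         design$n_genes, replace = TRUE)
    gene_kos <- lapply(n_per_gene, function(m)
      sample(all_kos, min(m, length(all_kos))))
    names(gene_kos) <- genes

    foreground <- sort(sample(genes, design$fg_size))
    n_spike <- round(design$spike_fraction * design$fg_size)
    spiked <- character()
    if (n_spike > 0L) {
      if (design$spiked_pathway_count < 1L)
        stop_fmt("infeasible design: spike_fraction > 0 needs at least one spiked pathway")
      spiked <- sort(sample(path_ids, design$spiked_pathway_count))
      spiked_kos <- unlist(catalog$kos[spiked], use.names = FALSE)
      fg_spiked <- sample(foreground, n_spike)
      # replace one uniform KO with a spiked-pathway KO -> guaranteed member
      for (g in fg_spiked) {
        kos_g <- gene_kos[[g]]
        kos_g[sample.int(length(kos_g), 1L)] <-
          spiked_kos[sample.int(length(spiked_kos), 1L)]
        gene_kos[[g]] <- kos_g
      }
    }
    annotation <- annotation_map(gene_kos)

    # realized contingency counts for the truth manifest
    t2g <- build_term2gene(annotation, catalog)
    universe <- intersect(genes, unique(unlist(t2g$genes, use.names = FALSE)))
    eff_fg <- intersect(foreground, universe)
    truth <- if (length(spiked)) {
      do.call(rbind, lapply(spiked, function(p) {
        memb <- intersect(t2g$genes[[p]], universe)
        data.frame(pathway_id = p,
                   k = length(intersect(memb, eff_fg)),
                   n = length(eff_fg),
                   K = length(memb),
                   N = length(universe),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(pathway_id = character(), k = integer(), n = integer(),
                 K = integer(), N = integer(), stringsAsFactors = FALSE)
    }
    list(catalog = catalog, annotation = annotation,
         foreground = foreground, background = genes,
         truth = truth, design = design)
  })
}

#' Write a synthetic study to disk
#'
#' Materializes a [simulate_study()] draw in exactly the formats the
#' pipeline reads: `catalog.tsv` (ko, pathway, name), `annotation.tsv`
#' (two-column gene-to-KO), `foreground.txt` / `background.txt` (one gene
#' per line) and `truth.tsv` (the spike manifest). Same design + same seed
#' produce byte-identical files.
#'
#' @param design a [spike_design()].
#' @param dir output directory (created if needed).
#' @return Named list of the written paths plus the `truth` data frame.
#' @export
generate_fixture <- function(design, dir) {
  study <- simulate_study(design)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(catalog = file.path(dir, "catalog.tsv"),
                annotation = file.path(dir, "annotation.tsv"),
                foreground = file.path(dir, "foreground.txt"),
                background = file.path(dir, "background.txt"),
                truth = file.path(dir, "truth.tsv"))
  write_catalog(study$catalog, paths$catalog)
  write_annotation_table(study$annotation, paths$annotation)
  writeLines(study$foreground, paths$foreground)
  writeLines(study$background, paths$background)
  utils::write.table(study$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(truth_table = study$truth))
}

#' Write a synthetic KGML pathway diagram
#'
#' Emits a minimal but well-formed KGML document for one catalog pathway:
#' one `ortholog` entry per KO, laid out on a grid with graphics
#' coordinates, suitable for [highlight_kgml()]. This is a synthetic
#' stand-in for a KEGG-distributed KGML file.
#'
#' @param catalog a [pathway_catalog()].
#' @param pathway_id pathway to render.
#' @param path output path (conventionally `<pathway_id>.xml`).
#' @return The number of entries written, invisibly.
#' @export
write_synthetic_kgml <- function(catalog, pathway_id, path) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  pathway_id <- normalize_pathway_id(pathway_id)
  kos <- catalog$kos[[pathway_id]]
  if (is.null(kos)) stop_fmt("pathway '%s' is not in the catalog", pathway_id)
  per_row <- 8L
  entry <- vapply(seq_along(kos), function(i) {
    x <- 60 + ((i - 1L) %% per_row) * 100
    y <- 60 + ((i - 1L) %/% per_row) * 60
    paste0('  <entry id="', i, '" name="ko:', kos[i],
           '" type="ortholog">\n',
           '    <graphics name="', kos[i],
           '" type="rectangle" x="', x, '" y="', y,
           '" width="46" height="17"/>\n',
           "  </entry>")
  }, "")
  doc <- c(sprintf('<pathway name="path:%s" org="ko" number="%s" title="%s">',
                   pathway_id, sub("^ko", "", pathway_id),
                   catalog$names[[pathway_id]]),
           entry, "</pathway>")
  writeLines(doc, path)
  invisible(length(kos))
}
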