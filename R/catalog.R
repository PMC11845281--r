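# The KO-to-pathway catalog and the pathway-to-gene ("term2gene") map.
#
# The catalog is a plain 3-column tab-delimited file
#   ko_id <TAB> pathway_id <TAB> pathway_name
# and stands in for live KEGG access, so the pipeline runs fully offline.

# accepted pathway spellings "path:ko00010", "map00010", "ko00010" -> "ko00010"
normalize_pathway_id <- function(ids, context = NULL) {
  ids <- trimws(as.character(ids))
  ids <- sub("^path:", "", ids, ignore.case = TRUE)
  ids <- sub("^map", "ko", tolower(ids))
  bad <- !grepl("^ko[0-9]{5}$", ids)
  if (any(bad)) {
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    stop_fmt("malformed pathway id '%s'%s: expected ko/map + 5 digits",
             ids[bad][1L], where)
  }
  ids
}

#' Construct a pathway catalog
#'
#' Holds, for each KEGG pathway, its display name and the set of KO ortholog
#' groups that belong to it. Pathway identifiers are normalized so that
#' `path:ko00010`, `map00010` and `ko00010` all denote `ko00010`.
#'
#' @param kos named list mapping pathway id to a character vector of KOs.
#' @param names named character vector mapping pathway id to display name.
#' @return An object of class `pathway_catalog` with elements `kos` (named
#'   list of sorted KO vectors) and `names` (named character vector).
#' @export
pathway_catalog <- function(kos = list(), names = character()) {
  if (length(kos)) {
    ids <- normalize_pathway_id(base::names(kos))
    base::names(kos) <- ids
    kos <- lapply(kos, function(k) sort(unique(normalize_ko(k))))
    if (any(lengths(kos) == 0L))
      stop_fmt("every pathway must carry at least one KO")
    nm_ids <- normalize_pathway_id(base::names(names))
    base::names(names) <- nm_ids
    missing_nm <- setdiff(ids, nm_ids)
    if (length(missing_nm))
      stop_fmt("pathway '%s' has no display name", missing_nm[1L])
    if (any(!nzchar(names)))
      stop_fmt("pathway names must be non-empty")
    kos <- kos[order(ids)]
    names <- names[base::names(kos)]
  }
  structure(list(kos = kos, names = names), class = "pathway_catalog")
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat(sprintf("pathway catalog: %d pathway(s), %d distinct KO(s)\n",
              length(x$kos), length(unique(unlist(x$kos, use.names = FALSE)))))
  invisible(x)
}

#' Load an offline KO-to-pathway catalog
#'
#' Reads a 3-column tab-delimited file `ko <TAB> pathway <TAB> pathway name`
#' (blank lines and `#` comments allowed) into a [pathway_catalog()]. Two rows
#' giving different names to the same pathway id are a consistency error.
#'
#' @param path path to the catalog file.
#' @return A [pathway_catalog()].
#' @export
load_catalog <- function(path) {
  lines <- read_text_lines(path)
  kos <- list()
  nms <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || grepl("^#", line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || !nzchar(trimws(f[1L])) || !nzchar(trimws(f[2L])) ||
        !nzchar(trimws(f[3L])))
      stop_fmt("'%s' line %d: expected 'ko<TAB>pathway<TAB>name'", path, i)
    ko <- tryCatch(normalize_ko(trimws(f[1L])),
                   error = function(e) stop_fmt("'%s' line %d: %s", path, i,
                                                conditionMessage(e)))
    pid <- tryCatch(normalize_pathway_id(trimws(f[2L])),
                    error = function(e) stop_fmt("'%s' line %d: %s", path, i,
                                                 conditionMessage(e)))
    nm <- trimws(f[3L])
    if (!is.na(nms[pid]) && nms[pid] != nm)
      stop_fmt("'%s' line %d: pathway %s named both '%s' and '%s'",
               path, i, pid, nms[pid], nm)
    nms[pid] <- nm
    kos[[pid]] <- c(kos[[pid]], ko)
  }
  pathway_catalog(kos, nms)
}

#' Write a pathway catalog to its tab-delimited form
#'
#' Inverse of [load_catalog()]: one `ko <TAB> pathway <TAB> name` row per
#' (KO, pathway) pair, sorted by pathway then KO.
#'
#' @param catalog a [pathway_catalog()].
#' @param path output path.
#' @return Number of rows written, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  rows <- unlist(lapply(names(catalog$kos), function(p)
    paste(catalog$kos[[p]], p, catalog$names[[p]], sep = "\t")),
    use.names = FALSE)
  if (is.null(rows)) rows <- character()
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(rows, con)
  invisible(length(rows))
}

#' Build the pathway-to-gene map
#'
#' Links genes to pathways through their shared KOs: gene `g` is listed under
#' pathway `p` exactly when at least one KO of `g` belongs to `p`'s KO set.
#' A gene contributes once per pathway no matter how many of its KOs hit it;
#' the witnessing KOs are kept as provenance (used for pathway-diagram
#' highlighting, where nodes are KO-level).
#'
#' @param annotation a [annotation_map()].
#' @param catalog a [pathway_catalog()].
#' @param exclude character vector of pathway ids to leave out (e.g. KEGG
#'   global/overview maps such as `ko01100`, if the user wants them removed).
#' @return An object of class `term2gene`: list with `genes` (named list
#'   pathway -> sorted gene ids), `provenance` (named list pathway -> named
#'   list gene -> witnessing KOs) and `pathway_names`.
#' @export
build_term2gene <- function(annotation, catalog, exclude = character()) {
  stopifnot(inherits(annotation, "ko_annotation"),
            inherits(catalog, "pathway_catalog"))
  pids <- names(catalog$kos)
  if (length(exclude)) pids <- setdiff(pids, normalize_pathway_id(exclude))
  cat_long <- data.frame(ko = unlist(catalog$kos[pids], use.names = FALSE),
                         pathway = rep(pids, lengths(catalog$kos[pids])),
                         stringsAsFactors = FALSE)
  ann_long <- data.frame(gene = rep(names(annotation), lengths(annotation)),
                         ko = unlist(annotation, use.names = FALSE),
                         stringsAsFactors = FALSE)
  hits <- merge(ann_long, cat_long, by = "ko")
  if (nrow(hits) == 0L)
    return(structure(list(genes = list(), provenance = list(),
                          pathway_names = character()),
                     class = "term2gene"))
  o <- order(hits$pathway, hits$gene, hits$ko, method = "radix")
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$pathway, hits$gene, hits$ko,
                                 sep = "\t")), , drop = FALSE]
  pg <- !duplicated(paste(hits$pathway, hits$gene, sep = "\t"))
  genes <- split(hits$gene[pg], factor(hits$pathway[pg],
                                       levels = unique(hits$pathway[pg])))
  attributes(genes) <- list(names = names(genes))
  prov <- lapply(split(seq_len(nrow(hits)), hits$pathway), function(idx)
    split(hits$ko[idx], factor(hits$gene[idx],
                               levels = unique(hits$gene[idx]))))
  ord <- order(names(genes))
  structure(list(genes = genes[ord],
                 provenance = prov[names(genes)[ord]],
                 pathway_names = catalog$names[names(genes)[ord]]),
            class = "term2gene")
}

#' @export
print.term2gene <- function(x, ...) {
  cat(sprintf("term2gene map: %d pathway(s), %d gene(s)\n",
              length(x$genes),
              length(unique(unlist(x$genes, use.names = FALSE)))))
  invisible(x)
}
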