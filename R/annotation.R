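# Parsing and merging of KO annotation tables.
#
# The canonical exchange format is a headerless two-column tab-delimited
# table "protein ID <TAB> KO accession"; eggNOG-mapper's richer
# .emapper.annotations output is also accepted and reduced to that form.

#' Construct a KO annotation map
#'
#' An annotation map records, for every gene (protein) identifier, the set of
#' KEGG Orthology (KO) accessions assigned to it by one or more ortholog
#' annotators. Genes without any KO are not stored: absence from the map means
#' "unannotated". KO accessions are normalized to the canonical `K` + 5 digit
#' spelling (an optional `ko:` prefix is stripped, case is folded).
#'
#' @param entries named list; names are gene identifiers, elements are
#'   character vectors of KO accessions.
#' @param sources character vector naming the contributing annotators
#'   (informational).
#' @return An object of class `ko_annotation`: a named list of sorted, unique
#'   KO character vectors, with a `sources` attribute.
#' @examples
#' m <- annotation_map(list(g1 = c("ko:K00001", "K00002")))
#' m[["g1"]]
#' @export
annotation_map <- function(entries = list(), sources = character()) {
  if (!is.list(entries)) stop_fmt("'entries' must be a list")
  if (length(entries) > 0L) {
    nm <- names(entries)
    if (is.null(nm) || any(!nzchar(nm)))
      stop_fmt("all annotation entries must be named by a non-empty gene id")
    # flat (gene, KO) pairs: duplicate gene names merge by union automatically
    genes <- rep(nm, lengths(entries))
    kos <- trimws(as.character(unlist(entries, use.names = FALSE)))
    keep <- nzchar(kos)
    genes <- genes[keep]
    kos <- normalize_ko(kos[keep])
    o <- order(genes, kos, method = "radix")
    genes <- genes[o]
    kos <- kos[o]
    dup <- duplicated(paste(genes, kos, sep = "\t"))
    entries <- split(kos[!dup], factor(genes[!dup],
                                       levels = unique(genes[!dup])))
    attributes(entries) <- list(names = names(entries))
  }
  structure(entries, class = "ko_annotation", sources = as.character(sources))
}

# normalize KO tokens: trim, strip optional "ko:" prefix, upper-case;
# anything not matching K\d{5} afterwards is a hard format error
normalize_ko <- function(kos, context = NULL) {
  kos <- trimws(as.character(kos))
  kos <- kos[nzchar(kos)]
  kos <- toupper(sub("^[Kk][Oo]:", "", kos))
  bad <- !grepl("^K[0-9]{5}$", kos)
  if (any(bad)) {
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    stop_fmt("malformed KO accession '%s'%s: expected K followed by 5 digits",
             kos[bad][1L], where)
  }
  kos
}

#' @export
print.ko_annotation <- function(x, ...) {
  cat(sprintf("KO annotation map: %d gene(s), %d distinct KO(s)\n",
              length(x), length(unique(unlist(x, use.names = FALSE)))))
  src <- attr(x, "sources")
  if (length(src)) cat("sources:", paste(src, collapse = ", "), "\n")
  invisible(x)
}

#' Parse an eggNOG-mapper annotations file
#'
#' Reads an eggNOG-mapper v2-style `.emapper.annotations` table: lines
#' starting `##` are comments, the header line starts with `#query`, and the
#' `KEGG_ko` column (located by name, not position) holds `-` for missing or
#' comma-separated `ko:Kxxxxx` tokens.
#'
#' @param path path to the annotations file.
#' @return A [annotation_map()] with one entry per query gene carrying at
#'   least one KO.
#' @export
parse_eggnog <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^##", lines)]
  hdr_i <- which(grepl("^#query", lines))[1L]
  if (is.na(hdr_i))
    stop_fmt("'%s' is not an eggNOG-mapper annotations file: no '#query' header",
             path)
  header <- strsplit(sub("^#", "", lines[hdr_i]), "\t", fixed = TRUE)[[1L]]
  ko_col <- match("KEGG_ko", header)
  if (is.na(ko_col))
    stop_fmt("'%s': expected a 'KEGG_ko' column in the eggNOG-mapper header",
             path)
  rows <- lines[-seq_len(hdr_i)]
  rows <- rows[nzchar(trimws(rows))]
  entries <- list()
  for (row in rows) {
    f <- strsplit(row, "\t", fixed = TRUE)[[1L]]
    gene <- trimws(f[1L])
    cell <- if (length(f) >= ko_col) trimws(f[ko_col]) else "-"
    if (!nzchar(gene) || cell == "-" || !nzchar(cell)) next
    kos <- normalize_ko(strsplit(cell, ",", fixed = TRUE)[[1L]],
                        context = paste0("file ", path))
    entries[[gene]] <- c(entries[[gene]], kos)
  }
  annotation_map(entries, sources = basename(path))
}

#' Parse a two-column gene-to-KO table
#'
#' Reads the tab-delimited `gene <TAB> KO` export produced by BlastKOALA and
#' KAAS (also the package's own canonical annotation format). Rows with an
#' empty KO cell are skipped; repeated gene ids accumulate KOs by union.
#'
#' @param path path to the table.
#' @return A [annotation_map()].
#' @export
parse_two_column <- function(path) {
  lines <- read_text_lines(path)
  entries <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || grepl("^#", line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    gene <- trimws(f[1L])
    ko_raw <- if (length(f) >= 2L) trimws(f[2L]) else ""
    if (!nzchar(gene))
      stop_fmt("'%s' line %d: empty gene id", path, i)
    if (!nzchar(ko_raw)) next   # gene with no KO assignment
    ko <- tryCatch(normalize_ko(ko_raw),
                   error = function(e) stop_fmt("'%s' line %d: %s",
                                                path, i, conditionMessage(e)))
    entries[[gene]] <- c(entries[[gene]], ko)
  }
  annotation_map(entries, sources = basename(path))
}

#' Merge annotation maps by union or intersection
#'
#' Combines up to three annotation sources. In `"union"` mode (a "sum" of
#' annotations) a gene-KO pair is kept if any source reports it; in
#' `"intersection"` mode (the conservative "minimum") only pairs reported by
#' every source survive. Genes left with no KO are dropped. A single input is
#' returned unchanged under either mode.
#'
#' @param maps list of 1-3 `ko_annotation` objects.
#' @param mode `"union"` or `"intersection"`.
#' @return A merged [annotation_map()].
#' @export
merge_annotations <- function(maps, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!is.list(maps) || length(maps) == 0L)
    stop_fmt("'maps' must be a non-empty list of annotation maps")
  if (inherits(maps, "ko_annotation"))
    stop_fmt("'maps' must be a list of annotation maps, not a single map")
  if (length(maps) > 3L)
    stop_fmt("at most three annotation sources can be merged (got %d)",
             length(maps))
  ok <- vapply(maps, inherits, logical(1L), what = "ko_annotation")
  if (!all(ok)) stop_fmt("all elements of 'maps' must be 'ko_annotation' objects")
  sources <- unlist(lapply(maps, attr, "sources"))
  if (length(maps) == 1L)
    return(annotation_map(unclass(maps[[1L]]), sources = sources))
  genes <- if (mode == "union") {
    Reduce(union, lapply(maps, names))
  } else {
    Reduce(intersect, lapply(maps, names))
  }
  entries <- lapply(genes, function(g) {
    sets <- lapply(maps, function(m) m[[g]])
    if (mode == "union") unique(unlist(sets, use.names = FALSE))
    else Reduce(intersect, sets)
  })
  names(entries) <- genes
  annotation_map(entries, sources = sources)
}

#' Write / read the canonical two-column annotation table
#'
#' `write_annotation_table()` emits one `gene <TAB> KO` row per (gene, KO)
#' pair, genes sorted lexicographically and KOs sorted within gene, so the
#' output is byte-deterministic. `read_annotation_table()` is its inverse.
#'
#' @param map a `ko_annotation` object.
#' @param path file path.
#' @return `write_annotation_table()` returns the number of rows written
#'   (invisibly); `read_annotation_table()` returns a [annotation_map()].
#' @export
write_annotation_table <- function(map, path) {
  stopifnot(inherits(map, "ko_annotation"))
  genes <- sort(names(map))
  rows <- unlist(lapply(genes, function(g)
    paste(g, sort(map[[g]]), sep = "\t")), use.names = FALSE)
  if (is.null(rows)) rows <- character()
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(rows, con)
  invisible(length(rows))
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) parse_two_column(path)
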