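# Shared fixture builders: everything is generated in code at test time.

# exhaustive hypergeometric upper-tail oracle: pmf sum from exact binomial
# coefficients (exact in double precision for N <= 30)
enum_upper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# direct Benjamini-Hochberg step-up oracle:
# adj_(i) = min(1, min_{j>=i} p_(j) * m / j) in the original order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# small deterministic catalog + annotation used across modules:
#   ko00010 "Glycolysis"  : K00001 K00002
#   ko00020 "TCA cycle"   : K00003
#   ko00030 "Pentose"     : K00004 K00005
toy_catalog <- function() {
  pathway_catalog(list(ko00010 = c("K00001", "K00002"),
                       ko00020 = "K00003",
                       ko00030 = c("K00004", "K00005")),
                  c(ko00010 = "Glycolysis", ko00020 = "TCA cycle",
                    ko00030 = "Pentose"))
}

toy_annotation <- function() {
  annotation_map(list(g1 = c("K00001", "K00002"),  # both KOs in ko00010
                      g2 = "K00001",
                      g3 = "K00003",
                      g4 = c("K00003", "K00004"),
                      g5 = "K00005",
                      g6 = "K99999"))              # hits no pathway
}

# a random annotation map over a small gene/KO space, for property tests
random_annotation <- function(n_genes = 20L, n_kos = 10L) {
  kos <- sprintf("K%05d", seq_len(n_kos))
  entries <- lapply(seq_len(n_genes), function(i)
    sample(kos, sample.int(3L, 1L)))
  names(entries) <- sprintf("g%03d", seq_len(n_genes))
  keep <- as.logical(sample(c(TRUE, FALSE), n_genes, replace = TRUE,
                            prob = c(0.8, 0.2)))
  annotation_map(entries[keep])
}

# as sets of "gene\tKO" pairs, for subset/equality checks
pair_set <- function(map) {
  sort(unlist(lapply(names(map), function(g) paste(g, map[[g]], sep = "\t")),
              use.names = FALSE))
}

# an eggNOG-mapper style annotations file; returns its path
write_eggnog_fixture <- function(rows) {
  path <- tempfile(fileext = ".emapper.annotations")
  header <- paste(c("#query", "seed_ortholog", "evalue", "KEGG_ko",
                    "KEGG_Pathway"), collapse = "\t")
  writeLines(c("## eggNOG-mapper style output", "## generated for tests",
               header, rows), path)
  path
}

# hand-written KGML with three ortholog entries (K00001, K00002, K00003)
write_toy_kgml <- function(path) {
  writeLines(c(
    '<pathway name="path:ko00010" org="ko" number="00010" title="Toy glycolysis">',
    '  <entry id="1" name="ko:K00001" type="ortholog">',
    '    <graphics name="K00001" type="rectangle" x="100" y="50" width="46" height="17"/>',
    "  </entry>",
    '  <entry id="2" name="ko:K00002 ko:K00009" type="ortholog">',
    '    <graphics name="K00002" type="rectangle" x="200" y="50" width="46" height="17"/>',
    "  </entry>",
    '  <entry id="3" name="ko:K00003" type="ortholog">',
    '    <graphics name="K00003" type="rectangle" x="300" y="120" width="46" height="17"/>',
    "  </entry>",
    "</pathway>"), path)
  path
}

# fit a small end-to-end enrichment from the toy fixtures
toy_fit <- function(foreground = c("g1", "g2", "g4"),
                    background = paste0("g", 1:6), ...) {
  t2g <- build_term2gene(toy_annotation(), toy_catalog())
  q <- make_query(foreground, background, t2g)
  run_enrichment(q, t2g, ...)
}

# a ko_enrichment object with prescribed member-gene sets, for viz tests:
# builds one single-KO pathway per set and a foreground equal to the union
fit_from_sets <- function(sets, extra_bg = 30L) {
  stopifnot(!is.null(names(sets)))
  kos <- sprintf("K%05d", seq_along(sets))
  names(kos) <- names(sets)
  catalog <- pathway_catalog(as.list(kos),
                             stats::setNames(paste("Pathway", names(sets)),
                                             names(sets)))
  genes <- unique(unlist(sets, use.names = FALSE))
  entries <- lapply(genes, function(g)
    kos[vapply(sets, function(s) g %in% s, logical(1L))])
  names(entries) <- genes
  filler <- sprintf("bgf%03d", seq_len(extra_bg))
  for (f in filler) entries[[f]] <- kos[[1L]]
  ann <- annotation_map(entries)
  t2g <- build_term2gene(ann, catalog)
  q <- make_query(genes, c(genes, filler), t2g)
  run_enrichment(q, t2g, alpha_p = 1, alpha_padj = 1)
}
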