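# Over-representation statistics: contingency counting, hypergeometric
# upper-tail p-values, fold enrichment, Benjamini-Hochberg adjustment, and
# the ranked result table.

#' Hypergeometric upper-tail p-value
#'
#' Probability of seeing `k` or more pathway members among `n` foreground
#' genes drawn without replacement from a universe of `N` genes of which `K`
#' are pathway members:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' The upper tail includes `k` itself, i.e. the same quantity as
#' `phyper(k - 1, K, N - K, n, lower.tail = FALSE)` and as the one-sided
#' (greater) Fisher exact test of the corresponding 2x2 table. The sum is
#' accumulated in log space from log-gamma binomial coefficients, so it is
#' stable for universes of tens of thousands of genes.
#'
#' @param k foreground genes in the pathway.
#' @param n foreground size.
#' @param K universe genes in the pathway.
#' @param N universe size.
#' @return `P(X >= k)`, a value in (0, 1]. Vectorized over its arguments.
#' @examples
#' hypergeom_pvalue(k = 5, n = 5, K = 5, N = 10)  # 1/choose(10,5)
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  args <- cbind(k = k, n = n, K = K, N = N)  # recycles
  apply(args, 1L, function(a) {
    k <- a[["k"]]; n <- a[["n"]]; K <- a[["K"]]; N <- a[["N"]]
    check_counts(k, n, K, N)
    hi <- min(n, K)
    i <- k:hi
    lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(lt)
    min(1, exp(m + log(sum(exp(lt - m)))))
  })
}

check_counts <- function(k, n, K, N) {
  v <- c(k = k, n = n, K = K, N = N)
  if (any(!is.finite(v)) || any(v != floor(v)) || any(v < 0))
    stop_fmt("contingency counts must be non-negative integers")
  if (n > N || K > N)
    stop_fmt("invalid contingency counts: need n <= N and K <= N (n=%d K=%d N=%d)",
             n, K, N)
  if (k > min(n, K) || k < max(0, n + K - N))
    stop_fmt("invalid contingency counts: k=%d outside [max(0,n+K-N), min(n,K)] for n=%d K=%d N=%d",
             k, n, K, N)
  invisible(TRUE)
}

#' Fold enrichment
#'
#' Ratio of the foreground pathway fraction to the background pathway
#' fraction, `(k/n) / (K/N)`. Values above 1 mean the pathway is
#' over-represented in the foreground.
#'
#' @inheritParams hypergeom_pvalue
#' @return A non-negative real. Vectorized.
#' @export
fold_enrichment <- function(k, n, K, N) {
  args <- cbind(k = k, n = n, K = K, N = N)
  apply(args, 1L, function(a) {
    if (a[["K"]] < 1 || a[["n"]] < 1)
      stop_fmt("fold enrichment needs K >= 1 and n >= 1")
    (a[["k"]] / a[["n"]]) / (a[["K"]] / a[["N"]])
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: for the sorted p-values
#' `p_(1) <= ... <= p_(m)`, the adjusted value of `p_(i)` is
#' `min(1, min_{j >= i} p_(j) * m / j)`, reported in the original input
#' order (the procedure is permutation-equivariant). Delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input
#' domain.
#'
#' @param p numeric vector of raw p-values, each in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop_fmt("'p' must be non-empty")
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_fmt("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Assemble the tested gene sets
#'
#' Derives from the raw foreground/background lists the universe actually
#' used by the test: background genes annotated to at least one pathway.
#' Foreground genes outside the background, and genes with no pathway
#' annotation, are dropped (with a warning and recorded counts) — this is
#' the convention of annotation-based over-representation tools, and it
#' changes `N`, so the drops are reported prominently.
#'
#' @param foreground,background character vectors of gene ids (duplicates
#'   are removed).
#' @param t2g a [build_term2gene()] map.
#' @return Object of class `gene_query` with elements `foreground`,
#'   `background`, `universe`, `effective_foreground` and `dropped` (named
#'   counts: `fg_not_in_background`, `fg_unannotated`, `bg_unannotated`).
#' @export
make_query <- function(foreground, background, t2g) {
  stopifnot(inherits(t2g, "term2gene"))
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  foreground <- foreground[nzchar(foreground)]
  background <- background[nzchar(background)]
  if (!length(foreground) || !length(background))
    stop_fmt("foreground and background gene lists must be non-empty")
  annotated <- unique(unlist(t2g$genes, use.names = FALSE))
  fg_in_bg <- intersect(foreground, background)
  n_out <- length(foreground) - length(fg_in_bg)
  universe <- intersect(background, annotated)
  eff_fg <- intersect(fg_in_bg, universe)
  dropped <- c(fg_not_in_background = n_out,
               fg_unannotated = length(fg_in_bg) - length(eff_fg),
               bg_unannotated = length(background) - length(universe))
  if (n_out > 0)
    warning(sprintf("%d foreground gene(s) absent from the background were dropped",
                    n_out), call. = FALSE)
  if (length(eff_fg) == 0L)
    stop_fmt("no annotated foreground genes: nothing to test")
  structure(list(foreground = sort(foreground),
                 background = sort(background),
                 universe = sort(universe),
                 effective_foreground = sort(eff_fg),
                 dropped = dropped),
            class = "gene_query")
}

#' @export
print.gene_query <- function(x, ...) {
  cat(sprintf(paste0("gene set query: %d foreground / %d background; ",
                     "universe %d, effective foreground %d\n"),
              length(x$foreground), length(x$background),
              length(x$universe), length(x$effective_foreground)))
  d <- x$dropped
  if (any(d > 0))
    cat(sprintf("dropped: %d fg not in bg, %d fg unannotated, %d bg unannotated\n",
                d[["fg_not_in_background"]], d[["fg_unannotated"]],
                d[["bg_unannotated"]]))
  invisible(x)
}

#' Run the over-representation analysis
#'
#' The central fitting function: for every pathway with at least one member
#' in the universe it counts the 2x2 contingency (`k` of `n` foreground
#' genes vs `K` of `N` universe genes), computes the hypergeometric
#' upper-tail p-value and fold enrichment, adjusts across the tested family
#' with Benjamini-Hochberg, and returns the ranked table. Pathways with
#' `k = 0` are part of the tested family (they contribute to the BH family
#' size `m`) unless `drop_empty = TRUE`.
#'
#' @param query a [make_query()] object.
#' @param t2g the [build_term2gene()] map used to build the query.
#' @param drop_empty if `TRUE`, restrict the tested family to pathways with
#'   at least one foreground member (changes the BH family size).
#' @param alpha_p,alpha_padj significance thresholds (strictly-less-than)
#'   stored with the result and used as defaults by [filter_significant()]
#'   and the plot builders; both default to 0.05.
#' @return Object of class `ko_enrichment`. Its `$table` is a data frame
#'   sorted by (adjusted p, raw p, pathway id) with columns `pathway_id`,
#'   `pathway_name`, `k`, `n`, `K`, `N`, `gene_ratio`, `bg_ratio`,
#'   `fold_enrichment`, `p_value`, `p_adjusted`, `genes` (comma-joined
#'   member foreground genes).
#' @examples
#' cat <- pathway_catalog(list(ko00010 = c("K00001", "K00002")),
#'                        c(ko00010 = "Glycolysis"))
#' ann <- annotation_map(list(g1 = "K00001", g2 = "K00002", g3 = "K00002"))
#' t2g <- build_term2gene(ann, cat)
#' q <- make_query(c("g1"), c("g1", "g2", "g3"), t2g)
#' run_enrichment(q, t2g)
#' @export
run_enrichment <- function(query, t2g, drop_empty = FALSE,
                           alpha_p = 0.05, alpha_padj = 0.05) {
  stopifnot(inherits(query, "gene_query"), inherits(t2g, "term2gene"))
  check_alpha(alpha_p); check_alpha(alpha_padj)
  uni <- query$universe
  eff <- query$effective_foreground
  N <- length(uni)
  n <- length(eff)
  if (N == 0L) stop_fmt("empty universe: no annotated background genes")
  pids <- names(t2g$genes)
  recs <- lapply(pids, function(p) {
    members <- intersect(t2g$genes[[p]], uni)
    K <- length(members)
    if (K == 0L) return(NULL)
    hits <- intersect(members, eff)
    k <- length(hits)
    list(pathway_id = p,
         pathway_name = unname(t2g$pathway_names[[p]]),
         k = k, n = n, K = K, N = N,
         genes = paste(sort(hits), collapse = ","))
  })
  recs <- recs[!vapply(recs, is.null, logical(1L))]
  if (drop_empty)
    recs <- recs[vapply(recs, function(r) r$k > 0L, logical(1L))]
  if (length(recs) == 0L)
    stop_fmt("no pathway has members in the universe: nothing to test")
  tab <- do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  tab$gene_ratio <- paste(tab$k, tab$n, sep = "/")
  tab$bg_ratio <- paste(tab$K, tab$N, sep = "/")
  tab$fold_enrichment <- fold_enrichment(tab$k, tab$n, tab$K, tab$N)
  tab$p_value <- hypergeom_pvalue(tab$k, tab$n, tab$K, tab$N)
  tab$p_adjusted <- bh_adjust(tab$p_value)
  ord <- order(tab$p_adjusted, tab$p_value, tab$pathway_id)
  tab <- tab[ord, c("pathway_id", "pathway_name", "k", "n", "K", "N",
                    "gene_ratio", "bg_ratio", "fold_enrichment",
                    "p_value", "p_adjusted", "genes")]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 n = n, N = N, m = nrow(tab),
                 thresholds = list(alpha_p = alpha_p, alpha_padj = alpha_padj),
                 drop_empty = drop_empty,
                 dropped = query$dropped,
                 call = match.call()),
            class = "ko_enrichment")
}

check_alpha <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0 || a > 1)
    stop_fmt("significance threshold must lie in (0, 1]")
  invisible(TRUE)
}

#' Filter an enrichment table at a significance threshold
#'
#' Keeps records whose chosen statistic is strictly below `alpha`
#' (a record with the statistic exactly equal to `alpha` is dropped),
#' preserving the ranking. `alpha = 1` disables the filter entirely (every
#' record is retained, including exact p = 1).
#'
#' @param x a `ko_enrichment` object.
#' @param by filter on raw p-values (`"p"`) or adjusted p-values (`"padj"`).
#' @param alpha threshold in (0, 1]; defaults to the threshold stored in `x`.
#' @return A `ko_enrichment` object with the filtered table.
#' @export
filter_significant <- function(x, by = c("padj", "p"), alpha = NULL) {
  stopifnot(inherits(x, "ko_enrichment"))
  by <- match.arg(by)
  if (is.null(alpha))
    alpha <- if (by == "padj") x$thresholds$alpha_padj else x$thresholds$alpha_p
  check_alpha(alpha)
  stat <- if (by == "padj") x$table$p_adjusted else x$table$p_value
  out <- x
  keep <- if (alpha == 1) rep(TRUE, length(stat)) else stat < alpha
  out$table <- x$table[keep, , drop = FALSE]
  rownames(out$table) <- NULL
  out$filter <- list(by = by, alpha = alpha)
  out
}

#' Write / read the enrichment result table
#'
#' `write_results()` emits a tab-delimited table with a header and one row
#' per pathway; ratios are printed as `k/n` and `K/N`, reals with 9
#' significant digits, genes comma-joined. `read_results()` parses such a
#' file back to a data frame with numeric columns reconstructed.
#'
#' @param x a `ko_enrichment` object.
#' @param path output (input) path.
#' @return `write_results()`: number of data rows written, invisibly.
#'   `read_results()`: a data frame in the written column order.
#' @export
write_results <- function(x, path) {
  stopifnot(inherits(x, "ko_enrichment"))
  tab <- x$table
  out <- data.frame(pathway_id = tab$pathway_id,
                    pathway_name = tab$pathway_name,
                    gene_ratio = tab$gene_ratio,
                    bg_ratio = tab$bg_ratio,
                    fold_enrichment = formatC(tab$fold_enrichment, digits = 9,
                                              format = "g"),
                    p_value = formatC(tab$p_value, digits = 9, format = "g"),
                    p_adjusted = formatC(tab$p_adjusted, digits = 9,
                                         format = "g"),
                    genes = tab$genes,
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(nrow(out))
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("pathway_id", "pathway_name", "gene_ratio", "bg_ratio",
            "fold_enrichment", "p_value", "p_adjusted", "genes")
  if (!all(need %in% colnames(tab)))
    stop_fmt("'%s' is not a koenrich results table", path)
  split_ratio <- function(r, part) as.integer(vapply(strsplit(r, "/", fixed = TRUE),
                                                     `[[`, "", part))
  tab$k <- split_ratio(tab$gene_ratio, 1L)
  tab$n <- split_ratio(tab$gene_ratio, 2L)
  tab$K <- split_ratio(tab$bg_ratio, 1L)
  tab$N <- split_ratio(tab$bg_ratio, 2L)
  tab$fold_enrichment <- as.numeric(tab$fold_enrichment)
  tab$p_value <- as.numeric(tab$p_value)
  tab$p_adjusted <- as.numeric(tab$p_adjusted)
  tab
}

# --- S3 methods for the result object ---------------------------------------

#' @export
print.ko_enrichment <- function(x, top = 10L, ...) {
  cat(sprintf("KO pathway over-representation: %d pathway(s) tested (m = %d)\n",
              nrow(x$table), x$m))
  cat(sprintf("foreground n = %d, universe N = %d\n", x$n, x$N))
  sig <- sum(x$table$p_adjusted < x$thresholds$alpha_padj)
  cat(sprintf("%d pathway(s) with adjusted p < %g\n", sig,
              x$thresholds$alpha_padj))
  show <- utils::head(x$table[, c("pathway_id", "pathway_name", "gene_ratio",
                                  "fold_enrichment", "p_value", "p_adjusted")],
                      top)
  print(show, row.names = FALSE, digits = 4)
  if (nrow(x$table) > top)
    cat(sprintf("... and %d more row(s)\n", nrow(x$table) - top))
  invisible(x)
}

#' @export
summary.ko_enrichment <- function(object, ...) {
  tab <- object$table
  structure(list(
    n_tested = nrow(tab),
    n_sig_p = sum(tab$p_value < object$thresholds$alpha_p),
    n_sig_padj = sum(tab$p_adjusted < object$thresholds$alpha_padj),
    thresholds = object$thresholds,
    foreground_n = object$n, universe_N = object$N,
    dropped = object$dropped,
    top = utils::head(tab, 5L)), class = "summary.ko_enrichment")
}

#' @export
print.summary.ko_enrichment <- function(x, ...) {
  cat(sprintf("pathways tested: %d\n", x$n_tested))
  cat(sprintf("significant raw p < %g: %d; adjusted p < %g: %d\n",
              x$thresholds$alpha_p, x$n_sig_p,
              x$thresholds$alpha_padj, x$n_sig_padj))
  cat(sprintf("foreground n = %d, universe N = %d\n", x$foreground_n,
              x$universe_N))
  cat("top pathways:\n")
  print(x$top[, c("pathway_id", "pathway_name", "gene_ratio",
                  "fold_enrichment", "p_adjusted")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.ko_enrichment <- function(x, ...) x$table

#' Plot an enrichment result
#'
#' Convenience method: draws the barplot of the top enriched pathways
#' (`-log10` adjusted p-values) on the current device. For the full set of
#' figure types and file output see [render_plotdata()].
#'
#' @param x a `ko_enrichment` object.
#' @param top_n number of pathways shown.
#' @param ... passed to [bar_lollipop_data()].
#' @export
plot.ko_enrichment <- function(x, top_n = 20L, ...) {
  pd <- bar_lollipop_data(x, top_n = top_n, kind = "barplot", ...)
  draw_plotdata(pd)
  invisible(pd)
}
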