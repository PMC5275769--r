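#' Union of target genes for a miRNA signature
#'
#' The gene list submitted to pathway enrichment: the union of validated
#' target sets over the signature miRNAs. Signature miRNAs absent from the
#' target map contribute nothing and are reported with a warning.
#'
#' @param mirnas Character vector of miRNA identifiers.
#' @param target_map A `target_map` (see [read_target_map()]).
#' @return Character vector of target genes.
#' @export
union_targets <- function(mirnas, target_map) {
  unmapped <- setdiff(mirnas, names(target_map))
  if (length(unmapped) > 0) {
    warning("miRNA(s) without target annotation: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  unique(unlist(target_map[intersect(mirnas, names(target_map))],
                use.names = FALSE))
}

#' Pathway over-representation test
#'
#' One-sided hypergeometric (Fisher exact) test per pathway: with a gene
#' universe of size `N`, a pathway of size `K` (after intersection with the
#' universe) and a query gene set of size `n`, the p-value is the upper tail
#' `P(X >= k)` for the observed overlap `k`. An overlap of 0 gives `p = 1`.
#'
#' @param gene_set Query genes (e.g. from [union_targets()]); genes outside
#'   the universe are dropped.
#' @param pathways A `pathway_set`.
#' @param universe Gene universe; default is the union of all pathway genes
#'   and the query set.
#' @return An `enrichment_result` data frame with columns `pathway`, `k`, `K`,
#'   `n`, `N`, `p`, ordered by increasing `p`.
#' @export
enrich <- function(gene_set, pathways, universe = NULL) {
  if (is.null(universe)) {
    universe <- unique(c(unlist(pathways, use.names = FALSE), gene_set))
  }
  universe <- unique(universe)
  if (length(universe) == 0) stop("gene universe is empty", call. = FALSE)
  gene_set <- intersect(unique(gene_set), universe)
  n <- length(gene_set)
  N <- length(universe)
  rows <- lapply(names(pathways), function(pw) {
    pg <- intersect(pathways[[pw]], universe)
    K <- length(pg)
    k <- length(intersect(gene_set, pg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Pathway enrichment with a random-miRNA-set negative-control filter
#'
#' Curated miRNA-target databases over-represent cancer and cell-cycle
#' pathways, so naive target enrichment yields many false positives. This
#' filter runs the same union-target enrichment for `n_sets` random draws of
#' `set_size` miRNAs from the miRNA universe and retains only query pathways
#' that are significant at `p_cutoff` for the query but in fewer than
#' `min_null_hits` of the random negative-control runs (default: in none of
#' them).
#'
#' @param query_mirnas The miRNA signature.
#' @param target_map A `target_map`.
#' @param pathways A `pathway_set`.
#' @param mirna_universe miRNAs the random sets are drawn from; default all
#'   mapped miRNAs. The query miRNAs are eligible for the draws unless
#'   `exclude_query = TRUE`.
#' @param n_sets Number of random negative-control sets (>= 0).
#' @param set_size Size of each random set.
#' @param p_cutoff Significance cutoff applied to the query and to every null
#'   run.
#' @param seed RNG seed for the draws.
#' @param universe Gene universe passed to [enrich()]; default is the union of
#'   all pathway genes and all mapped target genes.
#' @param exclude_query Exclude the query miRNAs from the random draws.
#' @param min_null_hits A query pathway is retained when its null hit count is
#'   strictly below this (default 1, i.e. zero null hits).
#' @return A `null_filter_report`: list with `enrichment` (query
#'   [enrich()] table), `query_pathways`, `null_hit_counts` (per query
#'   pathway), `retained`, and `parameters`.
#' @export
random_null_filter <- function(query_mirnas, target_map, pathways,
                               mirna_universe = names(target_map),
                               n_sets = 20, set_size = 11, p_cutoff = 1e-6,
                               seed = 1, universe = NULL,
                               exclude_query = FALSE, min_null_hits = 1) {
  if (exclude_query) {
    mirna_universe <- setdiff(mirna_universe, query_mirnas)
  }
  if (set_size > length(mirna_universe)) {
    stop(sprintf("set_size (%d) exceeds the miRNA universe (%d)",
                 set_size, length(mirna_universe)), call. = FALSE)
  }
  if (n_sets < 0) stop("n_sets must be >= 0", call. = FALSE)
  if (is.null(universe)) {
    universe <- unique(c(unlist(pathways, use.names = FALSE),
                         unlist(target_map, use.names = FALSE)))
  }
  query_enr <- enrich(union_targets(query_mirnas, target_map), pathways,
                      universe)
  query_pathways <- query_enr$pathway[query_enr$p < p_cutoff]
  hits <- stats::setNames(integer(length(query_pathways)), query_pathways)
  with_seed(seed, {
    for (b in seq_len(n_sets)) {
      draw <- sample(mirna_universe, set_size)
      ne <- enrich(union_targets(draw, target_map), pathways, universe)
      sig <- ne$pathway[ne$p < p_cutoff]
      common <- intersect(query_pathways, sig)
      hits[common] <- hits[common] + 1L
    }
  })
  structure(list(
    enrichment = query_enr,
    query_pathways = query_pathways,
    null_hit_counts = hits,
    retained = query_pathways[hits < min_null_hits],
    parameters = list(n_sets = n_sets, set_size = set_size,
                      p_cutoff = p_cutoff, seed = seed,
                      universe_size = length(unique(universe)),
                      mirna_universe_size = length(mirna_universe),
                      exclude_query = exclude_query,
                      min_null_hits = min_null_hits)
  ), class = "null_filter_report")
}

#' @export
print.null_filter_report <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "null_filter_report: %d query pathway(s) at p < %g; %d retained after %d random sets of %d miRNAs\n",
    length(x$query_pathways), p$p_cutoff, length(x$retained), p$n_sets,
    p$set_size))
  if (length(x$retained) > 0) {
    cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabular view of a null-filter report
#'
#' One row per query-significant pathway: enrichment p-value, the number of
#' negative-control runs in which the pathway was also significant, and
#' whether it was retained.
#'
#' @param x A `null_filter_report`.
#' @param ... Unused.
#' @return Data frame with columns `pathway`, `p`, `null_hits`, `retained`.
#' @export
as.data.frame.null_filter_report <- function(x, ...) {
  enr <- x$enrichment
  qp <- x$query_pathways
  data.frame(
    pathway = qp,
    p = enr$p[match(qp, enr$pathway)],
    null_hits = as.integer(x$null_hit_counts[qp]),
    retained = qp %in% x$retained,
    stringsAsFactors = FALSE
  )
}
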