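# Over-representation analysis of gene sets against a supplied term map
# (no live GO/KEGG access): exact hypergeometric upper tail computed in
# log space, BH adjustment across tested terms.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts query genes falling in a term of size K, for
#' a query of size n drawn from a universe of size N. Each term of the
#' sum C(K,i) C(N-K, n-i) / C(N,n) is evaluated in log space via
#' `lchoose` and combined with a log-sum-exp, so the tail is exact and
#' stable even for large universes.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K term size in the universe.
#' @param n query size.
#' @param N universe size.
#' @return the upper-tail probability.
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n))
    stop("infeasible (k, K, n, N) = (", k, ", ", K, ", ", n, ", ", N, ")")
  if (k == 0) return(1)
  i <- k:min(K, n)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' Read a feature-to-term annotation map
#'
#' TSV with columns `gene`, `term`, `name`, `namespace` (BP/CC/MF or
#' `pathway`). The universe defaults to every annotated gene.
#'
#' @param path file path.
#' @return a list of class `term_map`: `terms` (named list of gene-id
#'   vectors), `names`, `namespace` (named by term), `universe`.
#' @export
read_term_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene", "term", "name", "namespace")
  if (!all(need %in% names(tab)))
    stop("term map needs columns: ", paste(need, collapse = ", "))
  term_map(tab)
}

#' Build a term map from a long-format annotation table
#' @param tab data.frame with columns `gene`, `term`, `name`, `namespace`.
#' @param universe optional gene universe; defaults to all annotated genes.
#' @return a `term_map` (see [read_term_map()]).
#' @export
term_map <- function(tab, universe = NULL) {
  terms <- split(tab$gene, tab$term)
  terms <- lapply(terms, unique)
  first <- !duplicated(tab$term)
  if (is.null(universe)) universe <- unique(tab$gene)
  structure(list(terms = terms,
                 names = stats::setNames(tab$name[first], tab$term[first]),
                 namespace = stats::setNames(tab$namespace[first],
                                             tab$term[first]),
                 universe = unique(universe)),
            class = "term_map")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term with at least `min_term_size` universe genes for
#' over-representation in the query, BH-adjusts across the tested terms,
#' and flags terms with adjusted p <= `padj_max` (non-strict). The
#' universe is the term map's universe, optionally intersected with an
#' expressed-gene set; query genes outside the universe are dropped with
#' a warning.
#'
#' @param query character vector of gene ids.
#' @param map a `term_map`.
#' @param padj_max enrichment cutoff on adjusted p (default 0.05, `<=`).
#' @param min_term_size smallest testable term (default 3).
#' @param expressed optional gene set to intersect with the universe.
#' @return data.frame sorted by adjusted p then term id: `term_id`,
#'   `name`, `namespace`, `k`, `K`, `n`, `N`, `p_value`, `p_adjusted`,
#'   `enriched`.
#' @export
enrich <- function(query, map, padj_max = 0.05, min_term_size = 3L,
                   expressed = NULL) {
  universe <- map$universe
  if (!is.null(expressed)) universe <- intersect(universe, expressed)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("no query genes in the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(map$terms), function(tid) {
    genes <- intersect(map$terms[[tid]], universe)
    K <- length(genes)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(query, genes))
    data.frame(term_id = tid,
               name = unname(map$names[tid]),
               namespace = unname(map$namespace[tid]),
               k = k, K = K, n = n, N = N,
               p_value = hypergeometric_p(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(term_id = character(0), name = character(0),
                      namespace = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      enriched = logical(0)))
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_value)
  res$enriched <- res$p_adjusted <= padj_max
  res[order(res$p_adjusted, res$term_id), , drop = FALSE]
}
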