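# Pathway over-representation testing: exact hypergeometric upper-tail
# probabilities with Benjamini-Hochberg correction, replacing the
# external David/KEGG step with an in-house computation on supplied gene
# sets.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N_u, K, n)`: the probability of
#' drawing at least `k` pathway members in a query of size `n` from a
#' universe of `N_u` genes of which `K` are in the pathway. Exact, via
#' the hypergeometric distribution function.
#'
#' @param k observed overlap (`0 <= k <= min(K, n)`).
#' @param K pathway size.
#' @param n query size.
#' @param N_u universe size (`K, n <= N_u`).
#' @return probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N_u) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(K > N_u) || any(n > N_u)) {
    stop("require 0 <= k <= min(K, n) and K, n <= N_u", call. = FALSE)
  }
  phyper(k - 1, K, N_u - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1, preserving input order.
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Pathway over-representation test
#'
#' Tests every pathway of a gene-set collection for over-representation
#' of the query genes (one-sided hypergeometric), adjusts across all
#' pathways by Benjamini-Hochberg, and reports pathways with at least one
#' overlapping gene, sorted by adjusted p-value then name. Query genes
#' outside the universe are dropped with a warning.
#'
#' @param query_genes character vector of query gene symbols.
#' @param gene_sets a `pathway_gene_sets` object from [read_gmt()].
#' @param alpha significance level on the adjusted p-value (default
#'   0.05).
#' @return data frame with columns `pathway`, `overlap` (k), `set_size`
#'   (K), `query_size` (n), `universe_size`, `p_value`, `adjusted_p`,
#'   `significant`, `overlap_genes` (pipe-joined, sorted).
#' @export
enrich <- function(query_genes, gene_sets, alpha = 0.05) {
  stopifnot(inherits(gene_sets, "pathway_gene_sets"),
            alpha > 0, alpha < 1)
  universe <- gene_sets$universe
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe ",
            "dropped: ", paste(head(outside, 5L), collapse = ", "),
            if (length(outside) > 5L) ", ..." else "", call. = FALSE)
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) {
    stop("no query genes remain after intersecting with the universe",
         call. = FALSE)
  }
  n <- length(query)
  N_u <- length(universe)
  names_sorted <- sort(names(gene_sets$sets), method = "radix")
  rows <- lapply(names_sorted, function(nm) {
    members <- intersect(gene_sets$sets[[nm]], universe)
    hit <- intersect(query, members)
    data.frame(pathway = nm, overlap = length(hit),
               set_size = length(members), query_size = n,
               universe_size = N_u,
               p_value = hypergeom_upper_tail(length(hit),
                                              length(members), n, N_u),
               overlap_genes = paste(sort(hit, method = "radix"),
                                     collapse = "|"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  # every pathway is a performed test: adjust across all, report k >= 1
  res$adjusted_p <- bh_adjust(res$p_value)
  res <- res[res$overlap >= 1L, , drop = FALSE]
  res$significant <- res$adjusted_p < alpha
  res <- res[order(res$adjusted_p, res$pathway, method = "radix"), ,
             drop = FALSE]
  res <- res[, c("pathway", "overlap", "set_size", "query_size",
                 "universe_size", "p_value", "adjusted_p", "significant",
                 "overlap_genes")]
  rownames(res) <- NULL
  res
}
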