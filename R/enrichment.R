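#' Hypergeometric upper-tail probability for over-representation
#'
#' Probability of observing `k` or more seed genes in a gene set of size
#' `K`, when `n` seed genes are drawn without replacement from a universe
#' of `N` genes: `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. This is
#' the one-sided Fisher exact test of enrichment. Exact via
#' [stats::phyper()].
#'
#' @param k Seed genes in the set.
#' @param K Set size within the universe.
#' @param n Seed genes in the universe.
#' @param N Universe size.
#' @return The tail probability, a scalar in `[0, 1]`.
#' @examples
#' hypergeom_sf(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_sf <- function(k, K, n, N) {
  check_counts(k, K, n, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_counts <- function(k, K, n, N) {
  v <- c(k = k, K = K, n = n, N = N)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
    stop("counts must be non-negative integers")
  if (K > N) stop("invariant violated: K <= N (", K, " > ", N, ")")
  if (n > N) stop("invariant violated: n <= N (", n, " > ", N, ")")
  if (k > min(K, n))
    stop("invariant violated: k <= min(K, n) (", k, " > ", min(K, n), ")")
  invisible(TRUE)
}

#' Test one gene set for seed-gene over-representation
#'
#' Both the seed list and the gene set are restricted to the universe
#' before counting, so genes absent from the annotation background never
#' contribute. A set disjoint from the seeds (or absent from the universe)
#' gets `p = 1`.
#'
#' @param seed A [seed_list()].
#' @param gene_set A [gene_set()].
#' @param universe Character vector of background gene symbols.
#' @param alternative `"greater"` (default, enrichment upper tail) or
#'   `"two.sided"` (Fisher exact two-sided, via [stats::fisher.test()]).
#' @return One-row data.frame: `set_id`, `name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `seed_genes` (comma-joined seed members of the set).
#' @export
enrich_term <- function(seed, gene_set, universe,
                        alternative = c("greater", "two.sided")) {
  stopifnot(inherits(seed, "seed_list"), inherits(gene_set, "gene_set"))
  alternative <- match.arg(alternative)
  universe <- normalize_symbols(universe)
  if (length(universe) == 0L) stop("universe must be non-empty")
  s <- intersect(seed$genes, universe)
  m <- intersect(gene_set$members, universe)
  hits <- intersect(s, m)
  k <- length(hits); K <- length(m); n <- length(s); N <- length(universe)
  p <- if (alternative == "greater") {
    hypergeom_sf(k, K, n, N)
  } else {
    fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2))$p.value
  }
  data.frame(set_id = gene_set$set_id, name = gene_set$name,
             k = k, K = K, n = n, N = N, p_value = p,
             seed_genes = paste(sort(hits), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns the BH-adjusted values in the input order:
#' `q_(i) = min_(j >= i) min(1, p_(j) * m / j)` over the ascending order
#' statistics. Thin validation wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Over-representation analysis of a seed list against a collection
#'
#' Tests every set in the collection, adjusts across all tested sets by
#' Benjamini-Hochberg, then applies the study's reporting filters: keep a
#' set when it contains at least `min_seed_genes` seed genes and its FDR is
#' below `fdr_threshold`. Results are ordered by ascending p, ties broken
#' by `set_id`.
#'
#' @inheritParams enrich_term
#' @param collection A [gene_set_collection()].
#' @param universe Background symbols; defaults to the union of all genes
#'   annotated in `collection`. The choice of background changes p-values
#'   materially; supply the annotation service's universe to mimic one.
#' @param min_seed_genes Minimum seed-gene count `k` to report (default 5).
#' @param fdr_threshold Keep sets with `fdr < fdr_threshold` (default 0.05).
#' @param prune_subsets If `TRUE`, drop a kept set whose seed members are a
#'   subset of another kept set with smaller p (a crude redundancy filter
#'   standing in for semantic-similarity pruning); off by default.
#' @return data.frame with columns `set_id`, `name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, `seed_genes`.
#' @export
run_enrichment <- function(seed, collection, universe = NULL,
                           min_seed_genes = 5, fdr_threshold = 0.05,
                           alternative = c("greater", "two.sided"),
                           prune_subsets = FALSE) {
  stopifnot(inherits(seed, "seed_list"),
            inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop("collection is empty")
  if (min_seed_genes < 1) stop("min_seed_genes must be >= 1")
  if (fdr_threshold < 0 || fdr_threshold > 1)
    stop("fdr_threshold must lie in [0, 1]")
  alternative <- match.arg(alternative)
  if (is.null(universe)) universe <- collection_universe(collection)
  rows <- lapply(collection$sets, enrich_term, seed = seed,
                 universe = universe, alternative = alternative)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- bh_adjust(res$p_value)
  # fdr_threshold = 1 disables the FDR filter (an adjusted value can equal 1)
  keep_fdr <- if (fdr_threshold >= 1) rep(TRUE, nrow(res)) else res$fdr < fdr_threshold
  res <- res[res$k >= min_seed_genes & keep_fdr, , drop = FALSE]
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  if (prune_subsets && nrow(res) > 1) {
    members <- strsplit(res$seed_genes, ",", fixed = TRUE)
    drop <- logical(nrow(res))
    for (i in seq_len(nrow(res))[-1]) {
      for (j in seq_len(i - 1)) {
        if (!drop[j] && all(members[[i]] %in% members[[j]])) {
          drop[i] <- TRUE; break
        }
      }
    }
    res <- res[!drop, , drop = FALSE]
  }
  res <- res[, c("set_id", "name", "k", "K", "n", "N",
                 "p_value", "fdr", "seed_genes")]
  rownames(res) <- NULL
  res
}

#' Write an enrichment table as TSV
#'
#' Fixed column order; p-values rendered in scientific notation with at
#' least six significant digits.
#'
#' @param result data.frame from [run_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  out <- result
  out$p_value <- formatC(out$p_value, format = "e", digits = 6)
  out$fdr <- formatC(out$fdr, format = "e", digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
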