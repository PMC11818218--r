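#' Two-sided Fisher exact p-value for a 2x2 enrichment table
#'
#' The table is (k, n-k; K-k, N-n-K+k): `k` differential proteins carrying a
#' term, out of `n` differential and `K` term-carrying proteins in a
#' background of `N`. Two-sided by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins that
#' are no more probable than the observed one (the convention of
#' `stats::fisher.test`, including its relative tolerance on "no more
#' probable"). Vectorized over `k`, `n`, `K`, `N`.
#'
#' @param k,n,K,N integer vectors (recycled).
#' @return numeric p-values in \[0, 1\].
#' @export
fisher_exact_p <- function(k, n, K, N) {
  args <- cbind(k = k, n = n, K = K, N = N)
  apply(args, 1, function(a) {
    lo <- max(0, a[["n"]] + a[["K"]] - a[["N"]])
    if (a[["k"]] > min(a[["n"]], a[["K"]]) || a[["k"]] < lo)
      stop("impossible 2x2 table")
    fisher_p_margin(a[["n"]], a[["K"]], a[["N"]])[a[["k"]] - lo + 1]
  })
}

#' Fisher p-values for every table with fixed margins
#'
#' Returns the two-sided minimum-likelihood p for each possible count `k`
#' (from `max(0, n+K-N)` to `min(n, K)`) under fixed margins, in one pass.
#' This is the engine behind [fisher_exact_p].
#'
#' @inheritParams fisher_exact_p
#' @return numeric vector of p-values, one per admissible `k` in order.
#' @export
fisher_p_margin <- function(n, K, N) {
  kk <- max(0, n + K - N):min(n, K)
  probs <- stats::dhyper(kk, K, N - K, n)
  # p(k) = sum of all table probabilities not exceeding that of table k
  pmin(1, colSums(probs * outer(probs, probs * (1 + 1e-7), `<=`)))
}

#' Fisher-exact enrichment of differential proteins
#'
#' Tests each annotation term of a namespace for over/under-representation
#' among differential proteins relative to a background universe (by default
#' all proteins bearing quantified modification sites). Terms with no
#' differential carrier (k = 0) are skipped. Raw p < `alpha` flags
#' significance; Benjamini-Hochberg adjusted p-values are reported alongside.
#'
#' @param diff_proteins character vector of differential protein ids (subset
#'   of `background`).
#' @param background character vector: the background protein universe.
#' @param annotations annotation tibble ([read_annotation]).
#' @param namespace one of GO-BP, GO-CC, GO-MF, KEGG, DOMAIN, COMPARTMENT.
#' @param alpha raw-p significance level (default 0.05).
#' @return tibble: `namespace`, `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_value`, `p_adj`, `significant`; sorted by p.
#' @export
fisher_enrich <- function(diff_proteins, background, annotations, namespace,
                          alpha = 0.05) {
  stopifnot(namespace %in% ANNOTATION_NAMESPACES)
  diff_proteins <- unique(diff_proteins)
  background <- unique(background)
  if (!all(diff_proteins %in% background))
    stop("diff_proteins must be a subset of the background universe")
  ann <- annotations[annotations$namespace == namespace &
                       annotations$protein_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(diff_proteins)
  by_term <- split(ann$protein_id, ann$term_id)
  term_names <- ann$term_name[!duplicated(ann$term_id)]
  names(term_names) <- ann$term_id[!duplicated(ann$term_id)]
  rows <- lapply(names(by_term), function(tid) {
    carriers <- unique(by_term[[tid]])
    k <- sum(diff_proteins %in% carriers)
    if (k < 1) return(NULL)   # term untouched by differential set
    K <- length(carriers)
    tibble::tibble(namespace = namespace, term_id = tid,
                   term_name = unname(term_names[tid]),
                   k = k, n = n, K = K, N = N,
                   fold_enrichment = (k / n) / (K / N),
                   p_value = fisher_exact_p(k, n, K, N))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(tibble::tibble(namespace = character(), term_id = character(),
                          term_name = character(), k = integer(), n = integer(),
                          K = integer(), N = integer(),
                          fold_enrichment = numeric(), p_value = numeric(),
                          p_adj = numeric(), significant = logical()))
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out[order(out$p_value, out$term_id), ]
}

#' Per-Q-group enrichment matrix with hierarchical clustering
#'
#' Runs [fisher_enrich] within each fold-change group (Q1-Q4) of the
#' differential records, keeps the union of terms significant in at least one
#' group, and assembles a term x group matrix of -log10(p). Rows (and
#' columns, when more than two) are ordered by average-linkage hierarchical
#' clustering with Euclidean distance; missing cells count as 0 for the
#' distance only and stay `NA` in the matrix.
#'
#' @param records differential tibble ([differential_analysis]) plus a
#'   `protein_id` column (site-to-protein mapping).
#' @param annotations annotation tibble.
#' @param namespace annotation namespace to test.
#' @param background background protein universe; defaults to all proteins in
#'   `records` (proteins with quantified sites).
#' @param alpha significance level for term inclusion.
#' @return list: `matrix` (-log10 p, clustered order), `results` (long tibble
#'   with per-group [fisher_enrich] output), `row_hclust`, `metadata`.
#' @export
q_group_enrichment <- function(records, annotations, namespace,
                               background = NULL, alpha = 0.05) {
  stopifnot("protein_id" %in% names(records))
  if (is.null(background)) background <- unique(records$protein_id)
  groups <- intersect(c("Q1", "Q2", "Q3", "Q4"), unique(records$q_group))
  res <- lapply(groups, function(g) {
    prot <- unique(records$protein_id[records$q_group == g])
    r <- fisher_enrich(prot, background, annotations, namespace, alpha)
    if (nrow(r)) r$group <- g
    r
  })
  res <- do.call(rbind, res[vapply(res, nrow, integer(1)) > 0])
  if (is.null(res) || !nrow(res))
    return(list(matrix = matrix(numeric(0), 0, 0), results = res,
                row_hclust = NULL,
                metadata = list(linkage = "average", distance = "euclidean")))
  keep_terms <- unique(res$term_id[res$significant])
  res_kept <- res[res$term_id %in% keep_terms, , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(keep_terms), ncol = length(groups),
              dimnames = list(sort(keep_terms), groups))
  for (i in seq_len(nrow(res_kept)))
    m[res_kept$term_id[i], res_kept$group[i]] <- -log10(res_kept$p_value[i])
  row_hc <- NULL
  if (nrow(m) > 2) {
    m0 <- m; m0[is.na(m0)] <- 0
    row_hc <- stats::hclust(stats::dist(m0), method = "average")
    m <- m[row_hc$order, , drop = FALSE]
  } else if (nrow(m) > 0) {
    m <- m[order(-apply(m, 1, max, na.rm = TRUE)), , drop = FALSE]
  }
  list(matrix = m, results = res_kept, row_hclust = row_hc,
       metadata = list(linkage = "average", distance = "euclidean",
                       alpha = alpha, namespace = namespace))
}

#' Category composition summary
#'
#' Counts and percentages of proteins per annotation term (the pie/bar
#' subcellular-compartment style summary). A protein with several terms is
#' counted once per term, so percentages may sum above 100.
#'
#' @param proteins character vector of protein ids to summarize.
#' @param annotations annotation tibble.
#' @param namespace annotation namespace.
#' @return tibble: `term_id`, `term_name`, `count`, `percent` (of supplied
#'   proteins), sorted by count.
#' @export
category_summary <- function(proteins, annotations, namespace) {
  proteins <- unique(proteins)
  ann <- annotations[annotations$namespace == namespace &
                       annotations$protein_id %in% proteins, , drop = FALSE]
  if (!nrow(ann))
    return(tibble::tibble(term_id = character(), term_name = character(),
                          count = integer(), percent = numeric()))
  by_term <- split(unique(ann[c("protein_id", "term_id")])$protein_id,
                   unique(ann[c("protein_id", "term_id")])$term_id)
  term_names <- ann$term_name[!duplicated(ann$term_id)]
  names(term_names) <- ann$term_id[!duplicated(ann$term_id)]
  counts <- vapply(by_term, length, integer(1))
  out <- tibble::tibble(term_id = names(counts),
                        term_name = unname(term_names[names(counts)]),
                        count = unname(counts),
                        percent = 100 * unname(counts) / length(proteins))
  out[order(-out$count, out$term_id), ]
}
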