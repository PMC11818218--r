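#' Score-filtered interaction subnetwork of differential proteins
#'
#' Keeps edges with confidence strictly above `score_min` (high-confidence
#' interactions) whose two endpoints are both differential proteins, computes node
#' degree on that filtered graph, and ranks nodes by degree (ties by id) to
#' select the `top_n` most connected proteins.
#'
#' @param edges edge tibble ([read_edge_table]).
#' @param records differential tibble with `protein_id` and `regulation`
#'   columns.
#' @param score_min minimum confidence score, exclusive (default 0.7).
#' @param top_n number of hub proteins to report (default 50).
#' @return list: `nodes` (top-n tibble: `protein_id`, `degree`, `regulation`,
#'   `rank`), `all_nodes` (every node of the filtered graph), `edges`
#'   (filtered edge tibble).
#' @export
build_network <- function(edges, records, score_min = 0.7, top_n = 50L) {
  diff_prot <- unique(records$protein_id[records$regulation != "NS"])
  keep <- edges$score > score_min &
    edges$protein_a %in% diff_prot & edges$protein_b %in% diff_prot
  fe <- edges[keep, , drop = FALSE]
  if (!nrow(fe)) {
    warning("no edges pass the confidence/differential filter")
    empty <- tibble::tibble(protein_id = character(), degree = integer(),
                            regulation = character(), rank = integer())
    return(list(nodes = empty, all_nodes = empty, edges = fe))
  }
  g <- igraph::graph_from_data_frame(fe[c("protein_a", "protein_b")],
                                     directed = FALSE)
  deg <- igraph::degree(g)
  reg_of <- records$regulation[match(names(deg), records$protein_id)]
  nodes <- tibble::tibble(protein_id = names(deg), degree = as.integer(deg),
                          regulation = reg_of)
  nodes <- nodes[order(-nodes$degree, nodes$protein_id), ]
  nodes$rank <- seq_len(nrow(nodes))
  list(nodes = utils::head(nodes, top_n), all_nodes = nodes, edges = fe)
}

#' Dataset-level quality control summary
#'
#' Per-sample five-number summaries (and counts) of log10 raw site
#' intensities over observed values, plus a sample-level PCA of the relative
#' quantification matrix: sites with any missing value are excluded
#' (complete cases, no imputation), each site column is mean-centered, and
#' the variance-explained fraction of each component is reported.
#'
#' @param r `relquant` (or matrix) of relative values.
#' @param raw [site_table] with the raw intensities.
#' @return list: `sample_summary` tibble (`sample`, `group`, `n_observed`,
#'   `min`, `q1`, `median`, `q3`, `max` of log10 intensity), `pca` (list with
#'   `variance_fraction`, `scores`, `n_sites_used`).
#' @export
qc_report <- function(r, raw) {
  m <- raw$intensities
  ss <- lapply(colnames(m), function(s) {
    x <- log10(m[, s][!is.na(m[, s])])
    q <- stats::quantile(x, c(0, .25, .5, .75, 1), names = FALSE)
    tibble::tibble(sample = s, group = unname(raw$groups[s]),
                   n_observed = length(x), min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5])
  })
  v <- if (inherits(r, "relquant")) r$values else as.matrix(r)
  complete <- v[stats::complete.cases(v), , drop = FALSE]
  message("qc_report: PCA on ", nrow(complete), " complete sites (",
          nrow(v) - nrow(complete), " excluded)")
  pca <- NULL
  if (nrow(complete) >= 2) {
    # samples are the observations, sites the variables
    fit <- stats::prcomp(t(complete), center = TRUE, scale. = FALSE)
    vf <- fit$sdev^2 / sum(fit$sdev^2)
    pca <- list(variance_fraction = vf, scores = fit$x,
                n_sites_used = nrow(complete))
  }
  list(sample_summary = do.call(rbind, ss), pca = pca)
}
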