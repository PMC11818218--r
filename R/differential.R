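#' Fold change of group means of relative values
#'
#' FC(site) = mean of observed relative values in group A divided by the mean
#' in group B (treatment over control). A site with no observed value in one
#' of the groups gets `NA`.
#'
#' @param r `relquant` (or plain matrix) of relative values.
#' @param group_a,group_b character vectors of sample ids.
#' @return named numeric vector site -> fold change.
#' @export
fold_change <- function(r, group_a, group_b) {
  v <- if (inherits(r, "relquant")) r$values else as.matrix(r)
  stopifnot(all(c(group_a, group_b) %in% colnames(v)))
  ma <- rowMeans(v[, group_a, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(v[, group_b, drop = FALSE], na.rm = TRUE)
  fc <- ma / mb
  fc[!is.finite(fc)] <- NA_real_
  fc
}

#' Coefficient of variation of paired replicate ratios
#'
#' For each site, replicate m of group A is paired with replicate m of group
#' B in column order (A1/B1, A2/B2, ...). The CV is the sample standard
#' deviation (n-1 denominator) of the complete-pair ratios divided by their
#' mean. This is the reproducibility index used in place of a t-test when a
#' design has too few replicates: a small CV means the treated/control ratio
#' is consistent across replicate pairs.
#'
#' @inheritParams fold_change
#' @return list with `cv` (named vector; `NA` when fewer than 2 complete
#'   pairs) and `n_pairs` (complete pairs used per site).
#' @export
cv_statistic <- function(r, group_a, group_b) {
  v <- if (inherits(r, "relquant")) r$values else as.matrix(r)
  stopifnot(all(c(group_a, group_b) %in% colnames(v)))
  n_pair <- min(length(group_a), length(group_b))
  a <- v[, group_a[seq_len(n_pair)], drop = FALSE]
  b <- v[, group_b[seq_len(n_pair)], drop = FALSE]
  ratios <- a / b
  cv <- apply(ratios, 1, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / mean(x)
  })
  n_pairs <- apply(ratios, 1, function(x) sum(is.finite(x)))
  list(cv = cv, n_pairs = n_pairs)
}

#' Per-site Welch t-test on log2 relative values
#'
#' Computed only when both groups have at least 3 observed values; smaller
#' designs (e.g. duplicates) return `NA` and fall back to the CV criterion
#' downstream. Degenerate sites with zero variance in both groups give p = 1
#' when the group means are equal and p = 0 otherwise.
#'
#' @inheritParams fold_change
#' @param min_n minimum observed values per group for the test.
#' @return named numeric vector site -> two-sided p (`NA` if not computable).
#' @export
site_t_test <- function(r, group_a, group_b, min_n = 3L) {
  v <- if (inherits(r, "relquant")) r$values else as.matrix(r)
  a <- log2(v[, group_a, drop = FALSE])
  b <- log2(v[, group_b, drop = FALSE])
  vapply(seq_len(nrow(v)), function(i) {
    xa <- a[i, ][is.finite(a[i, ])]
    xb <- b[i, ][is.finite(b[i, ])]
    if (length(xa) < min_n || length(xb) < min_n) return(NA_real_)
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    stats::t.test(xa, xb)$p.value
  }, numeric(1)) |> stats::setNames(rownames(v))
}

#' Call regulation status from fold change, CV and p-value
#'
#' A site is significant when its t-test p is below `alpha`, or — when no
#' t-test is computable (small designs) — when its CV is below
#' `cv_threshold`. Significant sites with fold change strictly above
#' `fc_threshold` are UP, strictly below `1/fc_threshold` are DOWN;
#' everything else is NS. A fold change exactly at the threshold is NS.
#'
#' @param fc numeric vector of fold changes.
#' @param cv numeric vector of CVs (`NA` allowed).
#' @param p numeric vector of p-values (`NA` allowed).
#' @param fc_threshold up-regulation threshold (default 1.5).
#' @param cv_threshold reproducibility threshold (default 0.1).
#' @param alpha significance level for the t-test route (default 0.05).
#' @return character vector in \{"UP", "DOWN", "NS"\} (`NA` fc gives NS).
#' @export
call_regulation <- function(fc, cv = NULL, p = NULL, fc_threshold = 1.5,
                            cv_threshold = 0.1, alpha = 0.05) {
  n <- length(fc)
  if (is.null(cv)) cv <- rep(NA_real_, n)
  if (is.null(p)) p <- rep(NA_real_, n)
  sig <- ifelse(!is.na(p), p < alpha, !is.na(cv) & cv < cv_threshold)
  out <- rep("NS", n)
  out[sig & !is.na(fc) & fc > fc_threshold] <- "UP"
  out[sig & !is.na(fc) & fc < 1 / fc_threshold] <- "DOWN"
  names(out) <- names(fc)
  out
}

#' Assign fold-change magnitude groups Q1-Q4
#'
#' Regulated sites are binned by fold change for stratified enrichment:
#' Q1: fc <= 1/2; Q2: 1/2 < fc < 1/1.5 (moderate down); Q3: 1.5 < fc <= 2;
#' Q4: fc > 2 (strong up). Non-significant sites get "NONE". Bounds are
#' overridable via `bounds = c(lower, inner)` with defaults (2, 1.5).
#'
#' @param fc numeric fold changes.
#' @param regulation character vector from [call_regulation].
#' @param bounds numeric length 2: outer and inner fold-change bounds.
#' @return character vector in \{"Q1".."Q4", "NONE"\}.
#' @export
assign_q_group <- function(fc, regulation, bounds = c(2, 1.5)) {
  outer_b <- bounds[1]; inner_b <- bounds[2]
  out <- rep("NONE", length(fc))
  reg <- regulation != "NS" & !is.na(fc)
  out[reg & fc <= 1 / outer_b] <- "Q1"
  out[reg & fc > 1 / outer_b & fc < 1 / inner_b] <- "Q2"
  out[reg & fc > inner_b & fc <= outer_b] <- "Q3"
  out[reg & fc > outer_b] <- "Q4"
  names(out) <- names(fc)
  out
}

#' Full differential screen over a relative-quant matrix
#'
#' Runs [fold_change], [cv_statistic] and [site_t_test], then
#' [call_regulation] and [assign_q_group], returning one record per site.
#' Sites whose fold change is undefined (a group entirely missing) are
#' excluded with a message.
#'
#' @inheritParams fold_change
#' @inheritParams call_regulation
#' @return tibble: `site_id`, `fc`, `cv`, `n_pairs`, `p_value`, `regulation`,
#'   `q_group`.
#' @export
differential_analysis <- function(r, group_a, group_b, fc_threshold = 1.5,
                                  cv_threshold = 0.1, alpha = 0.05) {
  fc <- fold_change(r, group_a, group_b)
  cvs <- cv_statistic(r, group_a, group_b)
  p <- site_t_test(r, group_a, group_b)
  drop <- is.na(fc)
  if (any(drop))
    message("differential_analysis: ", sum(drop),
            " site(s) without a defined fold change excluded")
  reg <- call_regulation(fc, cvs$cv, p, fc_threshold, cv_threshold, alpha)
  qg <- assign_q_group(fc, reg)
  tibble::tibble(site_id = names(fc), fc = unname(fc), cv = unname(cvs$cv),
                 n_pairs = unname(cvs$n_pairs), p_value = unname(p),
                 regulation = unname(reg), q_group = unname(qg))[!drop, ]
}

#' Completeness filter for the differential heatmap
#'
#' Keeps differential (UP/DOWN) sites quantified in at least
#' `ceiling(min_fraction * n_samples)` samples, and returns the matching
#' relative-value rows for plotting (missing cells stay `NA`).
#'
#' @param records tibble from [differential_analysis].
#' @param r `relquant` (or matrix) the records were computed from.
#' @param min_fraction minimum fraction of samples quantified (default 2/3).
#' @return list: `site_ids` kept, `matrix` of their relative values.
#' @export
heatmap_filter <- function(records, r, min_fraction = 2 / 3) {
  v <- if (inherits(r, "relquant")) r$values else as.matrix(r)
  need <- ceiling(min_fraction * ncol(v))
  diff_ids <- records$site_id[records$regulation != "NS"]
  obs <- rowSums(!is.na(v[diff_ids, , drop = FALSE]))
  keep <- diff_ids[obs >= need]
  list(site_ids = keep, matrix = v[keep, , drop = FALSE])
}

#' Select the top differential sites
#'
#' Ranks differential (UP/DOWN) sites by |log2 fold change| descending, ties
#' broken by smaller CV and then site id, and returns the first `n`.
#'
#' @param records tibble from [differential_analysis].
#' @param n number of sites (default 30).
#' @return tibble of the top records in rank order, with `rank` column.
#' @export
top_n_sites <- function(records, n = 30L) {
  rec <- records[records$regulation != "NS", , drop = FALSE]
  score <- abs(log2(rec$fc))
  cv_key <- ifelse(is.na(rec$cv), Inf, rec$cv)
  ord <- order(-score, cv_key, rec$site_id)
  out <- rec[utils::head(ord, n), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Write differential records as TSV
#' @param records tibble from [differential_analysis]
#' @param path output path
#' @export
write_differential <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
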