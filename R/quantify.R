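#' Centralize intensities into relative quantitative values
#'
#' Each row (site or protein) is divided by its own mean over the observed
#' samples, so complete rows average exactly 1. This removes per-site scale
#' while keeping between-sample structure, and is the first step of the
#' relative quantification cascade. Rows with fewer than two observed values
#' carry no between-sample information and are dropped.
#'
#' @param x a [site_table], a `protein_quant`, or a numeric matrix with
#'   rownames (rows = features, columns = samples; `NA` = missing).
#' @param min_observed minimum non-missing values a row needs to be kept.
#' @return a `relquant` object: list with `values` (matrix of relative
#'   values, strictly positive where present), `corrected = FALSE`,
#'   `dropped` (ids of excluded rows) and `flags`.
#' @examples
#' m <- matrix(c(10, 20, 30, 40), nrow = 1,
#'             dimnames = list("s1", paste0("S", 1:4)))
#' centralize(m)$values  # 0.4 0.8 1.2 1.6
#' @export
centralize <- function(x, min_observed = 2L) {
  m <- if (inherits(x, "site_table")) x$intensities
       else if (inherits(x, "protein_quant")) x$intensities
       else as.matrix(x)
  n_obs <- rowSums(!is.na(m))
  keep <- n_obs >= min_observed
  if (any(!keep))
    message("centralize: dropped ", sum(!keep),
            " row(s) with < ", min_observed, " observed values")
  dropped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  r <- m / rowMeans(m, na.rm = TRUE)
  structure(list(values = r, corrected = FALSE, dropped = dropped,
                 flags = character(0)),
            class = "relquant")
}

#' @export
print.relquant <- function(x, ...) {
  cat("relquant:", nrow(x$values), "rows x", ncol(x$values), "samples;",
      if (x$corrected) "protein-corrected" else "uncorrected", "\n")
  if (length(x$dropped)) cat("dropped rows:", length(x$dropped), "\n")
  if (length(x$flags)) cat("fallback (uncorrected) sites:", length(x$flags), "\n")
  invisible(x)
}

#' Correct site-level relative values by parent-protein abundance
#'
#' Divides each site's relative value by the parent protein's relative value
#' in the same sample, removing apparent regulation that only reflects a
#' change in protein expression. The correction is cell-wise: where the
#' protein is absent from the protein table or missing in a sample, the site
#' value is kept unchanged and the site is flagged, so a single dropout does
#' not discard the site.
#'
#' @param site_r `relquant` from [centralize] on the site table.
#' @param protein_r `relquant` from [centralize] on the protein table.
#' @param site_meta tibble with `site_id`, `protein_id` (e.g. `x$meta` of the
#'   [site_table]).
#' @return a `relquant` with `corrected = TRUE`; `flags` lists sites with at
#'   least one uncorrected cell.
#' @export
correct_by_protein <- function(site_r, protein_r, site_meta) {
  stopifnot(inherits(site_r, "relquant"), inherits(protein_r, "relquant"))
  v <- site_r$values
  parent <- site_meta$protein_id[match(rownames(v), site_meta$site_id)]
  if (anyNA(parent)) stop("sites missing from site_meta: ",
                          paste(rownames(v)[is.na(parent)], collapse = ", "))
  pv <- protein_r$values[match(parent, rownames(protein_r$values)), ,
                         drop = FALSE]
  pv <- pv[, colnames(v), drop = FALSE]
  corrected <- v / pv
  # fall back to the uncorrected value where the protein value is unavailable
  fallback <- is.na(pv) & !is.na(v)
  corrected[fallback] <- v[fallback]
  flagged <- rownames(v)[rowSums(fallback) > 0 | is.na(match(parent, rownames(protein_r$values)))]
  structure(list(values = corrected, corrected = TRUE,
                 dropped = site_r$dropped, flags = unique(flagged)),
            class = "relquant")
}

#' Write a relative-quantification matrix as TSV
#'
#' One row per site, one column per sample, plus a `flags` column marking
#' sites with any uncorrected (fallback) cell.
#'
#' @param r a `relquant`
#' @param path output path
#' @export
write_relquant <- function(r, path) {
  out <- cbind(data.frame(site_id = rownames(r$values)),
               as.data.frame(r$values, check.names = FALSE),
               flags = ifelse(rownames(r$values) %in% r$flags,
                              "uncorrected_cells", ""))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
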