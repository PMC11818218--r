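#' Construct a site-intensity table
#'
#' The central input container: per-site raw intensities across samples,
#' with protein/position/residue identity and localization probability.
#' Missing measurements are `NA`; raw zeros are treated as missing.
#'
#' @param meta tibble with columns `site_id`, `protein_id`, `position`,
#'   `residue`, `localization_prob`.
#' @param intensities numeric matrix, rows = sites (rownames = `site_id`),
#'   columns = samples. Non-negative; `NA` = missing.
#' @param groups named character vector mapping sample id to group label.
#' @return an object of class `site_table`.
#' @export
site_table <- function(meta, intensities, groups) {
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("site_id", "protein_id", "position", "residue",
                  "localization_prob") %in% names(meta)))
  if (anyDuplicated(meta$site_id))
    stop("duplicate site_id: ",
         paste(unique(meta$site_id[duplicated(meta$site_id)]), collapse = ", "))
  if (any(meta$position < 1)) stop("positions must be >= 1")
  bad_res <- setdiff(unique(meta$residue), AA_ALPHABET)
  if (length(bad_res))
    stop("residue not in amino-acid alphabet: ", paste(bad_res, collapse = ", "))
  if (any(meta$localization_prob < 0 | meta$localization_prob > 1, na.rm = TRUE))
    stop("localization_prob must lie in [0, 1]")
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  rownames(intensities) <- meta$site_id
  if (any(intensities < 0, na.rm = TRUE)) stop("negative intensity")
  # zero intensity means "not quantified" in label-free data
  intensities[!is.na(intensities) & intensities == 0] <- NA_real_
  missing_groups <- setdiff(colnames(intensities), names(groups))
  if (length(missing_groups))
    stop("samples without a group assignment: ",
         paste(missing_groups, collapse = ", "))
  groups <- groups[colnames(intensities)]
  structure(list(meta = meta, intensities = intensities, groups = groups),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat("site_table:", nrow(x$meta), "sites x", ncol(x$intensities), "samples\n")
  cat("groups:", paste(sprintf("%s=%s", names(x$groups), x$groups), collapse = " "), "\n")
  cat("missing cells:", sum(is.na(x$intensities)), "\n")
  invisible(x)
}

#' Read a modification-site intensity table
#'
#' Expects a tab-delimited file with header columns `protein_id`, `position`,
#' `residue`, `localization_prob` followed by one intensity column per sample.
#' Site ids are canonicalized as `<protein_id>_K<position>` (more generally
#' `_<residue><position>`). Zero intensities are loaded as missing.
#'
#' @param path file path.
#' @param group_map named character vector: sample id -> group label.
#' @return a [site_table].
#' @export
read_site_table <- function(path, group_map) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "residue", "localization_prob")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(df), required)
  if (!length(sample_cols)) stop("no sample intensity columns found")
  neg <- which(apply(df[sample_cols] < 0, 1, any, na.rm = TRUE))
  if (length(neg)) stop("negative intensity at row(s): ", paste(neg, collapse = ", "))
  meta <- tibble::tibble(
    site_id = paste0(df$protein_id, "_", df$residue, df$position),
    protein_id = as.character(df$protein_id),
    position = as.integer(df$position),
    residue = as.character(df$residue),
    localization_prob = as.numeric(df$localization_prob)
  )
  tab <- site_table(meta, as.matrix(df[sample_cols]), group_map)
  message("read_site_table: ", nrow(meta), " sites, ",
          length(sample_cols), " samples from ", path)
  tab
}

#' Write a site-intensity table (tab-delimited, `NA` for missing)
#' @param x a [site_table]
#' @param path output path
#' @export
write_site_table <- function(x, path) {
  out <- cbind(as.data.frame(x$meta[, c("protein_id", "position", "residue",
                                        "localization_prob")]),
               as.data.frame(x$intensities, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' IDs are the first whitespace-delimited header token; sequences are
#' uppercased. Ambiguity letters (U/B/Z/X) are kept but reported.
#'
#' @param path FASTA file.
#' @return named character vector protein_id -> sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  n_amb <- sum(vapply(out, function(s)
    sum(strsplit(s, "")[[1]] %in% AA_AMBIGUOUS), integer(1)))
  if (n_amb > 0)
    message("read_fasta: ", n_amb, " ambiguous residues (U/B/Z/X) retained")
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a protein-level quantification table
#'
#' Tab-delimited: `protein_id` then one intensity column per sample.
#' Zeros become missing, mirroring the site table convention.
#'
#' @param path file path.
#' @return list with `intensities` matrix (rownames = protein_id), class
#'   `protein_quant`.
#' @export
read_protein_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(df)) stop("missing required column(s): protein_id")
  if (anyDuplicated(df$protein_id))
    stop("duplicate protein_id: ",
         paste(unique(df$protein_id[duplicated(df$protein_id)]), collapse = ", "))
  m <- as.matrix(df[setdiff(names(df), "protein_id")])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein_id
  if (any(m < 0, na.rm = TRUE)) stop("negative intensity")
  m[!is.na(m) & m == 0] <- NA_real_
  structure(list(intensities = m), class = "protein_quant")
}

#' Write a protein quantification table
#' @param x `protein_quant` object or intensity matrix with protein rownames
#' @param path output path
#' @export
write_protein_table <- function(x, path) {
  m <- if (inherits(x, "protein_quant")) x$intensities else x
  out <- cbind(data.frame(protein_id = rownames(m)),
               as.data.frame(m, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an annotation map (protein -> functional terms)
#'
#' Tab-delimited columns: `protein_id`, `namespace`, `term_id`, `term_name`.
#' Namespace must be one of GO-BP, GO-CC, GO-MF, KEGG, DOMAIN, COMPARTMENT.
#' Exact duplicate (protein, namespace, term) rows are collapsed.
#'
#' @param path file path.
#' @return tibble with the four columns, deduplicated.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("protein_id", "namespace", "term_id", "term_name")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$namespace), ANNOTATION_NAMESPACES)
  if (length(bad)) stop("unknown annotation namespace: ", paste(bad, collapse = ", "))
  df <- df[!duplicated(df[c("protein_id", "namespace", "term_id")]), , drop = FALSE]
  tibble::as_tibble(df[required])
}

#' Read a protein-interaction edge table
#'
#' Tab-delimited columns: `protein_a`, `protein_b`, `score` (confidence in
#' \[0,1\]). Edges are undirected: (a,b) and (b,a) are merged keeping the
#' maximum score; self-loops are dropped with a warning.
#'
#' @param path file path.
#' @return tibble `protein_a`, `protein_b`, `score` with `protein_a < protein_b`.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("protein_a", "protein_b", "score")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (any(df$score < 0 | df$score > 1, na.rm = TRUE))
    stop("edge scores must lie in [0, 1]")
  loops <- df$protein_a == df$protein_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    df <- df[!loops, , drop = FALSE]
  }
  if (!nrow(df))
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          score = numeric()))
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  key <- paste(a, b, sep = "\r")
  score <- vapply(split(df$score, key), max, numeric(1))
  keys <- strsplit(names(score), "\r", fixed = TRUE)
  out <- tibble::tibble(protein_a = vapply(keys, `[`, character(1), 1L),
                        protein_b = vapply(keys, `[`, character(1), 2L),
                        score = unname(score))
  out[order(out$protein_a, out$protein_b), ]
}

#' Write an edge table
#' @param edges tibble as returned by [read_edge_table]
#' @param path output path
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an annotation map
#' @param ann tibble as returned by [read_annotation]
#' @param path output path
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
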