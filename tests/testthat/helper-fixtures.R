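# small in-code fixtures shared across test files

# 4 sites x 4 samples (C1 C2 SA1 SA2), complete unless values supplied
make_site_fixture <- function(values = NULL) {
  samples <- c("C1", "C2", "SA1", "SA2")
  meta <- tibble::tibble(
    site_id = paste0("P", 1:4, "_K", c(10, 20, 30, 40)),
    protein_id = paste0("P", 1:4),
    position = c(10L, 20L, 30L, 40L),
    residue = "K",
    localization_prob = c(0.99, 0.95, 0.8, 1))
  if (is.null(values))
    values <- matrix(c(10, 20, 30, 40,
                       5, 5, 5, 5,
                       8, NA, 24, 16,
                       100, 200, 50, 25), nrow = 4, byrow = TRUE)
  colnames(values) <- samples
  site_table(meta, values,
             c(C1 = "C", C2 = "C", SA1 = "SA", SA2 = "SA"))
}

write_fixture_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

fixture_group_map <- c(C1 = "C", C2 = "C", SA1 = "SA", SA2 = "SA")

# site TSV data.frame in the on-disk dialect
site_tsv_df <- function() {
  data.frame(protein_id = paste0("P", 1:4),
             position = c(10, 20, 30, 40), residue = "K",
             localization_prob = c(0.99, 0.95, 0.8, 1),
             C1 = c(10, 5, 8, 100), C2 = c(20, 5, 0, 200),
             SA1 = c(30, 5, 24, 50), SA2 = c(40, 5, 16, 25),
             check.names = FALSE)
}

# random relquant-like matrix with sample names split in two groups
random_rel_matrix <- function(n_sites, seed = 1, missing_rate = 0) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_sites * 4), n_sites, 4,
              dimnames = list(paste0("s", seq_len(n_sites)),
                              c("C1", "C2", "SA1", "SA2")))
  if (missing_rate > 0) m[runif(length(m)) < missing_rate] <- NA
  m
}

# random windows drawn from a residue frequency vector (no pads)
random_windows <- function(n, freq, seed = 1) {
  set.seed(seed)
  aa <- names(freq)
  vapply(seq_len(n), function(i) {
    chars <- sample(aa, 21, replace = TRUE, prob = freq)
    chars[11] <- "K"
    paste(chars, collapse = "")
  }, character(1))
}

uniform_freq <- function() setNames(rep(1 / 20, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
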