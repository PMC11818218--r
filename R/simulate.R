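#' Simulation configuration
#'
#' Describes a synthetic 2-group label-free PTM experiment with planted
#' ground truth: log-normal site intensities, multiplicative replicate
#' noise, differential sites of known fold change, optional
#' protein-abundance confounding, planted sequence motifs and planted
#' enriched annotation terms. Defaults mirror a control-vs-treatment design
#' with two replicates per group.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical bundles.
#' @param n_proteins number of proteins in the synthetic proteome.
#' @param n_sites number of modification sites (placed on lysines).
#' @param n_samples_per_group replicates per group (default 2).
#' @param frac_differential fraction of sites with a planted fold change.
#' @param true_fc_range range the planted up-regulation fold changes are
#'   drawn from (down-regulated sites use reciprocals).
#' @param replicate_noise_sigma_log2 SD of the per-replicate log2
#'   multiplicative noise.
#' @param missing_rate completely-at-random missingness per site cell.
#' @param protein_confounding fraction of differential sites whose intensity
#'   shift is fully explained by parent-protein abundance (removed by
#'   protein correction).
#' @param motif_spec list of lists `(offset, residue, fg_carry, bg_freq)`:
#'   plant `residue` at `offset` from the modified lysine in `fg_carry` of
#'   modified-site windows, with proteome-wide frequency `bg_freq`.
#' @param enriched_terms list of lists `(term_id, carry, background)`: give
#'   the term to differential proteins with probability `carry` and to
#'   others with probability `background`.
#' @param group_labels labels for (control, treatment).
#' @param baseline_log10_mean,baseline_log10_sd log10-normal parameters of
#'   baseline site intensity.
#' @param length_range protein length range (residues).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 300L,
                       n_sites = 1000L,
                       n_samples_per_group = 2L,
                       frac_differential = 0.1,
                       true_fc_range = c(2, 4),
                       replicate_noise_sigma_log2 = 0.1,
                       missing_rate = 0.05,
                       protein_confounding = 0,
                       motif_spec = NULL,
                       enriched_terms = NULL,
                       group_labels = c("C", "SA"),
                       baseline_log10_mean = 7,
                       baseline_log10_sd = 0.5,
                       length_range = c(150L, 600L)) {
  cfg <- list(seed = as.integer(seed), n_proteins = n_proteins,
              n_sites = n_sites, n_samples_per_group = n_samples_per_group,
              frac_differential = frac_differential,
              true_fc_range = true_fc_range,
              replicate_noise_sigma_log2 = replicate_noise_sigma_log2,
              missing_rate = missing_rate,
              protein_confounding = protein_confounding,
              motif_spec = motif_spec, enriched_terms = enriched_terms,
              group_labels = group_labels,
              baseline_log10_mean = baseline_log10_mean,
              baseline_log10_sd = baseline_log10_sd,
              length_range = length_range)
  stopifnot(frac_differential >= 0, frac_differential <= 1,
            missing_rate >= 0, missing_rate < 1,
            protein_confounding >= 0, protein_confounding <= 1,
            all(true_fc_range > 1), n_samples_per_group >= 1)
  class(cfg) <- "sim_config"
  cfg
}

# residue sampling frequencies: uniform, overridden by motif bg frequencies
residue_frequencies <- function(cfg) {
  freq <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  for (ms in cfg$motif_spec) {
    freq[ms$residue] <- ms$bg_freq
    other <- setdiff(AA_ALPHABET, vapply(cfg$motif_spec, `[[`, character(1),
                                         "residue"))
    freq[other] <- (1 - sum(freq[setdiff(AA_ALPHABET, other)])) / length(other)
  }
  if (freq["K"] <= 0) stop("alphabet cannot generate lysines")
  freq / sum(freq)
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' Emits every input the pipeline consumes — site intensities, protein
#' quantification, FASTA, annotations, interaction edges — plus a truth
#' table recording each planted effect, so recovery can be scored exactly.
#'
#' @param cfg a [sim_config].
#' @param out_dir optional directory; when given, the bundle is written as
#'   the tab-delimited/FASTA files the readers consume (plus `truth.tsv`).
#' @return list: `sites` ([site_table]), `proteins` (`protein_quant`),
#'   `fasta` (named character), `annotations`, `edges`, `truth` (list of
#'   `sites` and `proteins` tibbles), `groups`, `config`.
#' @export
simulate_bundle <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  freq <- residue_frequencies(cfg)
  prot_ids <- sprintf("PROT%04d", seq_len(cfg$n_proteins))
  lens <- sample(cfg$length_range[1]:cfg$length_range[2], cfg$n_proteins,
                 replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = freq), collapse = ""),
    character(1))
  names(seqs) <- prot_ids

  # candidate K positions across the proteome
  k_pos <- do.call(rbind, lapply(prot_ids, function(p) {
    pos <- which(strsplit(seqs[[p]], "")[[1]] == "K")
    if (!length(pos)) return(NULL)
    data.frame(protein_id = p, position = pos)
  }))
  if (is.null(k_pos) || nrow(k_pos) < cfg$n_sites)
    stop("proteome has too few lysines for the requested site count")
  picked <- k_pos[sort(sample.int(nrow(k_pos), cfg$n_sites)), ]

  # planted fold changes (treatment over control)
  n_diff <- round(cfg$frac_differential * cfg$n_sites)
  diff_idx <- sort(sample.int(cfg$n_sites, n_diff))
  up <- diff_idx[seq_len(floor(n_diff / 2))]
  down <- setdiff(diff_idx, up)
  site_fc <- rep(1, cfg$n_sites)
  site_fc[up] <- stats::runif(length(up), cfg$true_fc_range[1],
                              cfg$true_fc_range[2])
  site_fc[down] <- 1 / stats::runif(length(down), cfg$true_fc_range[1],
                                    cfg$true_fc_range[2])

  # protein confounding: the parent protein shifts by the site's fold change
  protein_fc <- stats::setNames(rep(1, cfg$n_proteins), prot_ids)
  confounded <- rep(FALSE, cfg$n_sites)
  if (cfg$protein_confounding > 0 && n_diff > 0) {
    n_conf <- round(cfg$protein_confounding * n_diff)
    for (i in sample(diff_idx, n_conf)) {
      p <- picked$protein_id[i]
      if (protein_fc[p] == 1) protein_fc[p] <- site_fc[i]
      site_fc[i] <- protein_fc[p]  # shift fully explained by the protein
      confounded[i] <- TRUE
    }
  }

  nrep <- cfg$n_samples_per_group
  ctrl <- paste0(cfg$group_labels[1], seq_len(nrep))
  trt <- paste0(cfg$group_labels[2], seq_len(nrep))
  samples <- c(ctrl, trt)
  groups <- stats::setNames(rep(cfg$group_labels, each = nrep), samples)

  noise <- function(n) 2^stats::rnorm(n, 0, cfg$replicate_noise_sigma_log2)
  base_site <- 10^stats::rnorm(cfg$n_sites, cfg$baseline_log10_mean,
                               cfg$baseline_log10_sd)
  m <- matrix(NA_real_, cfg$n_sites, length(samples),
              dimnames = list(NULL, samples))
  for (s in ctrl) m[, s] <- base_site * noise(cfg$n_sites)
  for (s in trt) m[, s] <- base_site * site_fc * noise(cfg$n_sites)
  if (cfg$missing_rate > 0)
    m[stats::runif(length(m)) < cfg$missing_rate] <- NA_real_

  base_prot <- 10^stats::rnorm(cfg$n_proteins, cfg$baseline_log10_mean + 0.5,
                               cfg$baseline_log10_sd)
  pm <- matrix(NA_real_, cfg$n_proteins, length(samples),
               dimnames = list(prot_ids, samples))
  for (s in ctrl) pm[, s] <- base_prot * noise(cfg$n_proteins)
  for (s in trt) pm[, s] <- base_prot * protein_fc * noise(cfg$n_proteins)

  meta <- tibble::tibble(
    site_id = paste0(picked$protein_id, "_K", picked$position),
    protein_id = picked$protein_id,
    position = as.integer(picked$position),
    residue = "K",
    localization_prob = round(stats::runif(cfg$n_sites, 0.75, 1), 3))

  # plant motifs by rewriting flanking residues of carrier sites
  motif_carrier <- rep(FALSE, cfg$n_sites)
  for (ms in cfg$motif_spec) {
    carriers <- which(stats::runif(cfg$n_sites) < ms$fg_carry)
    for (i in carriers) {
      p <- meta$protein_id[i]
      at <- meta$position[i] + ms$offset
      if (at < 1 || at > nchar(seqs[[p]])) next
      substr(seqs[[p]], at, at) <- ms$residue
      motif_carrier[i] <- TRUE
    }
  }
  # rewriting can overwrite a lysine that hosts another site; drop such sites
  res_at <- substr(seqs[meta$protein_id], meta$position, meta$position)
  clobbered <- res_at != "K"
  if (any(clobbered)) {
    meta <- meta[!clobbered, ]; m <- m[!clobbered, , drop = FALSE]
    site_fc <- site_fc[!clobbered]; confounded <- confounded[!clobbered]
    motif_carrier <- motif_carrier[!clobbered]
  }

  true_reg <- ifelse(site_fc / protein_fc[meta$protein_id] > 1.5, "UP",
                     ifelse(site_fc / protein_fc[meta$protein_id] < 1 / 1.5,
                            "DOWN", "NS"))
  truth_sites <- tibble::tibble(
    site_id = meta$site_id, protein_id = meta$protein_id,
    apparent_fc = site_fc,
    true_fc = site_fc / unname(protein_fc[meta$protein_id]),
    true_regulation = true_reg,
    protein_confounded = confounded,
    motif_carrier = motif_carrier)

  diff_prot <- unique(truth_sites$protein_id[truth_sites$true_regulation != "NS"])
  ann <- simulate_annotations(cfg, prot_ids, diff_prot)
  edges <- simulate_edges(cfg, prot_ids, diff_prot)
  truth_prot <- tibble::tibble(protein_id = prot_ids,
                               true_protein_fc = unname(protein_fc),
                               is_differential = prot_ids %in% diff_prot)

  sites <- site_table(meta, m, groups)
  proteins <- structure(list(intensities = pm), class = "protein_quant")
  bundle <- list(sites = sites, proteins = proteins, fasta = seqs,
                 annotations = ann, edges = edges,
                 truth = list(sites = truth_sites, proteins = truth_prot),
                 groups = groups, config = cfg)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

simulate_annotations <- function(cfg, prot_ids, diff_prot) {
  rows <- list()
  for (et in cfg$enriched_terms) {
    carry <- ifelse(prot_ids %in% diff_prot, et$carry, et$background)
    hit <- prot_ids[stats::runif(length(prot_ids)) < carry]
    if (length(hit))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein_id = hit, namespace = "GO-BP", term_id = et$term_id,
        term_name = paste("planted process", et$term_id))
  }
  # filler terms at uniform frequency across namespaces
  filler <- expand.grid(ns = c("GO-BP", "KEGG", "DOMAIN", "COMPARTMENT"),
                        i = 1:5, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(filler))) {
    tid <- sprintf("%s:F%02d", filler$ns[r], filler$i[r])
    hit <- prot_ids[stats::runif(length(prot_ids)) < 0.1]
    if (length(hit))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein_id = hit, namespace = filler$ns[r], term_id = tid,
        term_name = paste("background category", tid))
  }
  do.call(rbind, rows)
}

simulate_edges <- function(cfg, prot_ids, diff_prot) {
  n_edge <- 3L * cfg$n_proteins
  a <- sample(prot_ids, n_edge, replace = TRUE)
  b <- sample(prot_ids, n_edge, replace = TRUE)
  keep <- a != b
  df <- tibble::tibble(protein_a = pmin(a[keep], b[keep]),
                       protein_b = pmax(a[keep], b[keep]),
                       score = round(stats::runif(sum(keep)), 3))
  if (length(diff_prot) >= 2) {
    hub <- diff_prot[1]
    spokes <- setdiff(diff_prot, hub)
    spokes <- spokes[seq_len(min(20L, length(spokes)))]
    df <- rbind(df, tibble::tibble(protein_a = pmin(hub, spokes),
                                   protein_b = pmax(hub, spokes),
                                   score = round(stats::runif(length(spokes),
                                                              0.75, 1), 3)))
  }
  key <- paste(df$protein_a, df$protein_b)
  df <- df[order(key, -df$score), ]
  df <- df[!duplicated(paste(df$protein_a, df$protein_b)), ]
  df[order(df$protein_a, df$protein_b), ]
}

#' Write a simulated bundle to disk in the pipeline's input dialects
#' @param bundle list from [simulate_bundle]
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_site_table(bundle$sites, file.path(out_dir, "sites.tsv"))
  write_protein_table(bundle$proteins, file.path(out_dir, "proteins.tsv"))
  write_fasta(bundle$fasta, file.path(out_dir, "proteins.fasta"))
  write_annotation(bundle$annotations, file.path(out_dir, "annotations.tsv"))
  write_edge_table(bundle$edges, file.path(out_dir, "edges.tsv"))
  utils::write.table(as.data.frame(bundle$truth$sites),
                     file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  groups <- split(names(bundle$groups), bundle$groups)
  yaml::write_yaml(list(groups = groups, seed = bundle$config$seed),
                   file.path(out_dir, "groups.yaml"))
  invisible(out_dir)
}
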