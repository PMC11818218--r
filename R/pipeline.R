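#' Default pipeline thresholds
#'
#' Fold-change threshold 1.5 (down below 1/1.5), CV threshold 0.1, t-test
#' alpha 0.05, motif binomial p 1e-6 with at least 20 supporting peptides,
#' interaction confidence above 0.7, 50 hub proteins, 2/3 sample-completeness
#' for the heatmap, top 30 sites.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(fc = 1.5, cv = 0.1, alpha = 0.05,
       motif_p = 1e-6, min_occ = 20L,
       score_min = 0.7, top_n_network = 50L,
       heatmap_fraction = 2 / 3, top_n_sites = 30L)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML names input paths (`sites`, `proteins`, `fasta`, `annotations`,
#' `edges`), the `groups` block (group label -> sample ids, first group =
#' control/denominator), optional `thresholds` overriding
#' [default_thresholds], optional `namespaces` to enrich, and `out_dir`.
#'
#' @param path YAML file.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$groups), length(cfg$groups) == 2)
  cfg$thresholds <- utils::modifyList(default_thresholds(),
                                      cfg$thresholds %||% list())
  stopifnot(cfg$thresholds$fc > 1, cfg$thresholds$cv > 0,
            cfg$thresholds$alpha > 0, cfg$thresholds$motif_p > 0)
  cfg$namespaces <- cfg$namespaces %||% c("GO-BP", "KEGG", "DOMAIN")
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' quantify -> differential -> enrichment -> motifs -> network/QC, from
#' either a YAML config ([read_pipeline_config]) or an in-memory bundle
#' ([simulate_bundle]). Each stage is deterministic given its inputs; a
#' failure aborts with the stage name. Returns all stage outputs plus a
#' manifest of counts and thresholds; with `out_dir` set, stage tables and a
#' JSON manifest are written.
#'
#' @param config `pipeline_config`, path to a YAML config, or a bundle list
#'   with elements `sites`, `proteins`, `fasta`, `annotations`, `edges`,
#'   `groups`.
#' @param out_dir optional output directory.
#' @param thresholds optional list overriding [default_thresholds] (used for
#'   bundle input).
#' @param namespaces annotation namespaces to enrich (bundle input).
#' @return list: `relquant`, `differential`, `heatmap`, `top_sites`,
#'   `enrichment` (per namespace), `q_enrichment`, `motifs`,
#'   `residue_heatmap`, `network`, `qc`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, thresholds = NULL,
                         namespaces = c("GO-BP", "KEGG", "DOMAIN")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (inherits(config, "pipeline_config")) {
    th <- config$thresholds
    namespaces <- config$namespaces
    out_dir <- out_dir %||% config$out_dir
    group_map <- stats::setNames(
      rep(names(config$groups), lengths(config$groups)),
      unlist(config$groups))
    bundle <- stage("io", {
      list(sites = read_site_table(config$sites, group_map),
           proteins = read_protein_table(config$proteins),
           fasta = if (!is.null(config$fasta)) {
             if (!file.exists(config$fasta))
               stop("motifs-stage prerequisite missing: FASTA not found at ",
                    config$fasta)
             read_fasta(config$fasta)
           },
           annotations = if (!is.null(config$annotations))
             read_annotation(config$annotations),
           edges = if (!is.null(config$edges)) read_edge_table(config$edges),
           groups = group_map)
    })
  } else {
    bundle <- config
    th <- utils::modifyList(default_thresholds(), thresholds %||% list())
  }
  groups <- bundle$groups
  labels <- unique(groups)
  stopifnot(length(labels) == 2)
  ctrl <- names(groups)[groups == labels[1]]
  trt <- names(groups)[groups == labels[2]]

  quant <- stage("quantify", {
    site_r <- centralize(bundle$sites)
    if (!is.null(bundle$proteins)) {
      prot_r <- centralize(bundle$proteins)
      correct_by_protein(site_r, prot_r, bundle$sites$meta)
    } else site_r
  })

  diff <- stage("differential", {
    d <- differential_analysis(quant, trt, ctrl, fc_threshold = th$fc,
                               cv_threshold = th$cv, alpha = th$alpha)
    d$protein_id <- bundle$sites$meta$protein_id[
      match(d$site_id, bundle$sites$meta$site_id)]
    d
  })
  heat <- stage("heatmap_filter",
                heatmap_filter(diff, quant, th$heatmap_fraction))
  top <- stage("top_sites", top_n_sites(diff, th$top_n_sites))

  enr <- NULL; qenr <- NULL
  if (!is.null(bundle$annotations)) {
    enr <- stage("enrichment", {
      diff_prot <- unique(diff$protein_id[diff$regulation != "NS"])
      background <- unique(diff$protein_id)
      lapply(stats::setNames(namespaces, namespaces), function(ns)
        fisher_enrich(diff_prot, background, bundle$annotations, ns,
                      alpha = th$alpha))
    })
    qenr <- stage("q_enrichment",
                  q_group_enrichment(diff, bundle$annotations, namespaces[1],
                                     alpha = th$alpha))
  }

  mot <- NULL; res_heat <- NULL
  if (!is.null(bundle$fasta)) {
    mot <- stage("motifs", {
      fg <- extract_windows(bundle$fasta, bundle$sites$meta)
      bg <- build_background(bundle$fasta, "K")
      list(fg = fg, bg = bg,
           motifs = motif_discovery(fg, bg, th$motif_p, th$min_occ))
    })
    res_heat <- stage("residue_heatmap", frequency_heatmap(mot$fg, mot$bg))
  }

  net <- NULL
  if (!is.null(bundle$edges))
    net <- stage("network", build_network(bundle$edges, diff, th$score_min,
                                          th$top_n_network))
  qc <- stage("qc", qc_report(quant, bundle$sites))

  manifest <- list(
    package_version = as.character(utils::packageVersion("malonmap")),
    thresholds = th,
    groups = list(control = ctrl, treatment = trt),
    counts = list(
      sites_read = nrow(bundle$sites$meta),
      sites_quantified = nrow(quant$values),
      sites_tested = nrow(diff),
      up = sum(diff$regulation == "UP"),
      down = sum(diff$regulation == "DOWN"),
      q_groups = as.list(table(diff$q_group[diff$q_group != "NONE"])),
      heatmap_sites = length(heat$site_ids),
      motifs_found = if (!is.null(mot)) nrow(mot$motifs) else NA,
      terms_significant = if (!is.null(enr))
        sum(vapply(enr, function(e) sum(e$significant), numeric(1))) else NA,
      network_nodes = if (!is.null(net)) nrow(net$nodes) else NA))

  out <- list(relquant = quant, differential = diff, heatmap = heat,
              top_sites = top, enrichment = enr, q_enrichment = qenr,
              motifs = mot, residue_heatmap = res_heat, network = net,
              qc = qc, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("stage %-14s %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_relquant(out$relquant, file.path(out_dir, "relative_quant.tsv"))
  write_differential(out$differential, file.path(out_dir, "differential.tsv"))
  if (length(out$heatmap$site_ids)) {
    hm <- cbind(data.frame(site_id = rownames(out$heatmap$matrix)),
                as.data.frame(out$heatmap$matrix, check.names = FALSE))
    utils::write.table(hm, file.path(out_dir, "heatmap_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  write_differential(out$top_sites, file.path(out_dir, "top_sites.tsv"))
  if (!is.null(out$enrichment)) {
    long <- do.call(rbind, out$enrichment)
    utils::write.table(as.data.frame(long),
                       file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  if (!is.null(out$motifs)) {
    mt <- out$motifs$motifs
    utils::write.table(as.data.frame(mt[setdiff(names(mt), "steps")]),
                       file.path(out_dir, "motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  if (!is.null(out$network)) {
    utils::write.table(as.data.frame(out$network$nodes),
                       file.path(out_dir, "network_nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    utils::write.table(as.data.frame(out$network$edges),
                       file.path(out_dir, "network_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
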