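# End-to-end orchestration: simulate or load inputs, classify, test
# divergence, analyse alternative promoters, enrich, build networks, and
# write a manifest of stage counts.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a [simulation_config()] in
#' `simulate`, or `expression` + `gene_map` file paths together with a
#' `design`.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate optional [simulation_config()].
#' @param expression,gene_map optional input TSV paths.
#' @param design [experiment_design()] for reading `expression`.
#' @param annotations,dag optional annotation / DAG TSV paths enabling the
#'   enrichment stage.
#' @param ppi optional PPI edge-list TSV path enabling the shortest-path
#'   subnetwork stage.
#' @param tpm_min,alpha_filter,alpha_class,alpha_div,r_coord,r_coexpr,enrich_alpha
#'   stage thresholds (defaults 1 TPM, 0.01, 0.01, 0.01, 0.5, 0.95, 0.05).
#' @param pseudocount log2 pseudocount, default 1.
#' @param seed integer seed governing every random draw of the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, expression = NULL,
                            gene_map = NULL, design = mcf7_design(),
                            annotations = NULL, dag = NULL, ppi = NULL,
                            tpm_min = 1, alpha_filter = 0.01,
                            alpha_class = 0.01, alpha_div = 0.01,
                            r_coord = 0.5, r_coexpr = 0.95,
                            enrich_alpha = 0.05, pseudocount = 1,
                            seed = 1L) {
  if (is.null(simulate) == is.null(expression))
    stop("give exactly one input source: 'simulate' or 'expression'")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "simulation_config"))
  if (!is.null(expression) && is.null(gene_map))
    stop("'gene_map' is required with 'expression'")
  for (a in c(alpha_filter, alpha_class, alpha_div, enrich_alpha))
    if (a <= 0 || a >= 1) stop("significance levels must lie in (0, 1)")
  if (r_coord < -1 || r_coord > 1 || r_coexpr < 0 || r_coexpr > 1)
    stop("correlation thresholds out of range")
  if (tpm_min < 0) stop("'tpm_min' must be non-negative")
  structure(
    list(out_dir = out_dir, simulate = simulate, expression = expression,
         gene_map = gene_map, design = design, annotations = annotations,
         dag = dag, ppi = ppi, tpm_min = tpm_min,
         alpha_filter = alpha_filter, alpha_class = alpha_class,
         alpha_div = alpha_div, r_coord = r_coord, r_coexpr = r_coexpr,
         enrich_alpha = enrich_alpha, pseudocount = pseudocount,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# fixed-format TSV writer shared by all pipeline outputs
.write_tsv <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- fmt_num(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full trajectory analysis
#'
#' Sequences the stages filtering -> classification -> divergence ->
#' promoter-gene mapping -> alternative promoters -> (optional) enrichment
#' -> co-expression networks -> (optional) PPI subnetworks, writing one TSV
#' per stage plus GraphML/edge-list network files and a `manifest.json`
#' containing the seed, all thresholds and the stage counts. Re-running an
#' identical configuration produces byte-identical output files.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(...) message("[promtraj] ", sprintf(...))

  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    sim <- generate_dataset(sim_cfg)
    tensor <- sim$tensor
    gmap <- sim$gene_map
    .write_tsv(sim$truth, file.path(config$out_dir, "truth.tsv"))
    stage("simulate: %d promoters, %d genes", length(tensor$promoters),
          length(unique(gmap$gene)))
  } else {
    tensor <- read_expression_table(config$expression, config$design)
    gmap <- read_gene_map(config$gene_map)
    stage("load: %d promoters", length(tensor$promoters))
  }

  cls <- classify_promoters(tensor, tpm_min = config$tpm_min,
                            alpha_filter = config$alpha_filter,
                            alpha_class = config$alpha_class,
                            pseudocount = config$pseudocount)
  .write_tsv(cls, file.path(config$out_dir, "classification.tsv"))
  counts <- table(factor(cls$label,
                         levels = c("filtered_low", "filtered_unresponsive",
                                    "generic", "stimulus_specific")))
  stage("classify: %d TPM-passing, %d retained (%d generic / %d specific)",
        sum(counts[-1]), sum(counts[3:4]), counts[["generic"]],
        counts[["stimulus_specific"]])

  specific <- cls$promoter[cls$label == "stimulus_specific"]
  div <- if (length(specific) > 0L)
    divergence_test(tensor, specific, alpha = config$alpha_div,
                    pseudocount = config$pseudocount)
  else
    data.frame(promoter = character(), p_fc = numeric(), padj_fc = numeric(),
               divergent = logical(), fc_trend = numeric())
  .write_tsv(div, file.path(config$out_dir, "divergence.tsv"))
  stage("divergence: %d tested, %d divergent", nrow(div), sum(div$divergent))

  lt <- log_transform(
    subset_tensor(tensor,
                  cls$promoter[cls$label %in% c("generic",
                                                "stimulus_specific")]),
    config$pseudocount)
  profiles <- promoter_profiles(lt)
  mapping <- map_labels_to_genes(cls, gmap)
  alt <- find_alternative_promoter_genes(mapping$mapped, profiles,
                                         config$r_coord)
  .write_tsv(alt, file.path(config$out_dir, "alt_promoters.tsv"))
  stage("altpromoters: %d alternative-promoter genes (%d in both groups)",
        nrow(alt), sum(alt$category == "both"))

  enr <- NULL
  if (!is.null(config$annotations)) {
    ann <- read_annotations(config$annotations, config$dag)
    ann <- filter_evidence(ann)
    study <- unique(mapping$mapped$gene[
      mapping$mapped$label == "stimulus_specific"])
    background <- unique(mapping$mapped$gene)
    enr <- fisher_enrichment(study, background, ann,
                             alpha = config$enrich_alpha)
    if (!is.null(ann$dag)) enr <- discard_child_terms(enr, ann$dag)
    .write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
    stage("enrich: %d terms tested, %d significant", nrow(enr),
          sum(enr$significant))
  }

  # co-expression networks per stimulus over gene-level profiles
  # (transcription-factor genes when flagged, otherwise all mapped genes)
  tf_genes <- unique(gmap$gene[gmap$is_tf & !is.na(gmap$gene)])
  for (s in tensor$design$stimuli) {
    sp <- stimulus_profiles(lt, s)
    gp <- gene_profiles(sp, gmap)
    if (length(tf_genes) >= 2L && sum(rownames(gp) %in% tf_genes) >= 2L)
      gp <- gp[rownames(gp) %in% tf_genes, , drop = FALSE]
    if (nrow(gp) >= 2L) {
      cm <- suppressWarnings(correlation_matrix(gp))
      cg <- build_coexpression_graph(cm, config$r_coexpr)
      write_graph_files(cg, file.path(config$out_dir,
                                      paste0("coexpression_", s)))
      stage("network (%s): %d nodes, %d edges", s, igraph::vcount(cg),
            igraph::ecount(cg))
    }
  }

  if (!is.null(config$ppi)) {
    ppi <- read_ppi_edges(config$ppi)
    for (grp in c("generic", "stimulus_specific")) {
      seeds <- unique(mapping$mapped$gene[
        mapping$mapped$label == grp & mapping$mapped$is_tf])
      if (length(seeds) > 0L && any(seeds %in% igraph::V(ppi)$name)) {
        sub <- shortest_path_subnetwork(ppi, seeds)
        write_graph_files(sub, file.path(config$out_dir,
                                         paste0("ppi_subnet_", grp)))
        stage("ppi-subnet (%s): %d nodes, %d edges", grp,
              igraph::vcount(sub), igraph::ecount(sub))
      }
    }
  }

  manifest <- list(
    seed = config$seed,
    thresholds = list(tpm_min = config$tpm_min,
                      alpha_filter = config$alpha_filter,
                      alpha_class = config$alpha_class,
                      alpha_div = config$alpha_div,
                      r_coord = config$r_coord, r_coexpr = config$r_coexpr,
                      enrich_alpha = config$enrich_alpha,
                      pseudocount = config$pseudocount),
    counts = list(
      n_promoters = nrow(cls),
      n_tpm_pass = sum(cls$label != "filtered_low"),
      n_retained = sum(cls$label %in% c("generic", "stimulus_specific")),
      n_generic = sum(cls$label == "generic"),
      n_specific = sum(cls$label == "stimulus_specific"),
      n_divergence_tested = nrow(div),
      n_divergent = sum(div$divergent),
      n_unmapped_promoters = length(mapping$unmapped),
      n_alt_genes = nrow(alt),
      n_alt_both = sum(alt$category == "both"),
      n_enriched_terms = if (is.null(enr)) NA else sum(enr$significant)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(list(classification = cls, divergence = div, mapping = mapping,
                 alt_promoters = alt, enrichment = enr, manifest = manifest))
}
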