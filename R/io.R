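# Readers and writers for the flat-file interfaces: promoter-gene maps,
# PPI edge lists, term annotations, and the packaged worked-example tables.

#' Construct a promoter-gene map
#'
#' The relation is many-to-many: one promoter may serve several genes (e.g.
#' a shared histone-cluster promoter) and one gene may have several
#' (alternative) promoters. Duplicate (promoter, gene) pairs are collapsed
#' with a warning.
#'
#' @param promoter,gene character vectors of equal length; `gene` may be NA
#'   for promoters without a gene-centric annotation.
#' @param entrez optional character/numeric vector of Entrez IDs.
#' @param is_tf logical vector flagging pairs whose gene is a transcription
#'   factor (an input flag; default all `FALSE`).
#' @return A data frame of class `gene_map` with columns `promoter`, `gene`,
#'   `entrez`, `is_tf`.
#' @export
gene_map <- function(promoter, gene, entrez = NA_character_, is_tf = FALSE) {
  df <- data.frame(promoter = as.character(promoter),
                   gene = as.character(gene),
                   entrez = as.character(entrez),
                   is_tf = as.logical(is_tf),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty gene map")
  dup <- duplicated(df[, c("promoter", "gene")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (promoter, gene) pair(s) removed")
    df <- df[!dup, , drop = FALSE]
  }
  df$is_tf[is.na(df$is_tf)] <- FALSE
  rownames(df) <- NULL
  class(df) <- c("gene_map", "data.frame")
  df
}

#' Read a promoter-gene map from TSV
#'
#' Expects a header row with columns `promoter` and `gene` (optionally
#' `entrez` and `is_tf`). The strings `"NA"` and `"N/A"` in the gene column
#' denote promoters without a gene annotation.
#'
#' @param path file path.
#' @return A `gene_map`.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "N/A", ""))
  if (nrow(tab) == 0L) stop("empty gene map file: ", path)
  if (!all(c("promoter", "gene") %in% names(tab)))
    stop("gene map must have 'promoter' and 'gene' columns: ", path)
  gene_map(tab$promoter, tab$gene,
           entrez = if ("entrez" %in% names(tab)) tab$entrez else NA,
           is_tf = if ("is_tf" %in% names(tab)) tab$is_tf else FALSE)
}

#' Write a promoter-gene map to TSV
#'
#' @param x a `gene_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Expects a TSV whose first two columns are gene symbols; any further
#' columns are ignored. Self-loops and repeated edges (in either direction)
#' are collapsed with a warning, yielding a simple undirected graph.
#'
#' @param path file path.
#' @return An undirected [igraph::igraph] graph.
#' @export
read_ppi_edges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty PPI edge list: ", path)
  g <- igraph::graph_from_data_frame(tab[, 1:2], directed = FALSE)
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    warning("duplicate edges and/or self-loops removed from PPI edge list")
    g <- igraph::simplify(g)
  }
  g
}

#' Read term annotations and an optional term DAG
#'
#' The annotation file is a TSV with columns `term`, `gene`, `evidence`
#' (one row per supporting evidence code); the DAG file, if given, is a TSV
#' with columns `child`, `parent`.
#'
#' @param annotation_path path to the term-gene-evidence TSV.
#' @param dag_path optional path to the child-parent TSV.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(annotation_path, dag_path = NULL) {
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (nrow(ann) == 0L) stop("empty annotation file: ", annotation_path)
  if (!all(c("term", "gene", "evidence") %in% names(ann)))
    stop("annotation file must have 'term', 'gene', 'evidence' columns")
  dag <- NULL
  if (!is.null(dag_path)) {
    dag <- utils::read.delim(dag_path, stringsAsFactors = FALSE)
    if (!all(c("child", "parent") %in% names(dag)))
      stop("DAG file must have 'child' and 'parent' columns")
  }
  annotation_set(ann, dag)
}

#' Load a packaged worked-example table
#'
#' Machine-readable transcriptions of the published worked-example tables
#' ship with the package: `"table1"` (the ten most significant promoters of
#' each trajectory class), `"table2"` (the seven promoters with significant
#' HRG:EGF fold-change dynamics) and `"table3"` (the 37 genes whose
#' alternative promoters span both trajectory classes).
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return For `"table1"`/`"table2"`: a data frame with columns `label`,
#'   `promoter`, `gene`, `tf`, `padj`, `coef`. For `"table3"`: a long data
#'   frame with one row per (gene, promoter) pair and columns `gene`,
#'   `gene_tf`, `promoter`, `label`.
#' @export
load_table_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "promtraj")
  if (!nzchar(path)) stop("fixture not found: ", name)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "N/A"))
  if (name %in% c("table1", "table2")) {
    stopifnot(all(tab$padj >= 0 & tab$padj <= 1))
    parse_promoter_id(tab$promoter)  # validates the IDs
    return(tab)
  }
  # table3: expand the "//"-separated promoter lists to long form
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    gp <- strsplit(tab$generic_promoters[i], "//", fixed = TRUE)[[1L]]
    sp <- strsplit(tab$specific_promoters[i], "//", fixed = TRUE)[[1L]]
    stopifnot(length(gp) == tab$n_generic[i], length(sp) == tab$n_specific[i])
    data.frame(gene = tab$gene[i], gene_tf = tab$tf[i],
               promoter = c(gp, sp),
               label = rep(c("generic", "stimulus_specific"),
                           c(length(gp), length(sp))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  parse_promoter_id(out$promoter)  # validates the IDs
  out
}

#' Write a graph as GraphML and edge-list TSV
#'
#' @param g an igraph graph.
#' @param prefix path prefix; `<prefix>.graphml` and `<prefix>.edges.tsv`
#'   are written.
#' @return character vector of the two paths, invisibly.
#' @export
write_graph_files <- function(g, prefix) {
  graphml <- paste0(prefix, ".graphml")
  edges <- paste0(prefix, ".edges.tsv")
  igraph::write_graph(g, graphml, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  if ("weight" %in% names(el)) el$weight <- fmt_num(el$weight)
  utils::write.table(el, edges, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml, edges))
}
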