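# Gene-set over-representation analysis: evidence-code filtering, one-sided
# Fisher's exact test per term, BH correction, and redundancy pruning on the
# term parent-child DAG.

# standard GO evidence-code vocabulary, used to recognise unknown codes
.go_evidence_codes <- c(
  "EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "HTP", "HDA", "HMP", "HGI", "HEP",
  "ISS", "ISO", "ISA", "ISM", "IGC", "IBA", "IBD", "IKR", "IRD", "RCA",
  "TAS", "NAS", "IC", "ND", "IEA"
)

#' Construct an annotation set
#'
#' Term-to-gene annotations with per-pair evidence codes plus an optional
#' parent-child DAG over the terms. The DAG must be acyclic and may only
#' mention known terms.
#'
#' @param annotations data frame with columns `term`, `gene`, `evidence`
#'   (one row per supporting code).
#' @param dag optional data frame with columns `child`, `parent`.
#' @param terms optional character vector fixing the term universe; defaults
#'   to all terms mentioned in `annotations` and `dag`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(annotations, dag = NULL, terms = NULL) {
  stopifnot(all(c("term", "gene", "evidence") %in% names(annotations)))
  annotations <- annotations[, c("term", "gene", "evidence")]
  if (is.null(terms))
    terms <- unique(c(annotations$term,
                      if (!is.null(dag)) c(dag$child, dag$parent)))
  if (!all(annotations$term %in% terms))
    stop("annotation mentions a term outside the term universe")
  if (!is.null(dag)) {
    stopifnot(all(c("child", "parent") %in% names(dag)))
    dag <- dag[, c("child", "parent")]
    if (!all(c(dag$child, dag$parent) %in% terms))
      stop("DAG mentions a term outside the term universe")
    g <- igraph::graph_from_data_frame(dag, directed = TRUE)
    if (!igraph::is_dag(g))
      stop("term parent-child relation contains a cycle")
  }
  structure(list(annotations = annotations, dag = dag, terms = terms),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set:", length(unique(x$annotations$term)), "annotated terms,",
      length(unique(x$annotations$gene)), "genes,",
      if (is.null(x$dag)) "no DAG" else paste(nrow(x$dag), "DAG edges"), "\n")
  invisible(x)
}

#' Keep only experimentally supported annotations
#'
#' Retains a (term, gene) pair when at least one of its evidence codes is in
#' the allowed set; pairs supported only by disallowed codes (e.g. the
#' electronic IEA) are dropped. Codes outside the standard vocabulary raise
#' a warning and count as disallowed.
#'
#' @param x an [annotation_set()].
#' @param allowed character vector of evidence codes to keep; default the
#'   experimental codes EXP, IDA, IPI, IMP, IGI.
#' @return A filtered `annotation_set` (same term universe and DAG).
#' @export
filter_evidence <- function(x, allowed = c("EXP", "IDA", "IPI", "IMP", "IGI")) {
  stopifnot(inherits(x, "annotation_set"))
  ann <- x$annotations
  unknown <- setdiff(unique(ann$evidence), .go_evidence_codes)
  if (length(unknown) > 0L)
    warning("unknown evidence code(s) treated as disallowed: ",
            paste(unknown, collapse = ", "))
  ann <- ann[ann$evidence %in% allowed, , drop = FALSE]
  annotation_set(ann, x$dag, terms = x$terms)
}

#' Fisher's exact test over-representation analysis
#'
#' For each term with at least one study gene, tests over-representation of
#' the study set among the term's genes with a one-sided (greater)
#' Fisher's exact test on the 2x2 table (study-in-term, study-out-of-term /
#' background-in-term, background-out-of-term), adjusts across tested terms
#' with BH, and flags terms with adjusted p below `alpha`.
#'
#' @param study character vector of study genes (must be a subset of
#'   `background`).
#' @param background character vector, the gene universe.
#' @param x an [annotation_set()] (typically after [filter_evidence()]).
#' @param alpha significance level on the adjusted p, default 0.05.
#' @return data frame sorted by p-value with columns `term`, `k` (study
#'   genes in term), `K` (study size), `n` (background genes in term), `N`
#'   (background size), `odds_ratio`, `p`, `padj`, `significant`.
#' @export
fisher_enrichment <- function(study, background, x, alpha = 0.05) {
  stopifnot(inherits(x, "annotation_set"))
  study <- unique(study)
  background <- unique(background)
  if (!all(study %in% background))
    stop("study genes must be a subset of the background")
  nn <- length(background)
  kk <- length(study)
  term_genes <- lapply(split(x$annotations$gene, x$annotations$term), unique)
  rows <- lapply(names(term_genes), function(tm) {
    genes <- intersect(term_genes[[tm]], background)
    n <- length(genes)
    k <- length(intersect(genes, study))
    if (k == 0L || n == 0L) return(NULL)
    tab <- matrix(c(k, kk - k, n - k, nn - kk - n + k), nrow = 2L)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(term = tm, k = k, K = kk, n = n, N = nn,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), odds_ratio = numeric(),
                      p = numeric(), padj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  out$padj <- bh_adjust(out$p)
  out$significant <- out$padj < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# term IDs reachable from `term` along the given edge direction
.reachable <- function(g, term, mode) {
  if (!term %in% igraph::V(g)$name) return(character())
  setdiff(names(igraph::subcomponent(g, term, mode = mode)), term)
}

#' Prune hierarchically redundant significant terms
#'
#' Operates on the term DAG (edges child -> parent). In the literal default
#' mode (`"drop_descendants"`) a significant term is removed when another
#' significant term is among its ancestors, keeping the more general terms;
#' the alternate mode (`"drop_ancestors"`) removes a significant term when a
#' significant descendant exists, keeping the more specific terms. Terms
#' absent from the DAG are unrelated to everything and always survive;
#' non-significant records pass through untouched.
#'
#' @param records an enrichment data frame from [fisher_enrichment()] (needs
#'   columns `term` and `significant`).
#' @param dag data frame with columns `child`, `parent`.
#' @param mode `"drop_descendants"` (default) or `"drop_ancestors"`.
#' @return `records` with the pruned rows removed.
#' @export
discard_child_terms <- function(records, dag,
                                mode = c("drop_descendants",
                                         "drop_ancestors")) {
  mode <- match.arg(mode)
  stopifnot(all(c("term", "significant") %in% names(records)))
  if (is.null(dag) || nrow(dag) == 0L) return(records)
  g <- igraph::graph_from_data_frame(dag[, c("child", "parent")],
                                     directed = TRUE)
  if (!igraph::is_dag(g))
    stop("term parent-child relation contains a cycle")
  sig <- records$term[records$significant]
  related <- if (mode == "drop_descendants") "out" else "in"
  drop <- vapply(records$term, function(tm) {
    tm %in% sig && any(.reachable(g, tm, related) %in% sig)
  }, logical(1L))
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
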