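# Gene-level view of promoter classifications: alternative promoter
# detection, group composition, and expression coordination among promoters
# of the same gene.

#' Replicate-averaged promoter profiles
#'
#' For each promoter, the replicate means per (stimulus, time) cell,
#' concatenated first arm then second arm in design time order. This is the
#' profile space used for coordination and co-expression correlations.
#'
#' @param x a log2-scale `expr_tensor`.
#' @return numeric matrix, promoters in rows, `2 * n_times` columns.
#' @export
promoter_profiles <- function(x) {
  stopifnot(inherits(x, "expr_tensor"))
  np <- length(x$promoters)
  m <- apply(x$values, c(1L, 2L, 3L), mean)
  out <- cbind(matrix(m[, 1L, ], nrow = np), matrix(m[, 2L, ], nrow = np))
  rownames(out) <- x$promoters
  colnames(out) <- paste(rep(x$design$stimuli, each = length(x$design$time_points)),
                         fmt_num(x$design$time_points), sep = "_")
  out
}

#' Replicate-averaged profiles within one stimulus arm
#'
#' @param x a log2-scale `expr_tensor`.
#' @param stimulus one of the design stimuli.
#' @return numeric matrix, promoters in rows, times in columns.
#' @export
stimulus_profiles <- function(x, stimulus) {
  stopifnot(inherits(x, "expr_tensor"))
  s <- match(stimulus, x$design$stimuli)
  if (is.na(s)) stop("unknown stimulus: ", stimulus)
  m <- apply(x$values, c(1L, 2L, 3L), mean)
  out <- matrix(m[, s, ], nrow = length(x$promoters))
  rownames(out) <- x$promoters
  colnames(out) <- fmt_num(x$design$time_points)
  out
}

#' Map promoter labels to genes
#'
#' Restricts classification records to retained promoters (labels `generic`
#' or `stimulus_specific`), joins them to the promoter-gene map, and drops
#' pairs without a gene annotation. A gene inherits every label of every
#' promoter mapped to it; a promoter shared by several genes contributes to
#' each independently.
#'
#' @param records data frame with at least columns `promoter` and `label`
#'   (as returned by [classify_promoters()]).
#' @param gmap a [gene_map()].
#' @return list with `mapped` (data frame: `gene`, `promoter`, `label`,
#'   `is_tf`) and `unmapped` (character vector of retained promoters with no
#'   gene annotation).
#' @export
map_labels_to_genes <- function(records, gmap) {
  stopifnot(all(c("promoter", "label") %in% names(records)))
  rec <- records[records$label %in% c("generic", "stimulus_specific"),
                 c("promoter", "label"), drop = FALSE]
  rec <- unique(rec)
  j <- merge(rec, as.data.frame(gmap)[, c("promoter", "gene", "is_tf")],
             by = "promoter", all.x = TRUE)
  mapped <- j[!is.na(j$gene), c("gene", "promoter", "label", "is_tf")]
  mapped <- mapped[order(mapped$gene, mapped$label, mapped$promoter), ]
  rownames(mapped) <- NULL
  unmapped <- sort(unique(rec$promoter[!rec$promoter %in% mapped$promoter]))
  list(mapped = mapped, unmapped = unmapped)
}

#' Mean pairwise correlation among a gene's promoter profiles
#'
#' Pearson correlation for every unordered pair of promoter profiles,
#' averaged arithmetically. Promoters with zero profile variance have
#' undefined correlations; their pairs are excluded with a warning. The
#' gene's promoters are called coordinated when the mean exceeds `r_coord`.
#'
#' @param profiles numeric matrix, one promoter profile per row (at least
#'   2 rows).
#' @param r_coord coordination threshold, default 0.5 (strict `>`).
#' @return list with `mean_pairwise_r`, `coordinated`, `n_pairs`.
#' @export
coordination_score <- function(profiles, r_coord = 0.5) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L)
    stop("coordination requires at least 2 promoter profiles")
  sds <- apply(profiles, 1L, stats::sd)
  keep <- sds > 0
  if (any(!keep))
    warning(sum(!keep), " zero-variance profile(s) excluded from pairing")
  if (sum(keep) < 2L)
    return(list(mean_pairwise_r = NA_real_, coordinated = NA, n_pairs = 0L))
  cc <- stats::cor(t(profiles[keep, , drop = FALSE]))
  rs <- cc[upper.tri(cc)]
  mean_r <- mean(rs)
  list(mean_pairwise_r = mean_r, coordinated = mean_r > r_coord,
       n_pairs = length(rs))
}

#' Element-wise average of promoter profiles into one gene profile
#'
#' @param profiles numeric matrix (promoters in rows) or list of
#'   equal-length numeric vectors.
#' @return numeric vector, the arithmetic mean profile.
#' @export
average_gene_profile <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    if (length(unique(lengths(profiles))) != 1L)
      stop("profiles have mismatched lengths")
    profiles <- do.call(rbind, profiles)
  }
  profiles <- as.matrix(profiles)
  if (nrow(profiles) == 0L) stop("at least one profile is required")
  colMeans(profiles)
}

#' Genes controlled by alternative promoters
#'
#' Returns every gene mapped by two or more retained promoters, with its
#' per-class promoter counts and lists, partitioned into genes with more
#' than one generic promoter only (`generic_only`), more than one
#' stimulus-specific promoter only (`specific_only`), and genes whose
#' promoters span both classes (`both`). When a profile matrix is supplied,
#' each gene also gets its coordination statistics.
#'
#' @param mapped the `mapped` data frame from [map_labels_to_genes()].
#' @param profiles optional matrix of promoter profiles (rownames are
#'   promoter IDs), e.g. from [promoter_profiles()].
#' @param r_coord coordination threshold passed to [coordination_score()].
#' @return data frame with columns `gene`, `n_generic`, `n_specific`,
#'   `generic_promoters`, `specific_promoters` (each `"//"`-separated),
#'   `category`, `is_tf`, `mean_pairwise_r`, `coordinated`.
#' @export
find_alternative_promoter_genes <- function(mapped, profiles = NULL,
                                            r_coord = 0.5) {
  stopifnot(all(c("gene", "promoter", "label") %in% names(mapped)))
  split_g <- split(mapped, mapped$gene)
  rows <- lapply(split_g, function(g) {
    gp <- sort(unique(g$promoter[g$label == "generic"]))
    sp <- sort(unique(g$promoter[g$label == "stimulus_specific"]))
    n_g <- length(gp)
    n_s <- length(sp)
    if (n_g + n_s < 2L) return(NULL)
    category <- if (n_g >= 1L && n_s >= 1L) "both"
                else if (n_g >= 2L) "generic_only" else "specific_only"
    r <- NA_real_
    coord <- NA
    if (!is.null(profiles)) {
      prom <- c(gp, sp)
      prom <- prom[prom %in% rownames(profiles)]
      if (length(prom) >= 2L) {
        cs <- coordination_score(profiles[prom, , drop = FALSE], r_coord)
        r <- cs$mean_pairwise_r
        coord <- cs$coordinated
      }
    }
    data.frame(gene = g$gene[1L], n_generic = n_g, n_specific = n_s,
               generic_promoters = paste(gp, collapse = "//"),
               specific_promoters = paste(sp, collapse = "//"),
               category = category,
               is_tf = any(g$is_tf, na.rm = TRUE),
               mean_pairwise_r = r, coordinated = coord,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), n_generic = integer(),
                      n_specific = integer(), generic_promoters = character(),
                      specific_promoters = character(), category = character(),
                      is_tf = logical(), mean_pairwise_r = numeric(),
                      coordinated = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Average promoter profiles to gene profiles
#'
#' @param profiles numeric matrix of promoter profiles (rownames promoter
#'   IDs).
#' @param gmap a [gene_map()]; promoters missing from `profiles` are
#'   ignored, genes without any profiled promoter are omitted.
#' @return numeric matrix, genes in rows.
#' @export
gene_profiles <- function(profiles, gmap) {
  gm <- as.data.frame(gmap)
  gm <- gm[!is.na(gm$gene) & gm$promoter %in% rownames(profiles), ]
  if (nrow(gm) == 0L) stop("no mapped promoters with profiles")
  genes <- sort(unique(gm$gene))
  out <- t(vapply(genes, function(g) {
    average_gene_profile(profiles[gm$promoter[gm$gene == g], , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(out) <- genes
  out
}
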