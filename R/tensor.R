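# The promoter x stimulus x time x replicate expression container and its
# TSV reader/writer.

#' Construct an expression tensor
#'
#' Holds promoter-level expression values as a 4-way array indexed by
#' promoter, stimulus, time and replicate. On input the values are on the
#' tags-per-million (TPM) scale and must be non-negative and finite;
#' after [log_transform()] the `log_transformed` flag is set and values may
#' be negative.
#'
#' @param values numeric array of dimension
#'   `c(n_promoters, 2, n_times, n_replicates)`.
#' @param promoters character vector of promoter IDs, in order.
#' @param design an [experiment_design()].
#' @param log_transformed logical flag; `TRUE` once values are log2.
#' @return An object of class `expr_tensor`.
#' @export
expression_tensor <- function(values, promoters, design,
                              log_transformed = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  promoters <- as.character(promoters)
  if (length(promoters) == 0L) stop("tensor must contain at least one promoter")
  if (anyDuplicated(promoters)) stop("duplicate promoter IDs")
  dims <- c(length(promoters), 2L, length(design$time_points),
            design$n_replicates)
  if (!is.array(values) || length(dim(values)) != 4L ||
      !all(dim(values) == dims))
    stop("'values' must be a 4-way array of dimension ",
         paste(dims, collapse = " x "))
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (!log_transformed && any(values < 0))
    stop("TPM-scale expression values must be non-negative")
  dimnames(values) <- list(promoters, design$stimuli,
                           fmt_num(design$time_points),
                           as.character(seq_len(design$n_replicates)))
  structure(
    list(values = values, promoters = promoters, design = design,
         log_transformed = isTRUE(log_transformed)),
    class = "expr_tensor"
  )
}

#' @export
print.expr_tensor <- function(x, ...) {
  cat("Expression tensor:", length(x$promoters), "promoters x",
      paste(x$design$stimuli, collapse = "/"), "x",
      length(x$design$time_points), "times x",
      x$design$n_replicates, "replicates\n")
  cat("  scale:", if (x$log_transformed) "log2" else "TPM", "\n")
  invisible(x)
}

#' Subset a tensor to a set of promoters
#'
#' @param x an `expr_tensor`.
#' @param promoters character vector of promoter IDs to keep, in the order
#'   they should appear.
#' @return An `expr_tensor`.
#' @export
subset_tensor <- function(x, promoters) {
  idx <- match(promoters, x$promoters)
  if (anyNA(idx))
    stop("unknown promoter(s): ", paste(promoters[is.na(idx)][1L]))
  vals <- x$values[idx, , , , drop = FALSE]
  expression_tensor(vals, promoters, x$design, x$log_transformed)
}

#' Extract one promoter's stimulus x time x replicate slice
#'
#' @param x an `expr_tensor`.
#' @param promoter single promoter ID.
#' @return numeric array of dimension `c(2, n_times, n_replicates)`.
#' @export
promoter_slice <- function(x, promoter) {
  i <- match(promoter, x$promoters)
  if (is.na(i)) stop("unknown promoter: ", promoter)
  a <- x$values[i, , , , drop = FALSE]
  array(a, dim = dim(x$values)[-1L], dimnames = dimnames(x$values)[-1L])
}

#' Extract one promoter's time x replicate matrix under one stimulus
#'
#' @inheritParams promoter_slice
#' @param stimulus one of the design's stimulus labels.
#' @return numeric matrix, times in rows, replicates in columns.
#' @export
time_matrix <- function(x, promoter, stimulus) {
  s <- match(stimulus, x$design$stimuli)
  if (is.na(s)) stop("unknown stimulus: ", stimulus)
  sl <- promoter_slice(x, promoter)
  matrix(sl[s, , ], nrow = dim(sl)[2L], ncol = dim(sl)[3L],
         dimnames = dimnames(sl)[2:3])
}

#' log2-transform an expression tensor
#'
#' Applies `log2(value + pseudocount)` element-wise and marks the tensor as
#' log-transformed. Transforming twice is an error.
#'
#' @param x an `expr_tensor` on the TPM scale.
#' @param pseudocount non-negative offset added before taking logs; the
#'   default 1 maps zero TPM to zero and preserves value ordering.
#' @return A log2-scale `expr_tensor`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expr_tensor"))
  if (x$log_transformed) stop("tensor is already log2-transformed")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("'pseudocount' must be a single non-negative number")
  if (pseudocount == 0 && any(x$values == 0))
    stop("pseudocount 0 with zero values would produce -Inf")
  expression_tensor(log2(x$values + pseudocount), x$promoters, x$design,
                    log_transformed = TRUE)
}

#' Minimum-expression filter
#'
#' A promoter is dropped if and only if every one of its values -- across
#' both stimuli, all time points and all replicates -- is below `threshold`
#' TPM. A single value at or above the threshold retains the promoter.
#'
#' @param x an `expr_tensor` on the TPM scale (not log-transformed).
#' @param threshold TPM threshold, default 1.
#' @return list with character vectors `retained` and `dropped`.
#' @export
filter_min_expression <- function(x, threshold = 1) {
  stopifnot(inherits(x, "expr_tensor"))
  if (x$log_transformed)
    stop("minimum-expression filter requires TPM-scale values, not log2")
  keep <- apply(x$values >= threshold, 1L, any)
  list(retained = x$promoters[keep], dropped = x$promoters[!keep])
}

#' Read a promoter expression table
#'
#' Reads a tab-separated table whose first column holds promoter IDs and
#' whose remaining columns are named `<stimulus>_<time>_<replicate>` as
#' produced by [sample_names()]. If the design starts at time 0 and the file
#' instead carries unstimulated columns named `0_<replicate>`, those columns
#' are duplicated into both stimulus arms (the 0 h sample is non-treated and
#' common to both), with a notice.
#'
#' @param path file path.
#' @param design the [experiment_design()] the columns must match.
#' @return An `expr_tensor` on the TPM scale, promoters in file order.
#' @export
read_expression_table <- function(path, design) {
  stopifnot(inherits(design, "experiment_design"))
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) stop("empty expression table: ", path)
  promoters <- tab[[1L]]
  if (anyDuplicated(promoters))
    stop("duplicate promoter IDs in ", path)
  cols <- names(tab)[-1L]
  expected <- sample_names(design)
  t0 <- design$time_points[1L] == 0
  zero_cols <- if (t0) paste("0", seq_len(design$n_replicates), sep = "_")
               else character()
  unknown <- setdiff(cols, c(expected, zero_cols))
  if (length(unknown) > 0L)
    stop("column '", unknown[1L], "' does not match the design")
  get_col <- function(nm) {
    if (nm %in% cols) return(tab[[nm]])
    # fall back to a shared unstimulated time-0 column
    if (t0) {
      parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
      if (parts[2L] == fmt_num(0)) {
        alt <- paste("0", parts[3L], sep = "_")
        if (alt %in% cols) return(structure(tab[[alt]], shared0 = TRUE))
      }
    }
    stop("column '", nm, "' required by the design is missing")
  }
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = length(expected))
  used_shared0 <- FALSE
  for (j in seq_along(expected)) {
    raw <- get_col(expected[j])
    if (isTRUE(attr(raw, "shared0"))) used_shared0 <- TRUE
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0L)
      stop("non-numeric value in column '", expected[j], "', row ", bad[1L])
    neg <- which(num < 0)
    if (length(neg) > 0L)
      stop("negative value in column '", expected[j], "', row ", neg[1L])
    vals[, j] <- num
  }
  if (used_shared0)
    message("unstimulated time-0 columns duplicated into both stimulus arms")
  dims <- c(nrow(tab), design$n_replicates, length(design$time_points), 2L)
  arr <- array(t(vals), dim = c(design$n_replicates,
                                length(design$time_points), 2L, nrow(tab)))
  # expected order is stimulus-major, then time, then replicate; vals has
  # samples in columns, so permute (rep, time, stim, promoter) -> tensor axes
  arr <- aperm(arr, c(4L, 3L, 2L, 1L))
  expression_tensor(arr, promoters, design, log_transformed = FALSE)
}

#' Write a promoter expression table
#'
#' Serializes an `expr_tensor` as TSV with columns in [sample_names()] order
#' and values printed with six significant digits, so that writing, reading
#' and re-writing reproduces the file byte-for-byte.
#'
#' @param x an `expr_tensor`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_tensor"))
  n <- length(x$promoters)
  # flatten back to sample-column order: stimulus-major, then time, then rep
  flat <- aperm(x$values, c(4L, 3L, 2L, 1L))
  mat <- matrix(flat, ncol = n)  # samples x promoters
  out <- cbind(promoter = x$promoters,
               matrix(fmt_num(t(mat)), nrow = n))
  colnames(out) <- c("promoter", sample_names(x$design))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
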