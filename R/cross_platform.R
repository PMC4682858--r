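# Cross-platform validation helpers: correlation-based classification for
# sparse designs and the two-sided Fisher test of label overlap between two
# platforms.

#' Correlation-based generic/stimulus-specific classification
#'
#' For designs too sparse to fit the ANOVA models (e.g. qPCR time courses),
#' a gene is called generic when the Pearson correlation between its two
#' stimulus-arm profiles strictly exceeds `r_cut`, and stimulus-specific
#' when the correlation is at or below `r_cut`.
#'
#' @param profile_a,profile_b equal-length numeric profiles (>= 3 points)
#'   of the same gene under the two stimuli.
#' @param r_cut correlation cut-off, default 0.5.
#' @return list with `r` and `label` (`"generic"`, `"stimulus_specific"`,
#'   or `"unclassified"` when a profile has zero variance).
#' @export
correlation_classify <- function(profile_a, profile_b, r_cut = 0.5) {
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length")
  if (length(profile_a) < 3L) stop("profiles need at least 3 points")
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0)
    return(list(r = NA_real_, label = "unclassified"))
  r <- stats::cor(profile_a, profile_b)
  list(r = r, label = if (r > r_cut) "generic" else "stimulus_specific")
}

#' Significance of classification overlap between two platforms
#'
#' Cross-tabulates the generic/stimulus-specific labels of the genes shared
#' by both platforms and tests the association with a two-sided Fisher's
#' exact test (two-sided p defined by summing the probabilities of all
#' tables at the observed margins whose point mass does not exceed the
#' observed table's).
#'
#' @param labels_a,labels_b named character vectors (`generic` /
#'   `stimulus_specific`), names are gene IDs; genes present on only one
#'   platform are excluded.
#' @return list with `table` (2x2 contingency table), `p.value` and
#'   `n_shared`.
#' @export
overlap_significance <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    stop("label vectors must be named by gene")
  shared <- intersect(names(labels_a), names(labels_b))
  if (length(shared) == 0L) stop("no genes shared by the two platforms")
  lev <- c("generic", "stimulus_specific")
  tab <- table(platform_a = factor(labels_a[shared], levels = lev),
               platform_b = factor(labels_b[shared], levels = lev))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p.value = ft$p.value, n_shared = length(shared))
}
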