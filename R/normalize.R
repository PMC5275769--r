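#' Select the consistently detected low-variance miRNA panel
#'
#' Picks the housekeeping panel used for reference-sample normalization: among
#' miRNAs detected in every sample, the `panel_size` with the lowest variance
#' of log expression (log2 counts, or the Ct value itself, which is already a
#' log2 scale). Ties are broken lexicographically by identifier.
#'
#' @param x An [expression_matrix()].
#' @param panel_size Number of panel miRNAs; defaults to 50 for counts and 40
#'   for Ct, the panel sizes used on the sequencing and qPCR platforms
#'   respectively.
#' @return Character vector of `panel_size` miRNA identifiers, ordered by
#'   increasing variance.
#' @export
detect_consistent_set <- function(x, panel_size = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(panel_size)) {
    panel_size <- if (x$platform == "counts") 50L else 40L
  }
  det <- detected(x)
  universal <- rownames(x$values)[rowSums(det) == ncol(x$values)]
  if (length(universal) < panel_size) {
    stop(sprintf(
      "only %d miRNAs are detected in every sample; cannot build a panel of %d",
      length(universal), panel_size), call. = FALSE)
  }
  v <- x$values[universal, , drop = FALSE]
  logv <- if (x$platform == "counts") log2(v) else v
  vars <- apply(logv, 1, stats::var)
  ord <- order(vars, universal)
  universal[ord][seq_len(panel_size)]
}

#' Normalize expression to a reference sample
#'
#' Scales every sample to a chosen reference sample by comparing the two over a
#' housekeeping panel of consistently detected miRNAs. For counts, the
#' per-sample factor is the aggregate (median by default) of the miRNA-wise
#' ratios `x[i, j] / x[i, ref]`; counts are divided by the factor and
#' log2-transformed with a pseudocount. For Ct data, the per-sample shift is
#' the aggregate of miRNA-wise Ct differences `Ct[i, j] - Ct[i, ref]`;
#' normalized values are `-(Ct - shift)` so that larger means more abundant and
#' differences are log2 fold changes.
#'
#' @param x An [expression_matrix()].
#' @param reference Reference sample identifier. Default: the sample with the
#'   largest number of detected miRNAs (ties broken by column order).
#' @param housekeeping Character vector of panel miRNAs, all detected in every
#'   sample. Default: [detect_consistent_set()] with `panel_size`.
#' @param panel_size Passed to [detect_consistent_set()] when `housekeeping`
#'   is not given.
#' @param aggregate `"median"` (robust default) or `"mean"`.
#' @param pseudocount Added to factor-corrected counts before log2 (counts
#'   platform only). The default 1 keeps zeros finite; set 0 on strictly
#'   positive data for exact scale equivariance.
#' @return A `normalization_result`: list with `normalized` (a
#'   `normalized_matrix` of log2-scale values carrying the labels),
#'   `reference`, `housekeeping`, and `factors` (per-sample scale factor or Ct
#'   shift; exactly 1 resp. 0 for the reference sample).
#' @export
normalize_to_reference <- function(x, reference = NULL, housekeeping = NULL,
                                   panel_size = NULL,
                                   aggregate = c("median", "mean"),
                                   pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") stats::median else mean
  det <- detected(x)
  if (is.null(reference)) {
    reference <- colnames(x$values)[which.max(colSums(det))]
  }
  if (!reference %in% colnames(x$values)) {
    stop("reference sample '", reference, "' not found", call. = FALSE)
  }
  if (is.null(housekeeping)) {
    housekeeping <- detect_consistent_set(x, panel_size)
  }
  absent <- setdiff(housekeeping, rownames(x$values))
  if (length(absent) > 0) {
    stop("housekeeping miRNA(s) absent from the matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (any(!det[housekeeping, ])) {
    bad <- housekeeping[rowSums(!det[housekeeping, , drop = FALSE]) > 0]
    stop("housekeeping miRNA(s) not detected in every sample: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hk <- x$values[housekeeping, , drop = FALSE]
  if (x$platform == "counts") {
    factors <- apply(hk / hk[, reference], 2, agg)
    normalized <- log2(sweep(x$values, 2, factors, "/") + pseudocount)
  } else {
    factors <- apply(hk - hk[, reference], 2, agg)
    normalized <- -sweep(x$values, 2, factors, "-")
  }
  names(factors) <- colnames(x$values)
  nm <- structure(list(values = normalized, platform = x$platform,
                       labels = x$labels, detected = det),
                  class = "normalized_matrix")
  structure(list(normalized = nm, reference = reference,
                 housekeeping = housekeeping, factors = factors),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf(
    "normalization_result: reference '%s', %d housekeeping miRNAs (%s)\n",
    x$reference, length(x$housekeeping), x$normalized$platform))
  cat("  factor range:", paste(signif(range(x$factors), 3), collapse = " .. "),
      "\n")
  invisible(x)
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d miRNAs x %d samples (log2 scale, %s)\n",
              nrow(x$values), ncol(x$values), x$platform))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' Remove contamination-marker miRNAs
#'
#' Drops the listed miRNAs (by default the red-blood-cell markers, see
#' [rbc_markers()]) from the matrix so they cannot enter normalization panels,
#' differential-expression candidate sets, or classifiers. Identifiers absent
#' from the matrix are ignored with a message.
#'
#' @param x An [expression_matrix()] or `normalized_matrix`.
#' @param exclusion Character vector of miRNA identifiers to remove.
#' @return The matrix without the excluded rows (same class as `x`).
#' @export
exclude_markers <- function(x, exclusion = rbc_markers()) {
  stopifnot(inherits(x, c("expression_matrix", "normalized_matrix")))
  if (length(exclusion) == 0) return(x)
  present <- intersect(exclusion, rownames(x$values))
  absent <- setdiff(exclusion, present)
  if (length(absent) > 0) {
    message("exclusion list entries not in the matrix (ignored): ",
            paste(absent, collapse = ", "))
  }
  if (length(present) == 0) return(x)
  message("excluding ", length(present), " marker miRNA(s): ",
          paste(present, collapse = ", "))
  keep <- setdiff(rownames(x$values), present)
  x$values <- x$values[keep, , drop = FALSE]
  if (!is.null(x$detected)) x$detected <- x$detected[keep, , drop = FALSE]
  x
}
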