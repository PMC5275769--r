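#' Construct an expression matrix
#'
#' Container for a miRNA expression matrix with miRNAs in rows and samples in
#' columns, tagged by measurement platform. Counts are non-negative
#' small-RNA-seq read counts; `ct` values are RT-qPCR cycle thresholds on the
#' log2 scale (lower Ct = more abundant), where `NA` marks an undetected
#' reaction.
#'
#' @param values Numeric matrix, miRNAs in rows (rownames = miRNA identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param platform `"counts"` or `"ct"`.
#' @param labels Optional class labels: a character vector named by sample (or
#'   ordered as the columns), values `"tumor"` or `"normal"`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `platform`, and `labels` (a factor with levels
#'   `c("normal", "tumor")`, or `NULL`).
#' @export
#'
#' @examples
#' m <- matrix(rpois(20, 50), 4, 5,
#'             dimnames = list(paste0("mir-", 1:4), paste0("s", 1:5)))
#' em <- expression_matrix(m, "counts",
#'                         labels = setNames(rep(c("tumor", "normal"), c(3, 2)),
#'                                           colnames(m)))
#' em
expression_matrix <- function(values, platform = c("counts", "ct"),
                              labels = NULL) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have miRNA rownames and sample colnames",
         call. = FALSE)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    stop("duplicate miRNA identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup) > 0) {
    stop("duplicate sample identifier(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (platform == "counts") {
    if (anyNA(values)) {
      stop("counts platform does not allow missing values", call. = FALSE)
    }
    if (any(values < 0)) {
      idx <- which(values < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative count at miRNA '%s', sample '%s'",
                   rownames(values)[idx[1]], colnames(values)[idx[2]]),
           call. = FALSE)
    }
  } else {
    if (any(values <= 0, na.rm = TRUE)) {
      stop("ct values must be positive", call. = FALSE)
    }
  }
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      extra <- setdiff(names(labels), colnames(values))
      if (length(extra) > 0) {
        stop("labeled sample(s) not in the matrix: ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
    }
    labels <- align_labels(labels, colnames(values))
    names(labels) <- colnames(values)
  }
  structure(list(values = values, platform = platform, labels = labels),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d miRNAs x %d samples (platform: %s)\n",
              nrow(x$values), ncol(x$values), x$platform))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  nd <- sum(!detected(x)) / length(x$values)
  cat(sprintf("  undetected entries: %.1f%%\n", 100 * nd))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' miRNA and sample identifiers of an expression matrix
#' @param x An `expression_matrix` or `normalized_matrix`.
#' @return Character vector of identifiers.
#' @export
mirna_ids <- function(x) rownames(x$values)

#' @rdname mirna_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Detection indicator
#'
#' A count is detected when it is positive; a Ct value is detected when it is
#' not missing (censoring above the detection ceiling is recorded as `NA` by
#' the simulator and by upstream instruments).
#'
#' @param x An `expression_matrix`.
#' @return Logical matrix of the same shape as `x$values`.
#' @export
detected <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$platform == "counts") x$values > 0 else !is.na(x$values)
}

#' Red-blood-cell contamination marker miRNAs
#'
#' Tumor brush biopsies are more frequently blood-contaminated than controls;
#' the erythrocyte miRNAs miR-451a, miR-144-3p and miR-144-5p therefore track
#' contamination rather than epithelial biology and are excluded before
#' analysis.
#'
#' @return Character vector of the three marker identifiers.
#' @export
rbc_markers <- function() {
  c("hsa-miR-451a", "hsa-miR-144-3p", "hsa-miR-144-5p")
}
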