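#' Read an expression matrix from TSV
#'
#' Expects miRNAs in rows and samples in columns, with the first column holding
#' miRNA identifiers and the header holding sample identifiers. Empty cells or
#' the literal `NA` become missing values (allowed for the `ct` platform only).
#' No detection-ceiling convention is applied by the reader.
#'
#' @param path Path to a tab-separated file.
#' @param platform `"counts"` or `"ct"`.
#' @param labels Optional labels as in [expression_matrix()], or a path to a
#'   two-column TSV (sample, class) as written by [write_labels()].
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, platform = c("counts", "ct"),
                            labels = NULL) {
  platform <- match.arg(platform)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("expression file needs an id column and at least one sample column", call. = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate miRNA identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- ids
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    labels <- read_labels(labels)
  }
  expression_matrix(v, platform, labels = labels)
}

#' Write an expression matrix to TSV
#'
#' @param x An `expression_matrix` or `normalized_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  v <- if (is.matrix(x)) x else x$values
  df <- data.frame(mirna = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample class labels
#'
#' Two-column TSV with header `sample`, `class`; classes are `tumor` or
#' `normal`.
#'
#' @param path File path.
#' @return `read_labels`: character vector of classes named by sample.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("label file must have two columns (sample, class)", call. = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_labels
#' @param labels Character vector of classes named by sample.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample = names(labels), class = as.character(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene order is
#' preserved; duplicate genes within a set are collapsed to the first
#' occurrence.
#'
#' @param path Path to a GMT file.
#' @return A `pathway_set`: a named list of character gene vectors with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(pathway_set(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields",
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2), names(sets))
  pathway_set(sets, descriptions = desc)
}

#' Construct a pathway set
#'
#' @param sets Named list of character gene vectors (non-empty).
#' @param descriptions Optional named character vector of descriptions.
#' @return A `pathway_set` object.
#' @export
pathway_set <- function(sets, descriptions = NULL) {
  if (length(sets) > 0) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      stop("pathway sets must be named", call. = FALSE)
    }
    if (any(lengths(sets) == 0)) {
      stop("pathway gene sets must be non-empty", call. = FALSE)
    }
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("pathway_set: %d pathways, median size %s\n", length(x),
              if (length(x)) stats::median(lengths(x)) else NA))
  invisible(x)
}

#' Write gene sets in GMT format
#'
#' @param pathways A `pathway_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  desc <- attr(pathways, "descriptions")
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], desc[[names(pathways)[i]]], pathways[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a miRNA-to-target-gene map
#'
#' Two-column TSV (header `mirna`, `gene`), one target pair per line. Rows are
#' aggregated by miRNA and duplicate pairs dropped.
#'
#' @param path File path.
#' @return `read_target_map`: a `target_map` — named list mapping each miRNA to
#'   a character vector of target genes.
#' @export
read_target_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1) {
    warning("empty target map file: ", path, call. = FALSE)
    return(structure(list(), class = "target_map"))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    stop("target map line ", which(nf != 2)[1] + 1L,
         " does not have exactly 2 fields", call. = FALSE)
  }
  mir <- vapply(fields, `[[`, "", 1)
  gene <- vapply(fields, `[[`, "", 2)
  tm <- lapply(split(gene, mir), unique)
  structure(tm[unique(mir)], class = "target_map")
}

#' @rdname read_target_map
#' @param target_map Named list mapping miRNA to target gene vectors.
#' @export
write_target_map <- function(target_map, path) {
  df <- data.frame(
    mirna = rep(names(target_map), lengths(target_map)),
    gene = unlist(target_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
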