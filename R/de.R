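#' Filter miRNAs by detection fraction
#'
#' Retains miRNAs detected in a sufficient fraction of samples. On the counts
#' platform a miRNA is kept when its detected fraction is at least
#' `min_detect_frac` (default 0.40, i.e. up to 60% of its reads may be zero);
#' on the Ct platform the comparison is strict (detectable in *over* 60% of
#' samples by default). A threshold of 0 keeps everything.
#'
#' @param x An [expression_matrix()].
#' @param min_detect_frac Minimum detected fraction in `[0, 1]`; platform
#'   default 0.40 (counts) or 0.60 (ct).
#' @return The filtered [expression_matrix()].
#' @export
detection_filter <- function(x, min_detect_frac = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(min_detect_frac)) {
    min_detect_frac <- if (x$platform == "counts") 0.40 else 0.60
  }
  if (min_detect_frac < 0 || min_detect_frac > 1) {
    stop("min_detect_frac must be in [0, 1]", call. = FALSE)
  }
  frac <- rowMeans(detected(x))
  keep <- if (x$platform == "ct" && min_detect_frac > 0) {
    frac > min_detect_frac
  } else {
    frac >= min_detect_frac
  }
  x$values <- x$values[keep, , drop = FALSE]
  x
}

#' Two-class differential expression test
#'
#' Per-miRNA two-sample t-test on normalized log2 values with
#' Benjamini-Hochberg FDR adjustment across all tested miRNAs. The fold change
#' is `2^(mean(tumor) - mean(normal))` of the normalized values — the linear
#' tumor/normal ratio for counts and the `-delta-delta-Ct` fold change for Ct
#' data (both platforms are log2 after normalization, with larger = more
#' abundant).
#'
#' @param x A `normalized_matrix`/`normalization_result` (or a plain log2
#'   matrix, features x samples).
#' @param labels Class labels (`tumor`/`normal`); taken from `x` when present.
#' @param var_equal Pooled-variance t-test (default); `FALSE` gives Welch.
#' @param detected_only Restrict each miRNA's test to samples in which it was
#'   detected (default). On the Ct platform undetected reactions are missing
#'   anyway; on the counts platform this masks structural dropout zeros, which
#'   would otherwise enter the log2 scale as extreme outliers far below any
#'   detected measurement. Has no effect on plain matrices without detection
#'   information.
#' @return A data frame of class `de_result` with one row per miRNA: `mirna`,
#'   `FC` (linear tumor/normal), `log2FC`, `t`, `p`, `q`, `detected_frac`
#'   (fraction of samples with a detected value). miRNAs with fewer than two
#'   usable values in a class get `NA` statistics and are excluded from the BH
#'   adjustment.
#' @export
two_class_test <- function(x, labels = NULL, var_equal = TRUE,
                           detected_only = TRUE) {
  vl <- values_and_labels(x, labels)
  y <- align_labels(vl$labels, colnames(vl$values))
  if (min(table(y)) < 2) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  v <- if (detected_only) masked_values(vl) else vl$values
  st <- row_t_stats(v, y == "tumor", var_equal = var_equal)
  ok <- st$n_a >= 2 & st$n_b >= 2
  t <- ifelse(ok, st$t, NA_real_)
  p <- ifelse(ok, st$p, NA_real_)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  log2fc <- st$mean_a - st$mean_b
  res <- data.frame(
    mirna = rownames(vl$values),
    FC = 2^log2fc,
    log2FC = log2fc,
    t = t,
    p = p,
    q = q,
    detected_frac = if (is.null(vl$detected)) rowMeans(!is.na(vl$values))
                    else rowMeans(vl$detected),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(res) <- c("de_result", "data.frame")
  res
}

#' Fold change from class means
#'
#' Linear tumor/normal ratio of mean expression levels, the quantity reported
#' alongside differential-expression calls.
#'
#' @param mean_a Tumor-class mean (non-negative).
#' @param mean_b Normal-class mean (strictly positive).
#' @return `mean_a / mean_b` (vectorized).
#' @export
#' @examples
#' fold_change(1422, 3810)  # ~0.37, an under-expressed gene
fold_change <- function(mean_a, mean_b) {
  if (any(mean_b == 0)) {
    stop("fold change undefined: normal-class mean is 0", call. = FALSE)
  }
  if (any(mean_a < 0) || any(mean_b < 0)) {
    stop("expression means must be non-negative", call. = FALSE)
  }
  mean_a / mean_b
}

# Rank-product statistics for one labeling: for every tumor x normal sample
# pair, miRNAs are ranked by the pairwise log-ratio (rank 1 = most
# up-regulated for the "up" statistic, most down-regulated for "down"); the
# statistic is the geometric mean of ranks across pairs. NA-tolerant: pairs
# where a miRNA is missing are skipped for that miRNA.
rp_statistic <- function(v, tumor_idx, normal_idx) {
  m <- nrow(v)
  sum_log_up <- sum_log_dn <- numeric(m)
  n_pairs <- integer(m)
  for (ti in tumor_idx) {
    for (ni in normal_idx) {
      d <- v[, ti] - v[, ni]
      ok <- !is.na(d)
      r_up <- rank(-d[ok], ties.method = "average")
      sum_log_up[ok] <- sum_log_up[ok] + log(r_up)
      # reversing the ranking: down-rank = (#ok + 1 - up-rank) for ties too
      sum_log_dn[ok] <- sum_log_dn[ok] + log(sum(ok) + 1 - r_up)
      n_pairs[ok] <- n_pairs[ok] + 1L
    }
  }
  rp_up <- ifelse(n_pairs > 0, exp(sum_log_up / n_pairs), NA_real_)
  rp_dn <- ifelse(n_pairs > 0, exp(sum_log_dn / n_pairs), NA_real_)
  list(up = rp_up, down = rp_dn)
}

#' Rank-product differential expression
#'
#' For every tumor/normal sample pair, miRNAs are ranked by the pairwise
#' log-ratio; the rank product is the geometric mean of a miRNA's ranks across
#' all pairs, computed separately for up- and down-regulation (small values
#' flag consistent regulation). Significance is assessed by label permutation:
#' for each direction, `rp_p = (1 + #\{permuted rp <= observed rp\}) /
#' (n_perm + 1)` per miRNA, and the reported two-sided `rp_p` is the smaller
#' directional p-value Bonferroni-doubled (capped at 1).
#'
#' @param x A `normalized_matrix`/`normalization_result` or log2 matrix.
#' @param labels Class labels; taken from `x` when present.
#' @param n_perm Number of label permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @return Data frame with columns `mirna`, `rp_up`, `rp_down`, `rp` (the
#'   statistic of the better-supported direction), `direction`, and `rp_p`.
#' @export
rank_product <- function(x, labels = NULL, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  vl <- values_and_labels(x, labels)
  v <- vl$values
  y <- align_labels(vl$labels, colnames(v))
  tumor_idx <- which(y == "tumor")
  normal_idx <- which(y == "normal")
  if (length(tumor_idx) < 1 || length(normal_idx) < 1) {
    stop("each class needs at least 1 sample", call. = FALSE)
  }
  obs <- rp_statistic(v, tumor_idx, normal_idx)
  cnt_up <- cnt_dn <- numeric(nrow(v))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(ncol(v))
      pr <- rp_statistic(v, perm[seq_along(tumor_idx)],
                         perm[-seq_along(tumor_idx)])
      cnt_up <- cnt_up + (pr$up <= obs$up)
      cnt_dn <- cnt_dn + (pr$down <= obs$down)
    }
  })
  p_up <- (1 + cnt_up) / (n_perm + 1)
  p_dn <- (1 + cnt_dn) / (n_perm + 1)
  use_up <- p_up < p_dn | (p_up == p_dn & obs$up <= obs$down)
  data.frame(
    mirna = rownames(v),
    rp_up = obs$up,
    rp_down = obs$down,
    rp = ifelse(use_up, obs$up, obs$down),
    direction = ifelse(use_up, "up", "down"),
    rp_p = pmin(1, 2 * pmin(p_up, p_dn)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Select a miRNA signature from differential-expression results
#'
#' Applies the signature gate used for downstream pathway analysis: FDR below
#' `q_max` and at least `min_fold`-fold change in either direction.
#'
#' @param de A `de_result` from [two_class_test()].
#' @param q_max FDR threshold (strict: `q < q_max`).
#' @param min_fold Minimal linear fold change (`FC >= min_fold` or
#'   `FC <= 1/min_fold`); `1` reduces the gate to the FDR filter.
#' @return Character vector of miRNA identifiers ordered by increasing `q`.
#' @export
select_signature <- function(de, q_max = 0.007, min_fold = 2) {
  stopifnot(is.data.frame(de), all(c("mirna", "FC", "q") %in% names(de)))
  keep <- !is.na(de$q) & de$q < q_max &
    (de$FC >= min_fold | de$FC <= 1 / min_fold)
  de$mirna[keep][order(de$q[keep])]
}
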