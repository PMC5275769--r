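# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Row-wise two-sample t statistics on a features x samples matrix.
# `is_a` flags the first class (tumor). Pooled variance by default, Welch
# optional. NAs tolerated; rows without enough observations get NA stats.
# Degenerate rows (zero pooled variance) get t = 0, p = 1 when the class
# means agree, and t = +/-Inf, p = 0 otherwise.
row_t_stats <- function(x, is_a, var_equal = TRUE) {
  xa <- x[, is_a, drop = FALSE]
  xb <- x[, !is_a, drop = FALSE]
  na <- rowSums(!is.na(xa))
  nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE)
  mb <- rowMeans(xb, na.rm = TRUE)
  ssa <- rowSums((xa - ma)^2, na.rm = TRUE)
  ssb <- rowSums((xb - mb)^2, na.rm = TRUE)
  d <- ma - mb
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ifelse(df > 0, (ssa + ssb) / df, NA_real_)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    va <- ssa / (na - 1)
    vb <- ssb / (nb - 1)
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  t <- d / se
  p <- 2 * stats::pt(-abs(t), df)
  zerovar <- !is.na(se) & se == 0
  if (any(zerovar)) {
    t[zerovar] <- ifelse(d[zerovar] == 0, 0, sign(d[zerovar]) * Inf)
    p[zerovar] <- ifelse(d[zerovar] == 0, 1, 0)
  }
  bad <- na < 1 | nb < 1 | is.na(df) | df < 1
  t[bad] <- NA_real_
  p[bad] <- NA_real_
  list(t = t, p = p, mean_a = ma, mean_b = mb, n_a = na, n_b = nb, df = df)
}

# Coerce labels to a factor with levels c("normal", "tumor"), aligned to
# `samples`, validating coverage and the two-class vocabulary.
align_labels <- function(labels, samples) {
  if (is.null(labels)) {
    stop("class labels are required but none were supplied", call. = FALSE)
  }
  lv <- as.character(labels)
  if (!is.null(names(labels))) {
    missing <- setdiff(samples, names(labels))
    if (length(missing) > 0) {
      stop("no class label for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    lv <- as.character(labels)[match(samples, names(labels))]
  } else if (length(labels) != length(samples)) {
    stop("labels must be named by sample or match the number of samples",
         call. = FALSE)
  }
  bad <- setdiff(unique(lv), c("tumor", "normal"))
  if (length(bad) > 0) {
    stop("class labels must be 'tumor' or 'normal'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(lv, levels = c("normal", "tumor"))
}

# Extract a numeric features x samples matrix plus labels from any of:
# expression_matrix, normalized_matrix, normalization_result, plain matrix.
values_and_labels <- function(x, labels = NULL) {
  det <- NULL
  if (inherits(x, "normalization_result")) x <- x$normalized
  if (inherits(x, c("expression_matrix", "normalized_matrix"))) {
    v <- x$values
    if (is.null(labels)) labels <- x$labels
    det <- if (inherits(x, "normalized_matrix")) x$detected else NULL
  } else if (is.matrix(x)) {
    v <- x
  } else {
    stop("expected an expression matrix, normalized matrix, or numeric matrix",
         call. = FALSE)
  }
  list(values = v, labels = labels, detected = det)
}

# Values with undetected entries masked to NA (identity when no detection
# information accompanies the matrix, and for the ct platform where
# undetected is already NA).
masked_values <- function(vl) {
  v <- vl$values
  if (!is.null(vl$detected)) v[!vl$detected] <- NA_real_
  v
}
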