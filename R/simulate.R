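#' Simulation configuration
#'
#' Parameters of the two-class synthetic miRNA expression generator. Defaults
#' mirror the brush-biopsy sequencing cohort the pipeline was designed around:
#' 20 tumor versus 7 normal samples over ~450 mature miRNAs, with 13 planted
#' differential miRNAs. Count data follow a gamma-Poisson (negative binomial)
#' model with log-normal baseline abundances spanning several orders of
#' magnitude, independent Bernoulli dropout, and a 3-fold uniform library-size
#' spread; Ct data are Gaussian on the cycle scale with censoring above the
#' detection ceiling.
#'
#' @param n_tumor,n_normal Samples per class.
#' @param n_mirna Number of miRNA features, including the three red-blood-cell
#'   contamination markers (so `n_mirna >= n_de + 3`).
#' @param n_de Number of planted differentially expressed miRNAs.
#' @param fold_changes Multiplicative effect sizes (linear scale, all `>= 1`),
#'   recycled to length `n_de`; each planted miRNA's direction (up or down in
#'   tumor) is randomized 50/50.
#' @param dispersion Negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param zero_inflation Probability of structural dropout per observation.
#' @param rbc_spike Multiplicative enrichment of the contamination markers in
#'   tumor samples only.
#' @param ct_ceiling Maximal Ct; values above it are recorded as undetected.
#' @param library_spread Max/min ratio of per-sample library-size factors
#'   (drawn uniformly on `[1, library_spread]`).
#' @param ct_noise_sd Replicate noise on the Ct scale, in cycles.
#' @param ct_sample_sd Per-sample Ct offset (input-amount variation), cycles.
#' @param seed Integer RNG seed; identical seed and config give bit-identical
#'   output.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tumor = 20, n_normal = 7, n_mirna = 450, n_de = 13,
                       fold_changes = 4, dispersion = 0.2,
                       zero_inflation = 0.15, rbc_spike = 8, ct_ceiling = 40,
                       library_spread = 3, ct_noise_sd = 0.5,
                       ct_sample_sd = 0.75, seed = 1) {
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid configuration field '", field, "': ", what,
                  call. = FALSE)
  }
  chk(is.numeric(n_tumor) && n_tumor >= 1, "n_tumor", "need >= 1")
  chk(is.numeric(n_normal) && n_normal >= 1, "n_normal", "need >= 1")
  chk(is.numeric(n_mirna) && n_mirna >= 4, "n_mirna", "need >= 4")
  chk(is.numeric(n_de) && n_de >= 0, "n_de", "need >= 0")
  chk(n_de <= n_mirna - 3, "n_de",
      "must leave room for the 3 contamination markers (n_de <= n_mirna - 3)")
  chk(is.numeric(fold_changes) && all(fold_changes >= 1), "fold_changes",
      "all effect sizes must be >= 1 on the linear scale")
  chk(is.numeric(dispersion) && dispersion >= 0, "dispersion", "need >= 0")
  chk(is.numeric(zero_inflation) && zero_inflation >= 0 && zero_inflation <= 1,
      "zero_inflation", "need a probability in [0, 1]")
  chk(is.numeric(rbc_spike) && rbc_spike >= 1, "rbc_spike", "need >= 1")
  chk(is.numeric(ct_ceiling) && ct_ceiling > 0, "ct_ceiling", "need > 0")
  chk(is.numeric(library_spread) && library_spread >= 1, "library_spread",
      "need >= 1")
  chk(is.numeric(seed) && is.finite(seed), "seed", "need a finite number")
  structure(list(
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    n_mirna = as.integer(n_mirna), n_de = as.integer(n_de),
    fold_changes = if (n_de > 0) rep_len(fold_changes, n_de) else numeric(0),
    dispersion = dispersion, zero_inflation = zero_inflation,
    rbc_spike = rbc_spike, ct_ceiling = ct_ceiling,
    library_spread = library_spread, ct_noise_sd = ct_noise_sd,
    ct_sample_sd = ct_sample_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

# Ground truth shared by both platforms: planted effects, marker rows, and
# the identifier of the pathway the annotation generator will enrich.
new_ground_truth <- function(de_fc, markers) {
  structure(list(de_mirnas = de_fc, contamination_markers = markers,
                 planted_pathway = "PW_PLANTED"),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d planted miRNAs, planted pathway '%s'\n",
              length(x$de_mirnas), x$planted_pathway))
  invisible(x)
}

# Shared latent layer: identifiers, baselines, planted effects.
sim_latent <- function(config) {
  markers <- rbc_markers()
  ids <- c(markers, sprintf("mir-%04d", seq_len(config$n_mirna - 3L)))
  ids <- sample(ids)  # marker rows land at random positions
  mu <- stats::rlnorm(config$n_mirna, meanlog = log(200), sdlog = 1.8)
  names(mu) <- ids
  de_ids <- character(0)
  true_fc <- numeric(0)
  if (config$n_de > 0) {
    de_ids <- sample(setdiff(ids, markers), config$n_de)
    dir <- sample(c(1, -1), config$n_de, replace = TRUE)
    true_fc <- config$fold_changes^dir
    names(true_fc) <- de_ids
  }
  n <- config$n_tumor + config$n_normal
  samples <- c(sprintf("T%02d", seq_len(config$n_tumor)),
               sprintf("N%02d", seq_len(config$n_normal)))
  labels <- stats::setNames(
    rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal)), samples)
  is_tumor <- labels == "tumor"
  # per-miRNA x per-sample expected abundance on the linear scale
  eff <- matrix(1, config$n_mirna, n, dimnames = list(ids, samples))
  if (length(de_ids) > 0) eff[de_ids, is_tumor] <- true_fc
  eff[markers, is_tumor] <- eff[markers, is_tumor] * config$rbc_spike
  list(ids = ids, mu = mu, eff = eff, samples = samples, labels = labels,
       truth = new_ground_truth(true_fc, markers))
}

#' Simulate a two-class miRNA count matrix
#'
#' Draws negative-binomial read counts with log-normal baseline means, uniform
#' library-size factors, planted tumor/normal fold changes (direction
#' randomized), contamination-marker spikes in tumor samples, and independent
#' Bernoulli dropout. Before dropout, the expected tumor/normal mean ratio of
#' each planted miRNA equals its planted fold change.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (an [expression_matrix()] with
#'   `platform = "counts"` and labels) and `truth` (a `ground_truth`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lat <- sim_latent(config)
    n <- length(lat$samples)
    sf <- stats::runif(n, 1, config$library_spread)
    mean_mat <- (lat$mu * lat$eff) %*% diag(sf, n)
    dimnames(mean_mat) <- list(lat$ids, lat$samples)
    counts <- if (config$dispersion > 0) {
      matrix(stats::rnbinom(length(mean_mat), mu = mean_mat,
                            size = 1 / config$dispersion),
             nrow(mean_mat), dimnames = dimnames(mean_mat))
    } else {
      matrix(stats::rpois(length(mean_mat), mean_mat),
             nrow(mean_mat), dimnames = dimnames(mean_mat))
    }
    if (config$zero_inflation > 0) {
      drop <- matrix(stats::runif(length(counts)) < config$zero_inflation,
                     nrow(counts))
      counts[drop] <- 0
    }
    list(matrix = expression_matrix(counts, "counts", labels = lat$labels),
         truth = lat$truth)
  })
}

#' Simulate a two-class miRNA Ct matrix
#'
#' Maps the same latent abundance model to the qPCR cycle-threshold scale:
#' `Ct = 36 - log2(abundance)` plus a per-sample offset and Gaussian replicate
#' noise, so a planted fold change `f` appears as a tumor-minus-normal Ct
#' difference of `-log2(f)`. Values above `ct_ceiling` and structural dropouts
#' are recorded as undetected (`NA`).
#'
#' @inheritParams simulate_counts
#' @return As [simulate_counts()], with `platform = "ct"`.
#' @export
simulate_ct <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lat <- sim_latent(config)
    n <- length(lat$samples)
    off <- stats::rnorm(n, 0, config$ct_sample_sd)
    ct0 <- 36 - log2(lat$mu)  # baseline cycle threshold per miRNA
    ct <- ct0 - log2(lat$eff) +
      matrix(off, nrow(lat$eff), n, byrow = TRUE) +
      matrix(stats::rnorm(length(lat$eff), 0, config$ct_noise_sd),
             nrow(lat$eff))
    ct <- pmax(ct, 1)
    ct[ct > config$ct_ceiling] <- NA_real_
    if (config$zero_inflation > 0) {
      drop <- matrix(stats::runif(length(ct)) < config$zero_inflation,
                     nrow(ct))
      ct[drop] <- NA_real_
    }
    dimnames(ct) <- list(lat$ids, lat$samples)
    list(matrix = expression_matrix(ct, "ct", labels = lat$labels),
         truth = lat$truth)
  })
}

#' Simulate a miRNA target map and pathway collection
#'
#' Builds a synthetic gene universe, a pathway collection, and a per-miRNA
#' target map with two planted structures: (i) the genes of
#' `truth$planted_pathway` are over-represented among the targets of the
#' planted differential miRNAs (strength `enrichment`), emulating a genuinely
#' regulated pathway, and (ii) a pool of "promiscuous" genes (the members of
#' `n_promiscuous` pathways) is drawn at an elevated rate by *every* miRNA,
#' emulating the carcinogenesis-pathway overweighting of curated target
#' databases that the random-set negative-control filter is designed to
#' remove.
#'
#' The target map covers `n_mirna_universe` miRNAs — a catalogue larger than
#' the profiled panel, mirroring the pool of miRNAs known to be expressed in
#' human cells from which negative-control sets are drawn — with the profiled
#' miRNAs as a subset.
#'
#' @param config A [sim_config()]; its `seed` (offset, so annotation draws are
#'   independent of the expression draws) makes the output reproducible.
#' @param truth A `ground_truth` from [simulate_counts()] or [simulate_ct()].
#' @param n_genes Size of the synthetic gene universe.
#' @param n_mirna_universe Total miRNAs in the target map (at least
#'   `config$n_mirna`).
#' @param n_pathways Total number of pathways.
#' @param pathway_size Genes per pathway.
#' @param targets_per_mirna Target genes drawn per miRNA.
#' @param enrichment Fraction (in `[0, 1]`) of each planted miRNA's
#'   non-promiscuous target draws taken from the planted pathway; `0` disables
#'   the planted enrichment.
#' @param n_promiscuous Number of promiscuous pathways.
#' @param promiscuous_frac Fraction of every miRNA's targets drawn from the
#'   promiscuous gene pool.
#'
#' @return A list with elements `target_map` (a `target_map`) and `pathways`
#'   (a `pathway_set`).
#' @export
simulate_annotation <- function(config, truth, n_genes = 2000,
                                n_mirna_universe = 2000,
                                n_pathways = 20, pathway_size = 50,
                                targets_per_mirna = 30, enrichment = 0.8,
                                n_promiscuous = 3, promiscuous_frac = 0.5) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (enrichment < 0 || enrichment > 1) {
    stop("invalid configuration field 'enrichment': need a value in [0, 1]",
         call. = FALSE)
  }
  if (n_mirna_universe < config$n_mirna) {
    stop("invalid configuration field 'n_mirna_universe': must be at least n_mirna",
         call. = FALSE)
  }
  with_seed(config$seed + 101L, {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    markers <- truth$contamination_markers
    mirnas <- c(markers, sprintf("mir-%04d", seq_len(n_mirna_universe - 3L)))
    # disjoint gene pools for the planted and promiscuous pathways
    special <- sample(genes, pathway_size * (1 + n_promiscuous))
    planted_genes <- special[seq_len(pathway_size)]
    prom_pool <- special[-seq_len(pathway_size)]
    sets <- list()
    sets[[truth$planted_pathway]] <- planted_genes
    for (i in seq_len(n_promiscuous)) {
      sets[[sprintf("PW_PROM%02d", i)]] <-
        prom_pool[(i - 1) * pathway_size + seq_len(pathway_size)]
    }
    for (i in seq_len(n_pathways - 1 - n_promiscuous)) {
      sets[[sprintf("PW%02d", i)]] <- sample(genes, pathway_size)
    }
    n_prom <- round(targets_per_mirna * promiscuous_frac)
    n_rest <- targets_per_mirna - n_prom
    tm <- lapply(stats::setNames(mirnas, mirnas), function(m) {
      t_prom <- sample(prom_pool, n_prom)
      if (m %in% names(truth$de_mirnas) && enrichment > 0) {
        n_pl <- round(n_rest * enrichment)
        t_rest <- c(sample(planted_genes, min(n_pl, pathway_size)),
                    sample(genes, n_rest - min(n_pl, pathway_size)))
      } else {
        t_rest <- sample(genes, n_rest)
      }
      unique(c(t_prom, t_rest))
    })
    list(target_map = structure(tm, class = "target_map"),
         pathways = pathway_set(sets))
  })
}
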