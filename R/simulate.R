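# Seeded simulators producing inputs with the statistical structure the
# package's analyses assume: (a) paired probe-level datasets whose genes share
# latent signal across datasets, (b) module-structured data driven by latent
# eigengenes, and (c) cell mixtures formed as known convex combinations of
# pure profiles. Every generator is bit-reproducible from its seed and
# returns the planted truth alongside the data.

#' Simulate a pair of probe-level expression datasets sharing gene signal
#'
#' Emulates two independent microarray studies of the same tissue measured
#' with different probe sets. Each gene `g` has a baseline level and a factor
#' loading, both shared between the datasets; within each dataset the gene's
#' latent profile is `loading * common_factor + sqrt(1 - loading^2) * noise`
#' (unit variance), so gene-level mean expression and co-expression structure
#' reproduce across datasets. Each probe measures
#' `baseline + signal_fraction * latent + N(0, noise_sd^2)`. One probe per
#' gene is the planted "carrier": it has the largest signal fraction and a
#' baseline bump, so selecting the probe with the highest mean expression also
#' selects the probe carrying the gene signal.
#'
#' With a unit-variance latent, the expected correlation between two probes of
#' the same gene with signal fractions `a1`, `a2` is
#' `a1 * a2 / sqrt((a1^2 + noise_sd^2) * (a2^2 + noise_sd^2))`.
#'
#' @param n_genes Number of genes.
#' @param max_probes Probes per gene are drawn uniformly from `1:max_probes`.
#' @param n_samples Integer vector of length 2: samples in each dataset.
#' @param carrier_signal Signal fraction of the planted carrier probe.
#' @param other_signal_range Range (min, max) of the uniform signal fractions
#'   of non-carrier probes.
#' @param carrier_mean_bump Baseline offset added to the carrier probe.
#' @param baseline_mean,baseline_sd Gene baseline levels are
#'   `N(baseline_mean, baseline_sd^2)`, shared between datasets.
#' @param loading_range Range of the per-gene factor loadings (shared between
#'   datasets) that induce gene-gene correlation.
#' @param noise_sd Probe-level noise standard deviation.
#' @param seed Integer seed.
#' @return List with `data` (list of two matrices, probes x samples), `groups`
#'   (named character vector probe -> gene), `planted` (data.frame `gene`,
#'   `carrier_probe`), and `spec` (the parameters used).
#' @export
simulate_probe_gene_pair <- function(n_genes = 100, max_probes = 4,
                                     n_samples = c(20, 20),
                                     carrier_signal = 0.9,
                                     other_signal_range = c(0.2, 0.6),
                                     carrier_mean_bump = 1,
                                     baseline_mean = 8, baseline_sd = 2,
                                     loading_range = c(0.2, 0.9),
                                     noise_sd = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1, max_probes >= 1, length(n_samples) == 2,
            all(n_samples >= 3), carrier_signal > 0,
            all(other_signal_range >= 0), noise_sd >= 0)
  with_seed(seed, {
    n_probes <- sample.int(max_probes, n_genes, replace = TRUE)
    gene_ids <- sprintf("g%03d", seq_len(n_genes))
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    lambda <- stats::runif(n_genes, loading_range[1], loading_range[2])

    probe_gene <- rep(seq_len(n_genes), n_probes)
    probe_rank <- sequence(n_probes)            # 1 = carrier
    probe_ids <- sprintf("%s_p%d", gene_ids[probe_gene], probe_rank)
    a <- ifelse(probe_rank == 1, carrier_signal,
                stats::runif(length(probe_gene), other_signal_range[1],
                             other_signal_range[2]))
    b <- baseline[probe_gene] +
      ifelse(probe_rank == 1, carrier_mean_bump,
             -stats::runif(length(probe_gene), 0.2, 1.5))

    make_dataset <- function(ns, tag) {
      f <- stats::rnorm(ns)                     # common factor across genes
      u <- matrix(stats::rnorm(n_genes * ns), n_genes, ns)
      latent <- outer(lambda, f) + sweep(u, 1, sqrt(1 - lambda^2), `*`)
      x <- b + a * latent[probe_gene, , drop = FALSE] +
        matrix(stats::rnorm(length(probe_gene) * ns, sd = noise_sd),
               length(probe_gene), ns)
      dimnames(x) <- list(probe_ids, sprintf("%s_s%02d", tag, seq_len(ns)))
      x
    }
    data1 <- make_dataset(n_samples[1], "d1")
    data2 <- make_dataset(n_samples[2], "d2")

    list(
      data = list(data1, data2),
      groups = stats::setNames(gene_ids[probe_gene], probe_ids),
      planted = data.frame(gene = gene_ids,
                           carrier_probe = sprintf("%s_p1", gene_ids),
                           stringsAsFactors = FALSE),
      spec = list(n_genes = n_genes, max_probes = max_probes,
                  n_samples = n_samples, carrier_signal = carrier_signal,
                  other_signal_range = other_signal_range,
                  carrier_mean_bump = carrier_mean_bump,
                  baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                  loading_range = loading_range, noise_sd = noise_sd,
                  seed = as.integer(seed))
    )
  })
}

#' Simulate module-structured expression data with planted hubs
#'
#' Each module is driven by a latent eigengene (standard normal across
#' samples); member rows are `loading * eigengene + N(0, noise_sd^2)`. One row
#' per module carries the `hub_loading` (the largest), so the true hub is
#' known; the remaining loadings are uniform on `loading_range`.
#'
#' @param n_modules Number of modules.
#' @param module_size Rows per module (>= 3 so connectivity-based collapsing
#'   applies).
#' @param n_samples Number of samples.
#' @param hub_loading Loading of the planted hub row.
#' @param loading_range Range of the non-hub loadings (below `hub_loading`).
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer seed.
#' @return List with `mat` (rows x samples), `groups` (row -> module),
#'   `loadings` (named numeric), `hubs` (named character, module -> planted
#'   hub row), `eigengenes` (modules x samples), and `spec`.
#' @export
simulate_modules <- function(n_modules = 5, module_size = 10, n_samples = 40,
                             hub_loading = 0.95,
                             loading_range = c(0.2, 0.5), noise_sd = 0.15,
                             seed = 1L) {
  stopifnot(n_modules >= 1, module_size >= 3, n_samples >= 3,
            hub_loading > max(loading_range), noise_sd >= 0)
  with_seed(seed, {
    modules <- sprintf("M%d", seq_len(n_modules))
    n <- n_modules * module_size
    row_module <- rep(seq_len(n_modules), each = module_size)
    member <- rep(seq_len(module_size), n_modules)
    ids <- sprintf("%s_r%02d", modules[row_module], member)
    loading <- ifelse(member == 1, hub_loading,
                      stats::runif(n, loading_range[1], loading_range[2]))
    E <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples,
                dimnames = list(modules, sprintf("s%02d", seq_len(n_samples))))
    mat <- loading * E[row_module, , drop = FALSE] +
      matrix(stats::rnorm(n * n_samples, sd = noise_sd), n, n_samples)
    dimnames(mat) <- list(ids, colnames(E))
    list(
      mat = mat,
      groups = stats::setNames(modules[row_module], ids),
      loadings = stats::setNames(loading, ids),
      hubs = stats::setNames(ids[member == 1], modules[row_module[member == 1]]),
      eigengenes = E,
      spec = list(n_modules = n_modules, module_size = module_size,
                  n_samples = n_samples, hub_loading = hub_loading,
                  loading_range = loading_range, noise_sd = noise_sd,
                  seed = as.integer(seed))
    )
  })
}

#' Simulate pure cell-type profiles and mixtures in known proportions
#'
#' Builds pure expression profiles with planted type-specific markers, then
#' forms mixture samples as proportion-weighted combinations of the pure
#' profiles plus multiplicative noise. A marker for type `t` is expressed at
#' an "on" level in `t` and at `on / fold` in every other type, with the
#' per-marker specificity `fold` drawn log-uniformly from `fold_range`;
#' background genes are expressed uniformly across types. Because each
#' mixture's proportions sum to 1, every marker's noise-free mixture profile
#' is an affine function of its type's proportions, so with `noise_sd = 0`
#' marker-based prediction recovers the truth with per-type correlation
#' exactly 1.
#'
#' Noise is multiplicative Gaussian — each observed value is
#' `value * (1 + N(0, noise_sd^2))` — emulating the roughly
#' intensity-proportional error of array data; with `clamp = TRUE` (default)
#' values are floored at 0 to emulate non-negative intensities (the clamp
#' slightly biases fold changes at high noise).
#'
#' @param n_types Number of cell types.
#' @param n_mix_samples Number of mixture samples.
#' @param markers_per_type Planted markers per type.
#' @param n_background Non-specific background genes.
#' @param pure_replicates Pure-profile replicate columns per type.
#' @param on_range Range of marker "on" levels (linear intensity scale).
#' @param fold_range Range of per-marker specificity folds (log-uniform).
#' @param background_range Range of background gene levels.
#' @param noise_sd Coefficient of variation of the multiplicative noise;
#'   0 gives noise-free data.
#' @param proportions Optional true proportion matrix (types x samples,
#'   columns summing to 1). Default: each sample's proportions drawn from a
#'   symmetric Dirichlet(2).
#' @param clamp Floor noisy values at 0?
#' @param seed Integer seed.
#' @return List with `pure` (genes x pure columns), `pure_types` (named
#'   character, pure column -> type), `mixtures` (genes x mixture samples),
#'   `proportions` (types x samples, columns sum to 1), `truth` (proportions
#'   rescaled so each type sums to 1 across samples — the scaling convention
#'   of [predict_proportions()]), `markers` (named character, planted marker
#'   gene -> type), and `spec`.
#' @export
simulate_mixture <- function(n_types = 4, n_mix_samples = 12,
                             markers_per_type = 50, n_background = 200,
                             pure_replicates = 3, on_range = c(5, 15),
                             fold_range = c(5, 20),
                             background_range = c(1, 10),
                             noise_sd = 0.1, proportions = NULL,
                             clamp = TRUE, seed = 1L) {
  stopifnot(n_types >= 2, n_mix_samples >= 3, markers_per_type >= 1,
            pure_replicates >= 1, noise_sd >= 0, all(fold_range > 1))
  with_seed(seed, {
    types <- sprintf("T%d", seq_len(n_types))
    n_markers <- n_types * markers_per_type
    marker_type <- rep(seq_len(n_types), each = markers_per_type)
    marker_ids <- sprintf("%s_m%03d", types[marker_type],
                          rep(seq_len(markers_per_type), n_types))
    bg_ids <- if (n_background > 0) sprintf("bg%04d", seq_len(n_background))
              else character(0)

    on <- stats::runif(n_markers, on_range[1], on_range[2])
    fold <- exp(stats::runif(n_markers, log(fold_range[1]),
                             log(fold_range[2])))
    S <- matrix(on / fold, n_markers, n_types,
                dimnames = list(marker_ids, types))
    S[cbind(seq_len(n_markers), marker_type)] <- on
    if (n_background > 0) {
      bg <- stats::runif(n_background, background_range[1],
                         background_range[2])
      S <- rbind(S, matrix(bg, n_background, n_types,
                           dimnames = list(bg_ids, types)))
    }

    if (is.null(proportions)) {
      raw <- matrix(stats::rgamma(n_types * n_mix_samples, shape = 2),
                    n_types, n_mix_samples)
      proportions <- sweep(raw, 2, colSums(raw), `/`)
    }
    stopifnot(nrow(proportions) == n_types,
              ncol(proportions) == n_mix_samples,
              all(proportions >= 0))
    if (any(rowSums(proportions) == 0)) {
      stop("a cell type has zero proportion in every sample")
    }
    dimnames(proportions) <- list(types, sprintf("mix%02d",
                                                 seq_len(n_mix_samples)))

    noisy <- function(x) {
      if (noise_sd > 0) {
        x <- x * (1 + matrix(stats::rnorm(length(x), sd = noise_sd),
                             nrow(x), ncol(x)))
        if (clamp) x[x < 0] <- 0
      }
      x
    }
    pure_cols <- rep(seq_len(n_types), each = pure_replicates)
    pure <- noisy(S[, pure_cols, drop = FALSE])
    colnames(pure) <- sprintf("%s_rep%d", types[pure_cols],
                              rep(seq_len(pure_replicates), n_types))
    mixtures <- noisy(S %*% proportions)

    list(
      pure = pure,
      pure_types = stats::setNames(types[pure_cols], colnames(pure)),
      mixtures = mixtures,
      proportions = proportions,
      truth = proportions / rowSums(proportions),
      markers = stats::setNames(types[marker_type], marker_ids),
      spec = list(n_types = n_types, n_mix_samples = n_mix_samples,
                  markers_per_type = markers_per_type,
                  n_background = n_background,
                  pure_replicates = pure_replicates, on_range = on_range,
                  fold_range = fold_range,
                  background_range = background_range, noise_sd = noise_sd,
                  clamp = clamp, seed = as.integer(seed))
    )
  })
}
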