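# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read from disk.

# Simulate one gene and fit the compensation model on its retained samples.
fit_one_synthetic_gene <- function(true_score, cohort_kind = "cellline",
                                   n = 200, seed = 1, base_mean = 500,
                                   amp_fraction = 0.25, nb_shape = 20,
                                   chains = 4, iter = 1000, warmup = 500,
                                   fit_seed = 42) {
  cfg <- simulation_config(n_tissues = 1, samples_per_tissue = n,
                           cohort_kind = cohort_kind, seed = seed)
  truth <- true_gene_params("G1", base_mean = base_mean,
                            true_score = true_score,
                            amp_fraction = amp_fraction, nb_shape = nb_shape)
  coh <- simulate_cohort(cfg, truth)
  des <- encode_copy_number(coh$log2_copy)
  sel <- select_samples_for_gene(des$c[1, ], cohort_kind)
  sf <- coh$sample_info$true_size_factor
  m <- compute_gene_mean(coh$counts[1, ], sf, sel$include)
  inc <- sel$include
  if (cohort_kind == "cellline") {
    fit_gene_cellline(coh$counts[1, inc], des$c[1, inc], des$d[1, inc],
                      sf[inc], m, rep("tissue_1", sum(inc)),
                      chains = chains, iter = iter, warmup = warmup,
                      seed = fit_seed)
  } else {
    fit_gene_tumor(coh$counts[1, inc], des$c[1, inc], des$d[1, inc],
                   sf[inc], m, rep("tissue_1", sum(inc)),
                   purity = coh$sample_info$purity[inc],
                   chains = chains, iter = iter, warmup = warmup,
                   seed = fit_seed)
  }
}

# Minimal multi-gene cohort fixture for pipeline tests.
small_cohort_fixture <- function(dir, seed = 7, cohort_kind = "cellline",
                                 samples = 60) {
  cfg <- simulation_config(n_tissues = 1, samples_per_tissue = samples,
                           cohort_kind = cohort_kind, seed = seed,
                           n_screens = 4, barcodes_per_gene = 4)
  truth <- rbind(
    true_gene_params("COMP1", true_score = -1, true_toxicity_lfc = -1),
    true_gene_params("SCAL1", true_score = 0),
    true_gene_params("HYPE1", true_score = 1)
  )
  coh <- simulate_cohort(cfg, truth)
  screens <- simulate_orf_screens(cfg, truth)
  write_fixture_set(coh, dir, screens)
  list(cohort = coh, screens = screens, config = cfg)
}

# Independent NB log-likelihood oracle: direct log-pmf summation from the
# gamma-function form of the NB pmf (never calls package code or dnbinom).
nb_loglik_oracle <- function(x, mu, shape) {
  sum(lgamma(x + shape) - lgamma(shape) - lgamma(x + 1) +
        shape * (log(shape) - log(shape + mu)) +
        x * (log(mu) - log(shape + mu)))
}

# Benjamini-Hochberg step-up computed by hand (descending-p running
# minimum of p * n / rank), independent of p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  out <- numeric(n)
  running <- 1
  for (j in seq_along(ord)) {
    k <- ord[j]
    running <- min(running, p[k] * n / (n - j + 1))
    out[k] <- running
  }
  out
}

# Exhaustive hypergeometric enumeration oracle for one-sided (enrichment)
# Fisher p: probability of >= k successes in the complex by direct
# enumeration of the hypergeometric pmf from factorials.
fisher_oracle <- function(k, complex_size, n_compensated, universe_size) {
  lchoose_ <- function(n, r) lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)
  ks <- k:min(complex_size, n_compensated)
  ks <- ks[complex_size - ks <= universe_size - n_compensated]
  sum(exp(lchoose_(n_compensated, ks) +
            lchoose_(universe_size - n_compensated, complex_size - ks) -
            lchoose_(universe_size, complex_size)))
}
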