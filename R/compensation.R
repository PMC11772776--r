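#' Negative binomial compensation model log-likelihood
#'
#' Evaluates the model's log-likelihood at fixed parameters: per sample
#' \eqn{\mu = \beta_1^{t} c p + \beta_2 d p + \beta_3^{t} (1-p)} (the
#' \eqn{\beta_3} term only for tumors) and
#' \eqn{r \sim NB(\mathrm{mean} = s\,m\,\mu, \mathrm{shape})}. Returns
#' `-Inf` if any implied mean is nonpositive. Exposed mainly for
#' diagnostics and numerical checks; fitting goes through
#' [fit_gene_cellline()] / [fit_gene_tumor()].
#'
#' @param counts integer counts for the retained samples.
#' @param c,d euploid equivalents and deviation per sample.
#' @param sm per-sample `size_factor * m` product.
#' @param tissue factor or character of tissue labels per sample.
#' @param beta1,beta3 named per-tissue coefficients (`beta3` ignored for
#'   cell lines).
#' @param beta2 deviation coefficient.
#' @param shape NB shape (variance = mu + mu^2/shape).
#' @param purity per-sample purity in (0, 1]; default 1 (cell lines).
#' @param tumor logical; include the non-cancer compartment term.
#' @return Scalar log-likelihood.
#' @export
nb_model_loglik <- function(counts, c, d, sm, tissue, beta1, beta2,
                            shape, beta3 = NULL, purity = rep(1, length(counts)),
                            tumor = FALSE) {
  tissue <- as.factor(tissue)
  levels_t <- levels(tissue)
  b1 <- as.numeric(beta1[levels_t])
  b3 <- if (tumor) as.numeric(beta3[levels_t]) else numeric(length(levels_t))
  .nb_model_loglik_cpp(as.integer(counts), as.numeric(c), as.numeric(d),
                       as.numeric(purity), as.numeric(sm),
                       as.integer(tissue) - 1L, length(levels_t), tumor,
                       b1, beta2, b3, shape)
}

# Split-Rhat (Gelman-Rubin with split chains) for one parameter.
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  B <- n * var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Crude effective sample size: initial positive autocorrelation sum,
# averaged over chains.
ess_basic <- function(draws_by_chain) {
  per_chain <- vapply(draws_by_chain, function(x) {
    n <- length(x)
    if (var(x) == 0) return(n)
    ac <- acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
    pos <- which(ac <= 0)
    k <- if (length(pos)) pos[1] - 1 else length(ac)
    n / (1 + 2 * sum(ac[seq_len(k)]))
  }, 0)
  sum(per_chain)
}

# Shared fitting core for the cell-line and tumor model variants.
fit_gene_nb <- function(counts, c, d, sm, tissue, purity, tumor,
                        chains = 4, iter = 1000, warmup = 500,
                        seed = NULL, rhat_threshold = 1.1) {
  stopifnot(length(counts) >= 2)
  tissue <- droplevels(as.factor(tissue))
  levels_t <- levels(tissue)
  T <- length(levels_t)
  b2_sd <- if (tumor) 0.2 else 0.5
  if (tumor && all(purity <= 0)) {
    stop("all purities are zero: cancer-cell component unidentifiable")
  }
  if (!is.null(seed)) set.seed(seed)

  # moment-based shape init on dosage-adjusted normalized counts
  adj <- counts / (sm * pmax(c, 0.25))
  mu0 <- mean(adj)
  v0 <- var(adj)
  shape0 <- if (is.finite(v0) && v0 > mu0) mu0^2 / (v0 - mu0) else 50
  shape0 <- min(max(shape0, 0.5), 500)

  P <- T + 1L + (if (tumor) T else 0L) + 1L
  init0 <- c(rep(0, T), 0, if (tumor) rep(0, T), log(shape0))

  ti <- as.integer(tissue) - 1L
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init <- init0 + c(rnorm(P - 1, 0, 0.1), rnorm(1, 0, 0.2))
    init[T + 1] <- 0   # beta2 start at the prior center keeps mu positive
    draws[[ch]] <- .nb_mh_chain_cpp(as.integer(counts), as.numeric(c),
                                    as.numeric(d), as.numeric(purity),
                                    as.numeric(sm), ti, T, tumor, b2_sd,
                                    init, as.integer(warmup), as.integer(iter))
  }

  all_draws <- do.call(rbind, draws)
  par_names <- c(paste0("log_beta1.", levels_t), "beta2",
                 if (tumor) paste0("log_beta3.", levels_t), "log_shape")
  colnames(all_draws) <- par_names

  rhat <- vapply(seq_len(P), function(k) {
    split_rhat(lapply(draws, function(m) m[, k]))
  }, 0)
  ess <- vapply(seq_len(P), function(k) {
    ess_basic(lapply(draws, function(m) m[, k]))
  }, 0)

  beta1_draws <- exp(all_draws[, seq_len(T), drop = FALSE])
  b2_draws <- all_draws[, T + 1]
  structure(list(
    cohort_kind = if (tumor) "tumor" else "cellline",
    tissues = levels_t,
    beta1 = setNames(colMeans(beta1_draws), levels_t),
    beta1_sd = setNames(apply(beta1_draws, 2, sd), levels_t),
    beta2 = mean(b2_draws),
    beta2_sd = sd(b2_draws),
    beta3 = if (tumor) {
      b3 <- exp(all_draws[, T + 1 + seq_len(T), drop = FALSE])
      setNames(colMeans(b3), levels_t)
    },
    beta3_sd = if (tumor) {
      b3 <- exp(all_draws[, T + 1 + seq_len(T), drop = FALSE])
      setNames(apply(b3, 2, sd), levels_t)
    },
    shape = mean(exp(all_draws[, P])),
    draws = all_draws,
    diagnostics = list(
      chains = chains, iter = iter, warmup = warmup,
      rhat = setNames(rhat, par_names),
      ess = setNames(ess, par_names),
      converged = all(is.finite(rhat)) && max(rhat) < rhat_threshold
    )
  ), class = "compensation_fit")
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat(sprintf("compensation_fit (%s): beta2 = %.3f (sd %.3f), shape = %.1f\n",
              x$cohort_kind, x$beta2, x$beta2_sd, x$shape))
  cat(sprintf("  beta1 [%s]: %s\n", paste(x$tissues, collapse = ", "),
              paste(sprintf("%.3f", x$beta1), collapse = ", ")))
  cat(sprintf("  max Rhat %.3f, converged: %s\n",
              max(x$diagnostics$rhat), x$diagnostics$converged))
  invisible(x)
}

#' Fit the cell-line compensation model for one gene
#'
#' Bayesian negative binomial regression of raw counts on DNA copy number
#' for a cell-line cohort (purity 1):
#' \deqn{\mu = \sum_t \beta_1^{t} c + \beta_2 d, \qquad
#'       r \sim NB(s\,m\,\mu, \sigma)}
#' with priors \eqn{\beta_1 \sim \mathrm{logNormal}(0,1)},
#' \eqn{\beta_2 \sim N(0, 0.5)} and a weakly informative
#' Gamma(0.01, 0.01) prior on the shape \eqn{\sigma}. The scaling term
#' \eqn{\beta_1} is tissue-specific; the deviation term \eqn{\beta_2} is
#' shared and carries the compensation signal. Posterior draws with a
#' nonpositive implied mean for any sample are rejected (identity link).
#' Inference is component-wise adaptive Metropolis MCMC, seeded and
#' reproducible; convergence is judged by split-Rhat.
#'
#' @param counts_row integer counts for the retained samples of one gene.
#' @param c,d per-sample euploid equivalents / deviation (see
#'   [encode_copy_number()]).
#' @param size_factors per-sample size factors.
#' @param m gene mean from [compute_gene_mean()].
#' @param tissue per-sample tissue labels.
#' @param chains,iter,warmup MCMC settings (post-warmup draws per chain =
#'   `iter`).
#' @param seed integer seed for reproducible inference.
#' @return A `compensation_fit` with posterior means/sds of
#'   \eqn{\beta_1^t}, \eqn{\beta_2}, \eqn{\sigma}, the raw draws, and
#'   diagnostics (split-Rhat, effective sample size, `converged`).
#' @export
fit_gene_cellline <- function(counts_row, c, d, size_factors, m, tissue,
                              chains = 4, iter = 1000, warmup = 500,
                              seed = NULL) {
  stopifnot(m > 0)
  fit_gene_nb(counts_row, c, d, sm = size_factors * m, tissue = tissue,
              purity = rep(1, length(counts_row)), tumor = FALSE,
              chains = chains, iter = iter, warmup = warmup, seed = seed)
}

#' Fit the tumor (purity-corrected) compensation model for one gene
#'
#' As [fit_gene_cellline()], but the cancer component is diluted by tumor
#' purity \eqn{p} and a tissue-specific non-cancer compartment is added:
#' \deqn{\mu = \sum_t \beta_1^{t} c\,p + \beta_2 d\,p +
#'       \sum_t \beta_3^{t} (1-p)}
#' with \eqn{\beta_2 \sim N(0, 0.2)} and
#' \eqn{\beta_3 \sim \mathrm{logNormal}(0,1)}. At purity 1 the model reduces
#' exactly to the cell-line model.
#'
#' @inheritParams fit_gene_cellline
#' @param purity per-sample tumor purity in (0, 1].
#' @return A `compensation_fit` (see [fit_gene_cellline()]) including
#'   \eqn{\beta_3^t} summaries.
#' @export
fit_gene_tumor <- function(counts_row, c, d, size_factors, m, tissue, purity,
                           chains = 4, iter = 1000, warmup = 500,
                           seed = NULL) {
  stopifnot(m > 0, all(purity > 0), all(purity <= 1))
  fit_gene_nb(counts_row, c, d, sm = size_factors * m, tissue = tissue,
              purity = purity, tumor = TRUE,
              chains = chains, iter = iter, warmup = warmup, seed = seed)
}

#' Normalize the deviation coefficient by mean euploid expression
#'
#' Computes \eqn{\beta_2^* = \beta_2 / \bar\beta_1}, where
#' \eqn{\bar\beta_1} is the mean over fitted tissues of the per-tissue
#' scaling coefficient's posterior mean (unweighted by default; optionally
#' weighted by per-tissue sample counts). On this scale \eqn{-1} means full
#' compensation (expression unchanged by gain), \eqn{0} pure dosage
#' scaling, and \eqn{+1} full hyperactivation (twice the per-copy
#' increment).
#'
#' @param fit a `compensation_fit`.
#' @param weights optional per-tissue sample counts for a weighted
#'   normalizer.
#' @return Scalar `beta2_star`.
#' @export
normalize_deviation <- function(fit, weights = NULL) {
  b1 <- fit$beta1
  norm <- if (is.null(weights)) {
    mean(b1)
  } else {
    w <- weights[fit$tissues]
    sum(b1 * w) / sum(w)
  }
  if (!is.finite(norm) || norm <= 0) {
    stop("mean euploid expression (beta1 normalizer) must be positive")
  }
  fit$beta2 / norm
}

#' Significance-shrunk compensation score
#'
#' Shrinks \eqn{\beta_2^*} toward zero by its pseudo-p-value: with
#' \eqn{z = \mathrm{mean}(\beta_2)/\mathrm{sd}(\beta_2)} over the posterior
#' and \eqn{p = 2\,\Phi(-|z|)} (two-sided), the score is
#' \eqn{s = (1 - p)\,\beta_2^*}. Genes with a posterior concentrated away
#' from zero keep essentially all of \eqn{\beta_2^*}; genes whose posterior
#' straddles zero are pulled to zero. Hence \eqn{|s| \le |\beta_2^*|}
#' always, with equality in the limit of overwhelming evidence.
#'
#' @param fit a `compensation_fit`.
#' @param beta2_star normalized deviation from [normalize_deviation()];
#'   recomputed if missing.
#' @return Data frame (one row) with `beta2_star`, `z`, `pseudo_p`,
#'   `score`.
#' @export
shrink_score <- function(fit, beta2_star = NULL) {
  if (is.null(beta2_star)) beta2_star <- normalize_deviation(fit)
  stopifnot(fit$beta2_sd > 0)
  z <- fit$beta2 / fit$beta2_sd
  pseudo_p <- 2 * pnorm(-abs(z))
  data.frame(
    beta2_star = beta2_star,
    z = z,
    pseudo_p = pseudo_p,
    score = (1 - pseudo_p) * beta2_star
  )
}

#' Classify genes as compensated or hyperactivated across two cohorts
#'
#' A gene is called compensated when its shrunk compensation score is below
#' `-threshold` in both cohorts (typically a cell-line and a tumor cohort),
#' and hyperactivated when both scores exceed `+threshold`. Inequalities
#' are strict. Genes scored in only one cohort are labeled
#' `"single-cohort"`.
#'
#' @param scores_a,scores_b data frames with columns `gene` and `score`
#'   from the two cohorts.
#' @param threshold score magnitude boundary (default 0.3).
#' @return Data frame with `gene`, `score_a`, `score_b`, `compensated`,
#'   `hyperactivated`, `status`.
#' @export
classify_compensation <- function(scores_a, scores_b, threshold = 0.3) {
  genes <- union(scores_a$gene, scores_b$gene)
  sa <- scores_a$score[match(genes, scores_a$gene)]
  sb <- scores_b$score[match(genes, scores_b$gene)]
  both <- !is.na(sa) & !is.na(sb)
  compensated <- both & sa < -threshold & sb < -threshold
  hyperactivated <- both & sa > threshold & sb > threshold
  data.frame(
    gene = genes, score_a = sa, score_b = sb,
    compensated = compensated, hyperactivated = hyperactivated,
    status = ifelse(!both, "single-cohort",
                    ifelse(compensated, "compensated",
                           ifelse(hyperactivated, "hyperactivated", "neither"))),
    stringsAsFactors = FALSE
  )
}

#' Gene-set contrast on per-gene scores
#'
#' Estimates the difference between a gene set and its complement with a
#' linear model on per-gene values (compensation scores, or toxicity
#' statistics via [complex_toxicity()]): an indicator-variable least-squares
#' fit whose coefficient is the in-set minus out-of-set mean, with a Wald
#' t-test for significance.
#'
#' @param values named numeric vector of per-gene values.
#' @param in_set logical vector (same length) marking set membership.
#' @return Data frame (one row) with `estimate`, `se`, `wald`, `p`,
#'   `n_in`, `n_out`. `p` is `NA` for degenerate (zero-residual-variance)
#'   inputs.
#' @export
gene_set_difference <- function(values, in_set) {
  stopifnot(length(values) == length(in_set))
  if (!any(in_set) || all(in_set)) {
    stop("gene set and complement must both be non-empty")
  }
  fit <- stats::lm(values ~ in_set)
  co <- summary(fit)$coefficients
  est <- co["in_setTRUE", "Estimate"]
  se <- co["in_setTRUE", "Std. Error"]
  wald <- est / se
  p <- co["in_setTRUE", "Pr(>|t|)"]
  if (!is.finite(se) || se == 0) { wald <- NA_real_; p <- NA_real_ }
  data.frame(estimate = est, se = se, wald = wald, p = p,
             n_in = sum(in_set), n_out = sum(!in_set))
}

#' Fit compensation scores for all eligible genes of a cohort
#'
#' Driver that preprocesses a cohort ([summarize_genes()]), fits the
#' per-gene model ([fit_gene_cellline()] or [fit_gene_tumor()]) on retained
#' samples, and derives normalized shrunk scores. Ineligible and
#' non-converged genes are reported with `NA` scores and a reason.
#'
#' @param counts gene x sample count matrix.
#' @param design `copy_number_design` (same dimensions).
#' @param sample_info data frame with `sample_id`, `tissue` and, for tumor
#'   cohorts, `purity` (missing purity defaults to 1 with a warning).
#' @param cohort_kind `"cellline"` or `"tumor"`.
#' @param chains,iter,warmup,seed MCMC settings; per-gene seeds are derived
#'   from `seed` so results do not depend on gene order.
#' @param tissue_subset optional tissue label: restrict to that tissue's
#'   samples (tissue-specific mode).
#' @inheritParams summarize_genes
#' @return Data frame with one row per gene: posterior summaries, `z`,
#'   `pseudo_p`, `score`, sample counts, `converged`, `reason`.
#' @export
fit_compensation <- function(counts, design, sample_info,
                             cohort_kind = c("cellline", "tumor"),
                             chains = 4, iter = 1000, warmup = 500,
                             seed = 1L, tissue_subset = NULL,
                             neutral_tolerance = 0.15, amp_min = NULL,
                             frequency_threshold = 0.15) {
  cohort_kind <- match.arg(cohort_kind)
  counts <- as.matrix(counts)
  if (!is.null(tissue_subset)) {
    keep <- sample_info$tissue %in% tissue_subset
    counts <- counts[, keep, drop = FALSE]
    design <- encode_copy_number(log2(design$linear_ratio[, keep, drop = FALSE]))
    sample_info <- sample_info[keep, , drop = FALSE]
  }
  purity <- if (cohort_kind == "tumor") {
    if (is.null(sample_info$purity) || all(is.na(sample_info$purity))) {
      warning("tumor cohort without purity: defaulting all purities to 1 ",
              "(cell-line behavior)", call. = FALSE)
      rep(1, nrow(sample_info))
    } else {
      p <- sample_info$purity
      p[is.na(p)] <- 1
      p
    }
  } else {
    rep(1, nrow(sample_info))
  }

  prep <- summarize_genes(counts, design, cohort_kind,
                          neutral_tolerance = neutral_tolerance,
                          amp_min = amp_min,
                          frequency_threshold = frequency_threshold)
  sf <- prep$size_factors
  genes <- prep$summary$gene
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    row <- prep$summary[i, ]
    base <- data.frame(
      gene = row$gene, cohort = cohort_kind,
      tissue_mode = if (is.null(tissue_subset)) "pan" else
        paste(tissue_subset, collapse = "+"),
      beta2_mean = NA_real_, beta2_sd = NA_real_, beta2_star = NA_real_,
      z = NA_real_, pseudo_p = NA_real_, score = NA_real_,
      n_neutral = row$n_neutral, n_amplified = row$n_amplified,
      amp_frequency = row$amp_frequency,
      frequently_amplified = row$frequently_amplified,
      converged = NA, reason = "", stringsAsFactors = FALSE
    )
    if (!isTRUE(row$eligible)) {
      base$reason <- "ineligible: too few amplified samples or zero mean"
      out[[i]] <- base
      next
    }
    inc <- prep$include[i, ]
    fit <- tryCatch(
      fit_gene_nb(counts[i, inc], design$c[i, inc], design$d[i, inc],
                  sm = sf[inc] * row$m, tissue = sample_info$tissue[inc],
                  purity = purity[inc], tumor = cohort_kind == "tumor",
                  chains = chains, iter = iter, warmup = warmup,
                  seed = gene_seed(seed, row$gene)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      base$reason <- conditionMessage(fit)
      out[[i]] <- base
      next
    }
    sc <- shrink_score(fit)
    base$beta2_mean <- fit$beta2
    base$beta2_sd <- fit$beta2_sd
    base$beta2_star <- sc$beta2_star
    base$z <- sc$z
    base$pseudo_p <- sc$pseudo_p
    base$converged <- fit$diagnostics$converged
    base$score <- if (isTRUE(fit$diagnostics$converged)) sc$score else NA_real_
    if (!isTRUE(fit$diagnostics$converged)) base$reason <- "non-converged fit"
    out[[i]] <- base
  }
  do.call(rbind, out)
}

# Stable per-gene seed below 2^31 derived from a base seed and the gene id.
gene_seed <- function(seed, gene_id) {
  h <- sum(utf8ToInt(as.character(gene_id)) * seq_along(utf8ToInt(as.character(gene_id))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
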