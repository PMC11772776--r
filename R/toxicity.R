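#' Barcode log2 fold changes from early/late screen counts
#'
#' Computes per-barcode log2 fold changes between the late and early time
#' points of a pooled ORF overexpression screen, normalizing each time
#' point by its total read count:
#' \deqn{lfc = \log_2\frac{(late + q)/N_{late}}{(early + q)/N_{early}}}
#' with pseudocount `q` (default 0.5). With the pseudocount disabled
#' (`q = 0`), barcodes absent at the early time point are excluded.
#'
#' @param early_counts,late_counts nonnegative integer read counts per
#'   barcode at the two time points.
#' @param pseudocount added to both counts before the ratio (default 0.5).
#' @return Numeric vector of log2 fold changes (`NA` for excluded
#'   barcodes when `pseudocount = 0`).
#' @export
compute_barcode_lfc <- function(early_counts, late_counts, pseudocount = 0.5) {
  stopifnot(length(early_counts) == length(late_counts),
            all(early_counts >= 0), all(late_counts >= 0), pseudocount >= 0)
  n_early <- sum(early_counts)
  n_late <- sum(late_counts)
  if (n_early <= 0 || n_late <= 0) stop("zero total reads at a time point")
  lfc <- log2((late_counts + pseudocount) / n_late) -
    log2((early_counts + pseudocount) / n_early)
  if (pseudocount == 0) {
    drop <- early_counts == 0
    if (any(drop)) {
      message(sum(drop), " barcode(s) absent at the early time point excluded")
      lfc[drop] <- NA_real_
    }
  }
  lfc
}

#' Per-gene overexpression toxicity from pooled barcode observations
#'
#' Estimates a gene's depletion on overexpression by an intercept-only
#' least-squares fit over its barcode log2 fold changes, treating each
#' barcode measurement in any screen as an independent observation. The
#' estimate is the pooled mean lfc; significance is a two-sided Wald
#' t-test of the intercept (equivalently, a one-sample t-test). Scope is
#' either pan-cancer (all screens) or tissue-specific (screens sharing a
#' cancer type).
#'
#' @param observations data frame with columns `screen`, `tissue`,
#'   `barcode`, `gene`, `lfc` (one gene's rows, or more — filtered by
#'   `gene`).
#' @param gene gene identifier to fit (default: the single gene present).
#' @param scope `"pan"` or a tissue label for tissue-specific analysis.
#' @param center_screens median-center lfc within each screen before
#'   pooling (off by default).
#' @return Data frame (one row) with `gene`, `scope`, `estimate`, `se`,
#'   `wald`, `p`, `n_obs`. With fewer than 2 observations `p` is `NA` and
#'   the gene is never classified toxic.
#' @export
fit_gene_toxicity <- function(observations, gene = NULL, scope = "pan",
                              center_screens = FALSE) {
  if (is.null(gene)) {
    gene <- unique(observations$gene)
    if (length(gene) != 1) stop("specify `gene` when observations cover several")
  }
  obs <- observations[observations$gene == gene, , drop = FALSE]
  if (!identical(scope, "pan")) {
    obs <- obs[obs$tissue %in% scope, , drop = FALSE]
  }
  if (center_screens && nrow(obs)) {
    med <- tapply(obs$lfc, obs$screen, median)
    obs$lfc <- obs$lfc - med[as.character(obs$screen)]
  }
  lfc <- obs$lfc[is.finite(obs$lfc)]
  n <- length(lfc)
  scope_label <- if (identical(scope, "pan")) "pan-cancer" else
    paste0("tissue:", paste(scope, collapse = "+"))
  if (n < 2) {
    return(data.frame(gene = gene, scope = scope_label,
                      estimate = if (n) mean(lfc) else NA_real_,
                      se = NA_real_, wald = NA_real_, p = NA_real_,
                      n_obs = n, stringsAsFactors = FALSE))
  }
  est <- mean(lfc)
  se <- sd(lfc) / sqrt(n)
  if (se == 0) {
    return(data.frame(gene = gene, scope = scope_label, estimate = est,
                      se = 0, wald = NA_real_, p = NA_real_, n_obs = n,
                      stringsAsFactors = FALSE))
  }
  wald <- est / se
  p <- 2 * pt(-abs(wald), df = n - 1)
  data.frame(gene = gene, scope = scope_label, estimate = est, se = se,
             wald = wald, p = p, n_obs = n, stringsAsFactors = FALSE)
}

#' Classify a gene as toxic on overexpression
#'
#' A gene is toxic when its overexpression is associated with at least a
#' `growth_decrease` (default 30%) reduction in growth — i.e. its mean
#' barcode log2 fold change is at most \eqn{\log_2(1 - 0.30) \approx
#' -0.515} — with Wald p-value below `p_threshold` (default 1e-5).
#' Barcode abundance is the growth proxy, so the lfc scale carries the
#' growth effect. Fits with undefined p are never classified toxic.
#'
#' @param fit one-row data frame from [fit_gene_toxicity()] (or several
#'   rows, classified element-wise).
#' @param growth_decrease minimum fractional growth decrease (default
#'   0.30).
#' @param p_threshold strict p-value bound (default 1e-5).
#' @return Logical vector.
#' @export
classify_toxic <- function(fit, growth_decrease = 0.30, p_threshold = 1e-5) {
  lfc_bound <- log2(1 - growth_decrease)
  ok <- !is.na(fit$p)
  ok & fit$estimate <= lfc_bound & fit$p < p_threshold
}

#' Fit toxicity for every gene in an ORF screen table
#'
#' @inheritParams fit_gene_toxicity
#' @inheritParams classify_toxic
#' @return Data frame with one row per gene (columns as
#'   [fit_gene_toxicity()] plus `toxic`).
#' @export
fit_toxicity <- function(observations, scope = "pan", center_screens = FALSE,
                         growth_decrease = 0.30, p_threshold = 1e-5) {
  genes <- unique(observations$gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    fit_gene_toxicity(observations, gene = g, scope = scope,
                      center_screens = center_screens)
  }))
  out$toxic <- classify_toxic(out, growth_decrease, p_threshold)
  out
}
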