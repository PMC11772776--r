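#' Median-of-ratios size factors from raw counts
#'
#' Computes per-sample library size factors with the median-of-ratios
#' estimator: each sample's factor is the median, over genes expressed in
#' every sample, of the ratio of the sample's count to the gene's geometric
#' mean across samples. Factors are rescaled so their geometric mean is 1,
#' which fixes the overall scale without changing relative library sizes.
#'
#' @param counts gene x sample matrix of raw nonnegative integer counts
#'   (genes in rows).
#' @return Named numeric vector of positive size factors, one per sample,
#'   with geometric mean 1.
#' @examples
#' counts <- rbind(g1 = c(2, 4), g2 = c(4, 8), g3 = c(6, 12))
#' compute_size_factors(counts)
#' @export
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and nonnegative")
  }
  if (ncol(counts) == 1L) {
    return(setNames(1, colnames(counts)))
  }
  expressed <- rowSums(counts > 0) == ncol(counts)
  if (!any(expressed)) {
    stop("no gene has nonzero counts in all samples; size factors undefined")
  }
  logc <- log(counts[expressed, , drop = FALSE])
  ref <- rowMeans(logc)                       # log geometric mean per gene
  sf <- apply(logc, 2, function(x) exp(median(x - ref)))
  sf <- sf / exp(mean(log(sf)))               # geometric mean 1
  sf
}

#' Encode log2 copy-number ratios as euploid equivalents and deviation
#'
#' Transforms a gene x sample table of log2 copy-number ratios into linear
#' space and parameterizes it as euploid equivalents \eqn{c = 2^{log2}} and
#' euploid deviation \eqn{d = c - 1}. \eqn{c} carries the part of expression
#' that scales with DNA dosage (1 at the sample's baseline ploidy, 0 with no
#' copies present); \eqn{d} carries the departure from that slope (0 at
#' baseline, -1 with no copies, +1 at twice the base copies). By
#' construction \eqn{c - d = 1} for every entry.
#'
#' @param log2_table gene x sample matrix (or data frame) of log2
#'   copy-number ratios; `NA`/`NaN` entries are flagged missing and excluded
#'   downstream. `-Inf` is accepted as the zero-copy sentinel.
#' @return Object of class `copy_number_design`: a list with matrices
#'   `linear_ratio`, `c`, `d` and logical `missing`, all gene x sample.
#' @examples
#' enc <- encode_copy_number(rbind(GENE1 = c(s1 = 0, s2 = 1)))
#' enc$d  # 0 at baseline, +1 at twice the base copies
#' @export
encode_copy_number <- function(log2_table) {
  x <- as.matrix(log2_table)
  missing <- is.na(x)
  linear <- 2^x
  linear[missing] <- NA_real_
  if (any(linear[!missing] < 0)) stop("linear copy ratios must be nonnegative")
  out <- list(
    linear_ratio = linear,
    c = linear,
    d = linear - 1,
    missing = missing
  )
  class(out) <- "copy_number_design"
  out
}

#' @export
print.copy_number_design <- function(x, ...) {
  cat(sprintf("copy_number_design: %d genes x %d samples (%d missing entries)\n",
              nrow(x$c), ncol(x$c), sum(x$missing)))
  invisible(x)
}

#' Sample inclusion and gene eligibility for the compensation fit
#'
#' A sample enters a gene's compensation fit only if it is copy-neutral
#' (\eqn{|c - 1| \le} `neutral_tolerance`) or carries a one-copy gain
#' (\eqn{c \ge 2 -} `neutral_tolerance`). A gene is eligible when it has at
#' least `amp_min` amplified samples, by default 3 for cell-line cohorts and
#' 5 for tumor cohorts. Samples at intermediate or reduced copy number are
#' excluded from the fit.
#'
#' @param c_row numeric vector of euploid equivalents for one gene across
#'   samples (`NA` allowed; treated as excluded).
#' @param cohort_kind `"cellline"` or `"tumor"`.
#' @param neutral_tolerance absolute tolerance on the linear copy scale
#'   (default 0.15).
#' @param amp_min minimum number of amplified samples for eligibility;
#'   default 3 (cellline) / 5 (tumor).
#' @return List with logical vectors `include`, `neutral`, `amplified`,
#'   counts `n_neutral`, `n_amplified`, and logical `eligible`.
#' @export
select_samples_for_gene <- function(c_row,
                                    cohort_kind = c("cellline", "tumor"),
                                    neutral_tolerance = 0.15,
                                    amp_min = NULL) {
  cohort_kind <- match.arg(cohort_kind)
  if (is.null(amp_min)) amp_min <- if (cohort_kind == "cellline") 3L else 5L
  ok <- !is.na(c_row)
  eps <- 1e-9   # absorb floating-point error at the tolerance boundary
  neutral <- ok & abs(c_row - 1) <= neutral_tolerance + eps
  amplified <- ok & c_row >= 2 - neutral_tolerance - eps
  list(
    include = neutral | amplified,
    neutral = neutral,
    amplified = amplified,
    n_neutral = sum(neutral),
    n_amplified = sum(amplified),
    eligible = sum(amplified) >= amp_min
  )
}

#' Flag commonly amplified genes by gain frequency
#'
#' A gene is commonly (frequently) amplified when it is gained in strictly
#' more than `frequency_threshold` of cohort samples (default 15%). Gain
#' calls can be supplied externally (e.g. GISTIC-style thresholded calls);
#' otherwise the design's amplified rule (\eqn{c \ge 1.85}) is applied.
#'
#' @param design `copy_number_design` from [encode_copy_number()].
#' @param gain_calls optional gene x sample logical matrix of external gain
#'   calls, overriding the in-house rule.
#' @param frequency_threshold strict lower bound on the gained fraction
#'   (default 0.15).
#' @param neutral_tolerance tolerance used by the in-house gain rule.
#' @return Data frame with `gene`, `amp_frequency`, `frequently_amplified`.
#' @export
classify_frequently_amplified <- function(design, gain_calls = NULL,
                                          frequency_threshold = 0.15,
                                          neutral_tolerance = 0.15) {
  if (is.null(gain_calls)) {
    stopifnot(inherits(design, "copy_number_design"))
    gain_calls <- !design$missing & design$c >= 2 - neutral_tolerance
  }
  gain_calls <- as.matrix(gain_calls)
  freq <- rowMeans(gain_calls, na.rm = TRUE)
  data.frame(
    gene = rownames(gain_calls) %||% as.character(seq_len(nrow(gain_calls))),
    amp_frequency = unname(freq),
    frequently_amplified = unname(freq > frequency_threshold),
    stringsAsFactors = FALSE
  )
}

#' Mean size-factor-normalized expression of a gene
#'
#' Computes \eqn{m}, the mean over included samples of count divided by size
#' factor. \eqn{m} rescales the regression so its coefficients are
#' comparable across genes regardless of expression level and library size.
#'
#' @param counts_row integer counts for one gene across samples.
#' @param size_factors per-sample positive size factors.
#' @param include logical inclusion mask (default all).
#' @return Positive scalar `m`. Errors if no sample is included or `m` is 0
#'   (the regression is undefined for an unexpressed gene).
#' @export
compute_gene_mean <- function(counts_row, size_factors,
                              include = rep(TRUE, length(counts_row))) {
  if (!any(include)) stop("no samples included; gene mean undefined")
  m <- mean(counts_row[include] / size_factors[include])
  if (m <= 0) stop("gene mean is zero over included samples; model undefined")
  m
}

#' Per-gene preprocessing summary
#'
#' Applies sample selection, eligibility, gain-frequency classification and
#' the gene mean to every gene in a cohort, producing the model-ready
#' summary consumed by the compensation fits.
#'
#' @param counts gene x sample count matrix.
#' @param design `copy_number_design` with matching dimensions.
#' @param cohort_kind `"cellline"` or `"tumor"`.
#' @param size_factors optional precomputed size factors.
#' @inheritParams select_samples_for_gene
#' @inheritParams classify_frequently_amplified
#' @return List with `summary` (data frame: gene, m, n_neutral, n_amplified,
#'   amp_frequency, eligible, frequently_amplified), `include` (gene x
#'   sample logical), and `size_factors`.
#' @export
summarize_genes <- function(counts, design,
                            cohort_kind = c("cellline", "tumor"),
                            size_factors = NULL,
                            neutral_tolerance = 0.15, amp_min = NULL,
                            frequency_threshold = 0.15) {
  cohort_kind <- match.arg(cohort_kind)
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == dim(design$c)))
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  amp <- classify_frequently_amplified(design,
                                       frequency_threshold = frequency_threshold,
                                       neutral_tolerance = neutral_tolerance)
  genes <- rownames(counts)
  include <- matrix(FALSE, nrow(counts), ncol(counts),
                    dimnames = dimnames(counts))
  res <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    sel <- select_samples_for_gene(design$c[i, ], cohort_kind,
                                   neutral_tolerance, amp_min)
    include[i, ] <- sel$include
    m <- if (any(sel$include)) {
      mi <- mean(counts[i, sel$include] / size_factors[sel$include])
      if (mi > 0) mi else NA_real_
    } else NA_real_
    res[[i]] <- data.frame(
      gene = genes[i], m = m,
      n_neutral = sel$n_neutral, n_amplified = sel$n_amplified,
      eligible = sel$eligible && is.finite(m),
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, res)
  summary$amp_frequency <- amp$amp_frequency[match(summary$gene, amp$gene)]
  summary$frequently_amplified <-
    amp$frequently_amplified[match(summary$gene, amp$gene)]
  list(summary = summary, include = include, size_factors = size_factors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
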