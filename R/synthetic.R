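#' Simulation configuration for synthetic cohorts and screens
#'
#' Bundles the cohort-shape parameters the generator needs. Defaults
#' emulate a TCGA/CCLE-like setting: tumor purity drawn from Beta(6, 3)
#' (mean about 0.67), log-normal library-size spread of about 20%, and a
#' small panel of screens with a handful of barcodes per gene.
#'
#' @param n_tissues number of tissues (>= 1); labels are `tissue_1`, ...
#' @param samples_per_tissue samples per tissue (>= 1).
#' @param cohort_kind `"cellline"` (purity 1, no non-cancer compartment)
#'   or `"tumor"`.
#' @param purity_shape1,purity_shape2 Beta parameters for tumor purity.
#' @param purity_fixed optional scalar in (0, 1]: use this purity for all
#'   tumor samples instead of drawing (no RNG consumed).
#' @param library_sdlog log-normal sd of true library factors (meanlog is
#'   set so the factors have geometric mean 1).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of config + truth.
#' @param n_screens,barcodes_per_gene,lfc_noise_sd ORF-screen shape:
#'   number of screens, barcodes per gene per screen, and the sd of the
#'   per-barcode log2-fold-change noise.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tissues = 1, samples_per_tissue = 200,
                              cohort_kind = c("cellline", "tumor"),
                              purity_shape1 = 6, purity_shape2 = 3,
                              purity_fixed = NULL,
                              library_sdlog = 0.2, seed = 1L,
                              n_screens = 3, barcodes_per_gene = 2,
                              lfc_noise_sd = 0.1) {
  cohort_kind <- match.arg(cohort_kind)
  stopifnot(n_tissues >= 1, samples_per_tissue >= 1, n_screens >= 1,
            barcodes_per_gene >= 1, lfc_noise_sd >= 0, library_sdlog >= 0,
            purity_shape1 > 0, purity_shape2 > 0)
  if (!is.null(purity_fixed)) {
    stopifnot(purity_fixed > 0, purity_fixed <= 1)
  }
  structure(list(
    n_tissues = as.integer(n_tissues),
    samples_per_tissue = as.integer(samples_per_tissue),
    cohort_kind = cohort_kind,
    purity_shape1 = purity_shape1, purity_shape2 = purity_shape2,
    purity_fixed = purity_fixed,
    library_sdlog = library_sdlog, seed = as.integer(seed),
    n_screens = as.integer(n_screens),
    barcodes_per_gene = as.integer(barcodes_per_gene),
    lfc_noise_sd = lfc_noise_sd
  ), class = "simulation_config")
}

#' Construct a ground-truth gene parameter table
#'
#' One row per gene. `true_score` is the generative analogue of the
#' normalized deviation coefficient: -1 means full compensation (expected
#' expression unchanged by gain), 0 pure dosage scaling, +1 full
#' hyperactivation (each gained copy adds twice the per-copy euploid
#' increment). Per-tissue baselines can be given as columns named
#' `base_mean.<tissue>` instead of the shared `base_mean`.
#'
#' @param gene_id character vector of gene identifiers.
#' @param base_mean expected size-normalized counts at the euploid state.
#' @param true_score real in \[-2, 2\].
#' @param amp_fraction fraction of samples per tissue carrying the gain.
#' @param amp_copies gained linear copy ratio (2 = one extra copy).
#' @param nb_shape NB shape of the observation noise.
#' @param normal_mean non-cancer compartment expression (tumor cohorts);
#'   defaults to `base_mean`.
#' @param true_toxicity_lfc generative mean barcode log2 fold change.
#' @return Data frame of class `true_gene_params`.
#' @export
true_gene_params <- function(gene_id, base_mean = 500, true_score = 0,
                             amp_fraction = 0.25, amp_copies = 2,
                             nb_shape = 20, normal_mean = base_mean,
                             true_toxicity_lfc = 0) {
  stopifnot(all(base_mean > 0), all(nb_shape > 0),
            all(amp_fraction >= 0), all(amp_fraction <= 1),
            all(amp_copies > 0), all(normal_mean >= 0),
            all(abs(true_score) <= 2))
  out <- data.frame(
    gene = as.character(gene_id), base_mean = base_mean,
    true_score = true_score, amp_fraction = amp_fraction,
    amp_copies = amp_copies, nb_shape = nb_shape,
    normal_mean = normal_mean, true_toxicity_lfc = true_toxicity_lfc,
    stringsAsFactors = FALSE
  )
  class(out) <- c("true_gene_params", "data.frame")
  out
}

#' Noiseless expected count of the generator
#'
#' The mean function the synthetic counts are drawn around: with euploid
#' equivalents \eqn{c = 2^{log2}} and deviation \eqn{d = c - 1}, the
#' cancer-cell mean is \eqn{base\,(c + score\,d)}; the observed mean mixes
#' it with the non-cancer compartment by purity and scales by the library
#' factor: \eqn{L\,(p \cdot cancer + (1-p)\,normal)}. No noise enters
#' before the NB draw.
#'
#' @param base_mean,true_score generative gene parameters.
#' @param log2_copy log2 copy ratio of the sample.
#' @param purity tumor purity (1 for cell lines).
#' @param normal_mean non-cancer compartment expression.
#' @param lib library factor.
#' @return Expected count (vectorized).
#' @export
synthetic_mean <- function(base_mean, true_score, log2_copy, purity = 1,
                           normal_mean = 0, lib = 1) {
  cc <- 2^log2_copy
  d <- cc - 1
  cancer <- base_mean * (cc + true_score * d)
  lib * (purity * cancer + (1 - purity) * normal_mean)
}

# per-gene, per-tissue base mean lookup supporting base_mean.<tissue> columns
.base_mean_for <- function(truth_row, tissue) {
  col <- paste0("base_mean.", tissue)
  if (col %in% names(truth_row)) return(truth_row[[col]])
  if (!"base_mean" %in% names(truth_row)) {
    stop("gene ", truth_row$gene, " has no base mean for tissue ", tissue)
  }
  truth_row$base_mean
}

#' Simulate a cell-line-like or tumor-like expression cohort
#'
#' Generates a gene x sample raw count matrix with matching log2
#' copy-number table, sample metadata and ground truth. For each gene a
#' fixed fraction of samples per tissue (rounded down, chosen as the first
#' samples after a seeded shuffle) carries a gain of `amp_copies`; all
#' other samples are copy-neutral. Counts are negative binomial around
#' [synthetic_mean()] with per-gene shape (variance = mu + mu^2/shape).
#' Library factors are log-normal with geometric mean 1; tumor purity is
#' Beta-distributed (or fixed). Everything is a deterministic function of
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param truth a [true_gene_params()] table with one row per gene.
#' @return A `synthetic_cohort` list: `counts`, `log2_copy` (gene x
#'   sample), `sample_info` (`sample_id`, `tissue`, `purity`,
#'   `true_size_factor`), `truth`, `config`.
#' @export
simulate_cohort <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"),
            is.data.frame(truth), nrow(truth) >= 1)
  tissues <- paste0("tissue_", seq_len(config$n_tissues))
  n <- config$n_tissues * config$samples_per_tissue
  sample_tissue <- rep(tissues, each = config$samples_per_tissue)
  sample_id <- sprintf("S%04d", seq_len(n))

  # refuse genes whose amplified-state mean would be negative
  for (i in seq_len(nrow(truth))) {
    cc <- truth$amp_copies[i]
    if (cc != 1) {
      mu_amp <- cc + truth$true_score[i] * (cc - 1)
      if (mu_amp <= 0) {
        stop("gene ", truth$gene[i], ": true_score ", truth$true_score[i],
             " implies a nonpositive amplified-state mean")
      }
    }
  }

  set.seed(config$seed)
  lib <- rlnorm(n, meanlog = 0, sdlog = config$library_sdlog)
  lib <- lib / exp(mean(log(lib)))
  purity <- if (config$cohort_kind == "cellline") {
    rep(1, n)
  } else if (!is.null(config$purity_fixed)) {
    rep(config$purity_fixed, n)
  } else {
    p <- rbeta(n, config$purity_shape1, config$purity_shape2)
    pmax(p, 1e-3)
  }

  g <- nrow(truth)
  counts <- matrix(0L, g, n, dimnames = list(truth$gene, sample_id))
  log2_copy <- matrix(0, g, n, dimnames = list(truth$gene, sample_id))
  tissue_idx <- split(seq_len(n), sample_tissue)

  for (i in seq_len(g)) {
    row <- truth[i, ]
    for (t in tissues) {
      idx <- tissue_idx[[t]]
      n_amp <- floor(row$amp_fraction * length(idx))
      amp <- if (n_amp > 0) sample(idx)[seq_len(n_amp)] else integer(0)
      log2_copy[i, amp] <- log2(row$amp_copies)
      base <- .base_mean_for(row, t)
      mu <- synthetic_mean(base, row$true_score, log2_copy[i, idx],
                           purity = purity[idx],
                           normal_mean = if (config$cohort_kind == "tumor")
                             row$normal_mean else 0,
                           lib = lib[idx])
      counts[i, idx] <- rnbinom(length(idx), mu = mu, size = row$nb_shape)
    }
  }

  storage.mode(counts) <- "integer"
  structure(list(
    counts = counts,
    log2_copy = log2_copy,
    sample_info = data.frame(
      sample_id = sample_id, tissue = sample_tissue, purity = purity,
      true_size_factor = lib, stringsAsFactors = FALSE
    ),
    truth = truth,
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort (%s): %d genes x %d samples, %d tissue(s)\n",
              x$config$cohort_kind, nrow(x$counts), ncol(x$counts),
              x$config$n_tissues))
  invisible(x)
}

#' Simulate pooled ORF overexpression screens
#'
#' Generates one record per gene x barcode x screen with
#' \eqn{lfc \sim N(\mathrm{true\_toxicity\_lfc}, \mathrm{lfc\_noise\_sd})}.
#' Screens are assigned tissue labels cycling through the config's
#' tissues, so tissue-specific analyses have matching screens.
#'
#' @inheritParams simulate_cohort
#' @return Data frame with `screen`, `tissue`, `barcode`, `gene`, `lfc`.
#' @export
simulate_orf_screens <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"), is.data.frame(truth))
  set.seed(config$seed + 1L)
  tissues <- paste0("tissue_", seq_len(config$n_tissues))
  screens <- sprintf("screen_%02d", seq_len(config$n_screens))
  screen_tissue <- tissues[(seq_len(config$n_screens) - 1) %%
                             config$n_tissues + 1]
  grid <- expand.grid(bc = seq_len(config$barcodes_per_gene),
                      gene = truth$gene, screen_i = seq_len(config$n_screens),
                      stringsAsFactors = FALSE)
  mu <- truth$true_toxicity_lfc[match(grid$gene, truth$gene)]
  data.frame(
    screen = screens[grid$screen_i],
    tissue = screen_tissue[grid$screen_i],
    barcode = paste0(grid$gene, "_bc", grid$bc),
    gene = grid$gene,
    lfc = rnorm(nrow(grid), mean = mu, sd = config$lfc_noise_sd),
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic cohort as a pipeline-ready fixture set
#'
#' Emits the exact tabular formats the pipeline readers consume — counts
#' TSV, log2 copy-number TSV, sample metadata TSV, ORF screen TSV, truth
#' TSV — plus a JSON manifest, so a generated cohort can exercise the full
#' file-based pipeline and round-trip losslessly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param screens optional ORF table from [simulate_orf_screens()].
#' @return Invisibly, the manifest list (`files`, `seed`, `cohort_kind`).
#' @export
write_fixture_set <- function(cohort, dir, screens = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(counts = "counts.tsv", copy_number = "copy_number.tsv",
             metadata = "sample_info.tsv", truth = "truth.tsv")
  write_matrix_tsv(cohort$counts, file.path(dir, files["counts"]))
  write_matrix_tsv(cohort$log2_copy, file.path(dir, files["copy_number"]))
  write_tsv(cohort$sample_info, file.path(dir, files["metadata"]))
  write_tsv(cohort$truth, file.path(dir, files["truth"]))
  if (!is.null(screens)) {
    files <- c(files, orf = "orf_screens.tsv")
    write_tsv(screens, file.path(dir, files["orf"]))
  }
  manifest <- list(files = as.list(files), seed = cohort$config$seed,
                   cohort_kind = cohort$config$cohort_kind)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
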