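# Tabular I/O. Dialect: tab-separated, UTF-8, "." decimal, no quoting,
# mandatory header row. Gene identifiers are opaque strings.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
}

write_matrix_tsv <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "")
}

#' Read a gene x sample count matrix (TSV or GCT 1.2)
#'
#' TSV: first column holds gene identifiers, remaining columns are
#' samples. GCT 1.2: two header lines (`#1.2`, then dimensions), `Name`
#' and `Description` columns followed by samples; the `Description`
#' column is discarded. Duplicate gene or sample identifiers, ragged
#' rows and non-integer entries are errors.
#'
#' @param path file path; GCT is detected by a leading `#1.2` line (or a
#'   `.gct` extension).
#' @return Integer gene x sample matrix with dimnames.
#' @export
read_counts <- function(path) {
  mat <- read_gene_matrix(path)
  nonint <- is.finite(mat) & mat != round(mat)
  if (any(nonint)) {
    idx <- which(nonint, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(mat)[idx[1]], colnames(mat)[idx[2]]))
  }
  if (any(!is.finite(mat))) stop("counts must be finite")
  if (any(mat < 0)) stop("counts must be nonnegative")
  storage.mode(mat) <- "integer"
  mat
}

#' Read a gene x sample log2 copy-number table
#'
#' Accepts the same TSV layout as [read_counts()], in the GISTIC-style
#' "byGene" dialect: the first column holds gene identifiers and any
#' further non-numeric leading columns (symbol, locus id, cytoband) are
#' tolerated, recorded, and dropped from the matrix. `NA` cells are kept
#' as missing and flagged downstream by [encode_copy_number()].
#'
#' @param path file path.
#' @return Numeric gene x sample matrix of log2 ratios; annotation
#'   columns, if any, are attached as the `annotations` attribute.
#' @export
read_copy_number <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stop("copy-number table needs a gene column plus samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier: ", genes[duplicated(genes)][1])
  }
  rest <- df[-1]
  is_ann <- vapply(rest, function(col) {
    suppressWarnings(all(is.na(as.numeric(col[!is.na(col)])) &
                           nzchar(as.character(col[!is.na(col)]))))
  }, TRUE)
  # leading annotation block only: stop at the first numeric column
  first_num <- which(!is_ann)[1]
  if (is.na(first_num)) stop("no numeric sample columns found")
  ann_cols <- seq_len(ncol(rest)) < first_num
  ann <- if (any(ann_cols)) {
    cbind(data.frame(gene = genes, stringsAsFactors = FALSE),
          rest[ann_cols])
  }
  num <- rest[!ann_cols]
  if (anyDuplicated(names(num))) {
    stop("duplicate sample identifier: ", names(num)[duplicated(names(num))][1])
  }
  mat <- as.matrix(as.data.frame(lapply(num, as.numeric)))
  dimnames(mat) <- list(genes, names(num))
  if (!is.null(ann)) attr(mat, "annotations") <- ann
  mat
}

read_gene_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (identical(first, "#1.2") || grepl("\\.gct$", path, ignore.case = TRUE)) {
    return(read_gct(path))
  }
  df <- read_tsv(path)
  if (ncol(df) < 2) stop("matrix table needs a gene column plus samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier: ", genes[duplicated(genes)][1])
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicate sample identifier: ",
         names(df)[-1][duplicated(names(df)[-1])][1])
  }
  mat <- as.matrix(as.data.frame(lapply(df[-1], function(col) {
    x <- suppressWarnings(as.numeric(col))
    if (any(is.na(x) & !is.na(col))) stop("non-numeric entry in column")
    x
  })))
  dimnames(mat) <- list(genes, names(df)[-1])
  mat
}

read_gct <- function(path) {
  lines <- readLines(path, n = 2)
  if (!identical(lines[1], "#1.2")) stop("unsupported GCT version: ", lines[1])
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  df <- read.delim(path, skip = 2, sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) != dims[1] || ncol(df) - 2L != dims[2]) {
    stop(sprintf("GCT dimensions (%d x %d) do not match body (%d x %d)",
                 dims[1], dims[2], nrow(df), ncol(df) - 2L))
  }
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier: ", genes[duplicated(genes)][1])
  }
  mat <- as.matrix(df[-(1:2)])            # Description column discarded
  dimnames(mat) <- list(genes, names(df)[-(1:2)])
  mat
}

#' Read sample metadata
#'
#' TSV with at least `sample_id` and `tissue`; optional `purity` and
#' `wgd_flag`. For tumor cohorts a missing purity column defaults to 1
#' (cell-line behavior) with a prominent warning.
#'
#' @param path file path.
#' @param cohort_kind `"cellline"` or `"tumor"`.
#' @return Data frame of sample metadata.
#' @export
read_sample_info <- function(path, cohort_kind = c("cellline", "tumor")) {
  cohort_kind <- match.arg(cohort_kind)
  df <- read_tsv(path)
  need <- c("sample_id", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (cohort_kind == "tumor" && is.null(df$purity)) {
    warning("tumor metadata has no purity column: defaulting purity to 1 ",
            "for all samples (treated as cell lines)", call. = FALSE)
    df$purity <- 1
  }
  if (cohort_kind == "cellline" && is.null(df$purity)) df$purity <- 1
  df
}

#' Read an ORF screen table
#'
#' TSV with `screen`, `tissue`, `barcode`, `gene`, then either an `lfc`
#' column (precomputed log2 fold changes) or `early_count` and
#' `late_count` columns, from which lfc is computed per screen by
#' [compute_barcode_lfc()].
#'
#' @param path file path.
#' @param pseudocount passed to [compute_barcode_lfc()] for count input.
#' @return Data frame with `screen`, `tissue`, `barcode`, `gene`, `lfc`.
#' @export
read_orf_screens <- function(path, pseudocount = 0.5) {
  df <- read_tsv(path)
  need <- c("screen", "tissue", "barcode", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ORF table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"lfc" %in% names(df)) {
    if (!all(c("early_count", "late_count") %in% names(df))) {
      stop("ORF table needs either an lfc column or early_count/late_count")
    }
    df$lfc <- NA_real_
    for (s in unique(df$screen)) {
      idx <- df$screen == s
      df$lfc[idx] <- compute_barcode_lfc(df$early_count[idx],
                                         df$late_count[idx], pseudocount)
    }
  }
  dup <- duplicated(df[c("screen", "barcode")])
  if (any(dup)) stop("duplicate (screen, barcode) pair: ",
                     df$barcode[dup][1], " in ", df$screen[dup][1])
  df[c("screen", "tissue", "barcode", "gene", "lfc")]
}

#' Pipeline configuration
#'
#' Collects input paths, cohort kinds, the classification thresholds and
#' inference settings for [run_pipeline()]. Threshold defaults are the
#' pipeline's published operating points: 0.15 copy-neutral tolerance,
#' 3/5 minimum amplified samples (cell line / tumor), +/-0.3 score
#' boundary, 30% growth decrease with p < 1e-5 for toxicity, 15% gain
#' frequency for common amplification.
#'
#' @param counts_a,copy_a,meta_a paths for cohort A (cell-line-like).
#' @param counts_b,copy_b,meta_b paths for cohort B (tumor-like);
#'   optional — without cohort B, classification uses cohort A on both
#'   sides.
#' @param orf path to the ORF screen table.
#' @param complexes optional path to a complex-membership TSV
#'   (`complex_id`, `gene`).
#' @param cohort_kind_a,cohort_kind_b `"cellline"` / `"tumor"`.
#' @param neutral_tolerance,amp_min_cellline,amp_min_tumor,score_threshold,toxic_growth_decrease,toxic_p,amp_frequency
#'   classification thresholds.
#' @param chains,iter,warmup,seed inference settings.
#' @param pseudocount ORF count pseudocount.
#' @param center_screens per-screen median centering of lfc.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_a, copy_a, meta_a,
                            counts_b = NULL, copy_b = NULL, meta_b = NULL,
                            orf = NULL, complexes = NULL,
                            cohort_kind_a = "cellline",
                            cohort_kind_b = "tumor",
                            neutral_tolerance = 0.15,
                            amp_min_cellline = 3L, amp_min_tumor = 5L,
                            score_threshold = 0.3,
                            toxic_growth_decrease = 0.30, toxic_p = 1e-5,
                            amp_frequency = 0.15,
                            chains = 4L, iter = 1000L, warmup = 500L,
                            seed = 1L, pseudocount = 0.5,
                            center_screens = FALSE) {
  stopifnot(neutral_tolerance > 0, neutral_tolerance < 1,
            score_threshold > 0, toxic_growth_decrease > 0,
            toxic_growth_decrease < 1, toxic_p > 0, toxic_p < 1,
            amp_frequency >= 0, amp_frequency < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [pipeline_config()]; relative input paths are resolved against the
#' YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("counts_a", "copy_a", "meta_a", "counts_b", "copy_b",
                 "meta_b", "orf", "complexes")
  for (k in intersect(path_keys, names(raw))) {
    if (!is.null(raw[[k]]) && !file.exists(raw[[k]])) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  do.call(pipeline_config, raw)
}

#' Run the full ARGOS discovery pipeline
#'
#' Reads the configured inputs, fits compensation scores in each cohort,
#' fits ORF toxicity, classifies compensated / hyperactivated / toxic /
#' frequently amplified genes, calls ARGOS genes, ranks complexes if a
#' membership table is configured, and writes `compensation.tsv`,
#' `toxicity.tsv`, `argos.tsv`, `complexes.tsv` and `run_manifest.json`
#' to `out_dir`. Deterministic given config + seed.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param out_dir output directory.
#' @return Invisibly, a list of the result tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fit_cohort <- function(counts_path, copy_path, meta_path, kind, label) {
    counts <- read_counts(counts_path)
    cn <- read_copy_number(copy_path)
    meta <- read_sample_info(meta_path, kind)
    samples <- intersect(colnames(counts), intersect(colnames(cn),
                                                     meta$sample_id))
    genes <- intersect(rownames(counts), rownames(cn))
    if (!length(samples) || !length(genes)) {
      stop("cohort ", label, ": no shared samples/genes across inputs")
    }
    counts <- counts[genes, samples, drop = FALSE]
    design <- encode_copy_number(cn[genes, samples, drop = FALSE])
    meta <- meta[match(samples, meta$sample_id), ]
    amp_min <- if (kind == "cellline") config$amp_min_cellline else
      config$amp_min_tumor
    res <- fit_compensation(counts, design, meta, cohort_kind = kind,
                            chains = config$chains, iter = config$iter,
                            warmup = config$warmup, seed = config$seed,
                            neutral_tolerance = config$neutral_tolerance,
                            amp_min = amp_min,
                            frequency_threshold = config$amp_frequency)
    res$cohort <- label
    res
  }

  comp_a <- fit_cohort(config$counts_a, config$copy_a, config$meta_a,
                       config$cohort_kind_a, "A")
  comp_b <- if (!is.null(config$counts_b)) {
    fit_cohort(config$counts_b, config$copy_b, config$meta_b,
               config$cohort_kind_b, "B")
  } else {
    comp_a
  }
  compensation <- rbind(comp_a,
                        if (!is.null(config$counts_b)) comp_b)
  write_tsv(compensation, file.path(out_dir, "compensation.tsv"))

  classes <- classify_compensation(
    comp_a[!is.na(comp_a$score), c("gene", "score")],
    comp_b[!is.na(comp_b$score), c("gene", "score")],
    threshold = config$score_threshold
  )

  toxicity <- NULL
  if (!is.null(config$orf)) {
    orf <- read_orf_screens(config$orf, config$pseudocount)
    toxicity <- fit_toxicity(orf, scope = "pan",
                             center_screens = config$center_screens,
                             growth_decrease = config$toxic_growth_decrease,
                             p_threshold = config$toxic_p)
    write_tsv(toxicity, file.path(out_dir, "toxicity.tsv"))
  }

  amp_flags <- unique(comp_a[c("gene", "frequently_amplified")])
  argos <- NULL
  if (!is.null(toxicity)) {
    argos <- call_argos(classes, toxicity, amp_flags)
    argos$score_a <- classes$score_a[match(argos$gene, classes$gene)]
    argos$score_b <- classes$score_b[match(argos$gene, classes$gene)]
    argos$toxicity_estimate <-
      toxicity$estimate[match(argos$gene, toxicity$gene)]
    write_tsv(argos, file.path(out_dir, "argos.tsv"))
  }

  complexes <- NULL
  if (!is.null(config$complexes) && !is.null(argos)) {
    membership <- read_tsv(config$complexes)
    complexes <- rank_complexes(
      membership,
      compensated_set = argos$gene[argos$compensated],
      universe = argos$gene,
      toxicity_estimates = setNames(argos$toxicity_estimate, argos$gene)
    )
    write_tsv(complexes, file.path(out_dir, "complexes.tsv"))
  }

  manifest <- list(
    seed = config$seed,
    thresholds = config[c("neutral_tolerance", "amp_min_cellline",
                          "amp_min_tumor", "score_threshold",
                          "toxic_growth_decrease", "toxic_p",
                          "amp_frequency")],
    inference = config[c("chains", "iter", "warmup")],
    attrition = list(
      cohort_a_genes = nrow(comp_a),
      cohort_a_eligible = sum(!is.na(comp_a$score)),
      cohort_b_genes = nrow(comp_b),
      cohort_b_eligible = sum(!is.na(comp_b$score)),
      classified_both = sum(classes$status != "single-cohort"),
      universe = if (!is.null(argos)) nrow(argos) else NA
    ),
    package_version = as.character(utils::packageVersion("argos"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(compensation = compensation, classification = classes,
                 toxicity = toxicity, argos = argos, complexes = complexes,
                 manifest = manifest))
}
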