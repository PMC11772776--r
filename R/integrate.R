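#' Combine compensation and toxicity calls into ARGOS classifications
#'
#' ARGOS (amplification-related gain of sensitivity) genes are genes that
#' are compensated under copy-number gain and toxic when overexpressed:
#' `argos = compensated AND toxic`. Frequent amplification is annotated
#' alongside but not required for the flag. The gene universe is the
#' intersection of the compensation and toxicity tables; attrition counts
#' are attached as attributes.
#'
#' @param compensation data frame from [classify_compensation()] (columns
#'   `gene`, `compensated`, `hyperactivated`).
#' @param toxicity data frame with `gene` and `toxic` (e.g. from
#'   [fit_toxicity()]).
#' @param amp_flags optional data frame with `gene` and
#'   `frequently_amplified`.
#' @return Data frame with `gene`, `compensated`, `hyperactivated`,
#'   `toxic`, `frequently_amplified`, `argos`; attribute `attrition`
#'   records the universe sizes.
#' @export
call_argos <- function(compensation, toxicity, amp_flags = NULL) {
  genes <- intersect(compensation$gene, toxicity$gene)
  if (!length(genes)) stop("compensation and toxicity tables share no genes")
  comp <- compensation[match(genes, compensation$gene), ]
  tox <- toxicity[match(genes, toxicity$gene), ]
  fa <- if (!is.null(amp_flags)) {
    amp_flags$frequently_amplified[match(genes, amp_flags$gene)]
  } else {
    rep(NA, length(genes))
  }
  out <- data.frame(
    gene = genes,
    compensated = comp$compensated %in% TRUE,
    hyperactivated = comp$hyperactivated %in% TRUE,
    toxic = tox$toxic %in% TRUE,
    frequently_amplified = fa,
    stringsAsFactors = FALSE
  )
  out$argos <- out$compensated & out$toxic
  attr(out, "attrition") <- c(
    n_compensation = nrow(compensation), n_toxicity = nrow(toxicity),
    n_universe = length(genes)
  )
  out
}

#' Compensation enrichment of a protein complex
#'
#' One-sided Fisher's exact test for over-representation of compensated
#' genes among a complex's members, over the tested gene universe. The
#' 2x2 table crosses membership with compensation; members outside the
#' universe are dropped with a warning.
#'
#' @param members character vector of the complex's gene ids.
#' @param compensated_set character vector of compensated gene ids.
#' @param universe character vector: all tested genes.
#' @return Data frame (one row) with the 2x2 counts, `odds_ratio` and
#'   `fisher_p`, or `NULL` if the complex is empty after intersection.
#' @export
complex_enrichment <- function(members, compensated_set, universe) {
  outside <- setdiff(members, universe)
  if (length(outside)) {
    warning(length(outside), " complex member(s) outside the tested universe dropped",
            call. = FALSE)
  }
  members <- intersect(members, universe)
  if (!length(members)) return(NULL)
  compensated_set <- intersect(compensated_set, universe)
  in_comp <- sum(members %in% compensated_set)
  in_not <- length(members) - in_comp
  out_comp <- length(compensated_set) - in_comp
  out_not <- length(universe) - length(members) - out_comp
  tab <- matrix(c(in_comp, in_not, out_comp, out_not), 2, 2)
  ft <- fisher.test(tab, alternative = "greater")
  data.frame(
    n_member_compensated = in_comp, n_member_other = in_not,
    n_nonmember_compensated = out_comp, n_nonmember_other = out_not,
    odds_ratio = unname(ft$estimate), fisher_p = ft$p.value
  )
}

#' Toxicity contrast of a complex's members
#'
#' Applies the gene-set contrast ([gene_set_difference()]) to per-gene ORF
#' depletion values (lfc estimates or Wald statistics) and returns the
#' signed Wald statistic: negative values mean the complex's members drop
#' out more than the background.
#'
#' @param members character vector of member gene ids.
#' @param estimates named numeric vector of per-gene toxicity values.
#' @return Scalar Wald statistic (`NA` if degenerate).
#' @export
complex_toxicity <- function(members, estimates) {
  in_set <- names(estimates) %in% members
  if (!any(in_set)) return(NA_real_)
  gene_set_difference(unname(estimates), in_set)$wald
}

#' Test and rank protein complexes
#'
#' Runs [complex_enrichment()] and [complex_toxicity()] for every complex,
#' corrects the Fisher p-values by Benjamini-Hochberg, and orders
#' complexes by ascending q-value with ties broken by more negative
#' toxicity (stronger member dropout first).
#'
#' @param complex_members data frame with columns `complex_id`, `gene`
#'   (one row per membership).
#' @param compensated_set character vector of compensated genes.
#' @param universe character vector of all tested genes.
#' @param toxicity_estimates named numeric vector of per-gene toxicity
#'   values (optional; `toxicity_wald` is `NA` without it).
#' @return Ranked data frame: `complex_id`, `n_members`, 2x2 counts,
#'   `odds_ratio`, `fisher_p`, `toxicity_wald`, `fdr_q`.
#' @export
rank_complexes <- function(complex_members, compensated_set, universe,
                           toxicity_estimates = NULL) {
  ids <- unique(complex_members$complex_id)
  rows <- lapply(ids, function(id) {
    members <- complex_members$gene[complex_members$complex_id == id]
    enr <- suppressWarnings(
      complex_enrichment(members, compensated_set, universe)
    )
    if (is.null(enr)) return(NULL)
    tox <- if (!is.null(toxicity_estimates)) {
      complex_toxicity(members, toxicity_estimates)
    } else NA_real_
    cbind(data.frame(complex_id = id,
                     n_members = length(intersect(members, universe)),
                     stringsAsFactors = FALSE),
          enr, toxicity_wald = tox)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no complex overlaps the tested universe")
  out <- do.call(rbind, rows)
  out$fdr_q <- p.adjust(out$fisher_p, method = "BH")
  ord <- order(out$fdr_q, out$toxicity_wald, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
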