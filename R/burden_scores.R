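#' Tumor mutational burden of one sample
#'
#' TMB is the count of nonsynonymous somatic mutations; the input table is
#' expected to have already passed [apply_quality_filters()] and
#' [select_nonsynonymous()].
#'
#' @param mutations Mutation table restricted to a single sample.
#' @return Integer count.
#' @export
compute_tmb <- function(mutations) {
  if (nrow(mutations) == 0) return(0L)
  if (length(unique(mutations$sample_id)) > 1) {
    stop("compute_tmb expects mutations from a single sample; got ",
         length(unique(mutations$sample_id)))
  }
  nrow(mutations)
}

#' Mutant-allele tumor heterogeneity (MATH)
#'
#' MATH summarises the dispersion of a tumor's variant allele fractions:
#' `100 * 1.4826 * median(|vaf - median(vaf)|) / median(vaf)`, i.e. 100
#' times the consistency-scaled median absolute deviation divided by the
#' median VAF. Wider VAF spread — the signature of subclonal structure —
#' gives larger MATH.
#'
#' MATH is inestimable (returns `NA`) when fewer than `min_mutations` VAFs
#' are available or the median VAF is zero.
#'
#' @param vafs Numeric vector of variant allele fractions in \[0, 1\].
#' @param min_mutations Minimum number of VAFs required (default 5; a
#'   median/MAD on fewer points is not meaningful).
#' @return MATH value, or `NA_real_` when inestimable.
#' @export
compute_math <- function(vafs, min_mutations = 5) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) > 0 && (min(vafs) < 0 || max(vafs) > 1)) {
    stop("vafs must lie in [0, 1]")
  }
  if (length(vafs) < min_mutations) return(NA_real_)
  med <- stats::median(vafs)
  if (med == 0) return(NA_real_)
  100 * stats::mad(vafs, constant = 1.4826) / med
}

#' Benefit score: TMB over MATH
#'
#' The per-tumor benefit score is the ratio of the tumor mutational burden
#' to MATH, with MATH replaced by 1 when it equals zero (a zero-dispersion
#' VAF set) so the ratio stays defined. A high score reflects a high
#' mutational load, low heterogeneity, or both. `NA` MATH (inestimable)
#' propagates to an `NA` score.
#'
#' @param tmb Non-negative mutation count(s).
#' @param math MATH value(s) as from [compute_math()].
#' @return Numeric benefit score(s); vectorised over inputs.
#' @export
compute_benefit_score <- function(tmb, math) {
  if (any(tmb < 0, na.rm = TRUE)) stop("tmb must be non-negative")
  denom <- ifelse(!is.na(math) & math == 0, 1, math)
  ifelse(is.na(math), NA_real_, tmb / denom)
}

#' Clonality call from the CCF lower confidence bound
#'
#' A mutation is clonal when the lower bound of the 95% confidence interval
#' of its cancer cell fraction exceeds 0.95 (strict). This is the rule used
#' with PyClone-style CCF posteriors.
#'
#' @param ccf_lower_ci Numeric vector of lower CCF confidence bounds.
#' @param threshold Clonality threshold on the lower bound (default 0.95).
#' @return Logical vector, `TRUE` = clonal.
#' @export
classify_clonal_ci <- function(ccf_lower_ci, threshold = 0.95) {
  if (any(is.na(ccf_lower_ci))) {
    stop("ccf_lower_ci missing for some mutations; ",
         "use classify_clonal_ccf() for annotations without CI bounds")
  }
  ccf_lower_ci > threshold
}

#' Clonality call from the CCF point estimate and clonality probabilities
#'
#' A mutation is clonal when its cancer cell fraction equals 1 (within
#' `tol`), or when both clonality probabilities are available and the
#' probability of being clonal exceeds the probability of being subclonal.
#' This is the rule used with ABSOLUTE-style annotations.
#'
#' @param ccf Numeric vector of CCF point estimates in \[0, 1\].
#' @param p_clonal,p_subclonal Optional probability vectors (`NA` allowed).
#' @param tol Tolerance for `ccf == 1` (default 1e-9).
#' @return Logical vector, `TRUE` = clonal.
#' @export
classify_clonal_ccf <- function(ccf, p_clonal = NULL, p_subclonal = NULL,
                                tol = 1e-9) {
  if (any(is.na(ccf))) stop("ccf must be present for every mutation")
  n <- length(ccf)
  if (is.null(p_clonal)) p_clonal <- rep(NA_real_, n)
  if (is.null(p_subclonal)) p_subclonal <- rep(NA_real_, n)
  near_one <- abs(ccf - 1) <= tol
  by_prob <- !is.na(p_clonal) & !is.na(p_subclonal) & p_clonal > p_subclonal
  near_one | by_prob
}

#' Clonal TMB of one sample
#'
#' Counts the annotations classified clonal under the chosen rule. The
#' annotation table should already be restricted to the sample's
#' quality-filtered nonsynonymous mutations, so the count is a clonal TMB.
#'
#' @param annotations Data frame with columns `ccf`, and `ccf_lower_ci`
#'   (rule `"ci"`) or `p_clonal`/`p_subclonal` (rule `"ccf"`, optional).
#' @param rule `"ci"` for the lower-confidence-bound rule
#'   ([classify_clonal_ci()]) or `"ccf"` for the point-estimate rule
#'   ([classify_clonal_ccf()]).
#' @return Integer count of clonal mutations.
#' @export
compute_clonal_tmb <- function(annotations, rule = c("ci", "ccf")) {
  rule <- match.arg(rule)
  if (nrow(annotations) == 0) return(0L)
  is_clonal <- switch(rule,
    ci = classify_clonal_ci(annotations$ccf_lower_ci),
    ccf = classify_clonal_ccf(annotations$ccf,
                              annotations$p_clonal,
                              annotations$p_subclonal)
  )
  sum(is_clonal)
}

#' Score every sample of a cohort
#'
#' Applies the quality filters, computes per-sample TMB (on the
#' nonsynonymous subset) and MATH (by default on all quality-filtered VAFs,
#' which is how MATH is conventionally computed from a MAF), and derives
#' the benefit score. Samples whose MATH is inestimable are retained with
#' `valid = FALSE` and `NA` scores so downstream stages can report the
#' exclusion.
#'
#' @param mutations Cohort mutation table ([read_maf()] schema).
#' @param policy A [filter_policy()].
#' @param min_mutations_for_math Minimum VAFs for an estimable MATH.
#' @param math_on `"all"` (default) computes MATH on every quality-filtered
#'   VAF; `"nonsynonymous"` restricts to the nonsynonymous subset.
#' @param tmb_after_quality_filter If `TRUE` (default) TMB counts
#'   quality-filtered mutations; if `FALSE`, all nonsynonymous mutations.
#' @return Data frame with one row per sample: `sample_id`, `tmb`, `math`,
#'   `math_substituted`, `benefit_score`, `n_vafs_used`, `valid`; attribute
#'   `n_excluded` gives the number of invalid samples.
#' @export
score_cohort <- function(mutations, policy = filter_policy(),
                         min_mutations_for_math = 5,
                         math_on = c("all", "nonsynonymous"),
                         tmb_after_quality_filter = TRUE) {
  math_on <- match.arg(math_on)
  samples <- unique(mutations$sample_id)
  if (length(samples) == 0) {
    out <- data.frame(sample_id = character(0), tmb = integer(0),
                      math = numeric(0), math_substituted = logical(0),
                      benefit_score = numeric(0), n_vafs_used = integer(0),
                      valid = logical(0), stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  q <- apply_quality_filters(mutations, policy)
  ns <- select_nonsynonymous(q, policy)
  tmb_src <- if (tmb_after_quality_filter) ns else
    select_nonsynonymous(mutations, policy)
  lev <- factor(tmb_src$sample_id, levels = samples)
  tmb <- as.integer(table(lev))

  vaf_src <- if (math_on == "all") q else ns
  vaf_by_sample <- split(vaf_src$vaf, factor(vaf_src$sample_id,
                                             levels = samples))
  n_vafs <- vapply(vaf_by_sample, length, integer(1))
  math <- vapply(vaf_by_sample, compute_math, numeric(1),
                 min_mutations = min_mutations_for_math)
  valid <- n_vafs >= min_mutations_for_math & !is.na(math)
  math[!valid] <- NA_real_
  out <- data.frame(
    sample_id = samples,
    tmb = tmb,
    math = math,
    math_substituted = valid & math == 0 & !is.na(math),
    benefit_score = compute_benefit_score(tmb, math),
    n_vafs_used = n_vafs,
    valid = valid,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  n_excl <- sum(!valid)
  if (n_excl > 0) {
    message("score_cohort: heterogeneity inestimable for ", n_excl,
            " sample(s); flagged valid = FALSE")
  }
  attr(out, "n_excluded") <- n_excl
  out
}

#' Read per-mutation clonality annotations
#'
#' Expects a tab-separated table with columns `sample_id`, `chromosome`,
#' `position`, `alt_allele`, `ccf`, and optionally `ccf_lower_ci`,
#' `p_clonal`, `p_subclonal`.
#'
#' @param path Path to the TSV.
#' @return Data frame of annotations.
#' @export
read_clonal_annotations <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "chromosome", "position", "alt_allele", "ccf")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    stop("clonality table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(ann$ccf_lower_ci)) {
    bad <- !is.na(ann$ccf_lower_ci) & !is.na(ann$ccf) &
      ann$ccf_lower_ci > ann$ccf + 1e-9
    if (any(bad)) stop("ccf_lower_ci exceeds ccf for ", sum(bad), " row(s)")
  }
  ann
}

#' Write a per-sample score table as TSV
#'
#' @param scores A table from [score_cohort()].
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
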