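#' Configuration for a full cohort analysis
#'
#' Inputs may be data frames (as from [simulate_cohort()]) or file paths,
#' which are read with the package's readers at run start.
#'
#' @param mutations Mutation table or path to a MAF-style TSV.
#' @param clinical Clinical table or path (`sample_id`, `time`, `event`,
#'   covariates).
#' @param clonal Optional clonality annotation table or path.
#' @param immune Optional immune-fraction table (long format) or path.
#' @param policy A [filter_policy()].
#' @param markers Markers to stratify survival on; subset of
#'   `c("tmb", "math", "benefit_score", "clonal_tmb")`.
#' @param clonal_rule `"ci"` or `"ccf"`; which clonality rule to apply.
#' @param minprop Minimum group fraction for the cutpoint scan.
#' @param min_mutations_for_math Minimum VAFs for an estimable MATH.
#' @param covariates Clinical covariate columns for the multivariate Cox
#'   model (the stratification group of the first marker is always added).
#' @param reference Named list of covariate reference levels.
#' @param dialect A [maf_dialect()] used when `mutations` is a path.
#' @param output_dir Optional directory; when set, [run_analysis()] writes
#'   stage outputs there.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(mutations, clinical, clonal = NULL,
                            immune = NULL,
                            policy = filter_policy(),
                            markers = c("tmb", "math", "benefit_score"),
                            clonal_rule = c("ccf", "ci"),
                            minprop = 0.1,
                            min_mutations_for_math = 5,
                            covariates = NULL,
                            reference = NULL,
                            dialect = maf_dialect(),
                            output_dir = NULL) {
  clonal_rule <- match.arg(clonal_rule)
  allowed <- c("tmb", "math", "benefit_score", "clonal_tmb")
  if (length(markers) == 0 || !all(markers %in% allowed)) {
    stop("markers must be a non-empty subset of: ",
         paste(allowed, collapse = ", "))
  }
  if ("clonal_tmb" %in% markers && is.null(clonal)) {
    stop("marker 'clonal_tmb' requires clonality annotations")
  }
  for (nm in c("mutations", "clinical", "clonal", "immune")) {
    x <- get(nm)
    if (is.character(x) && !file.exists(x)) {
      stop(nm, " input file not found: ", x)
    }
  }
  cfg <- list(mutations = mutations, clinical = clinical, clonal = clonal,
              immune = immune, policy = policy, markers = markers,
              clonal_rule = clonal_rule, minprop = minprop,
              min_mutations_for_math = min_mutations_for_math,
              covariates = covariates, reference = reference,
              dialect = dialect, output_dir = output_dir)
  class(cfg) <- "analysis_config"
  cfg
}

# Per-sample clonal TMB: join annotations to the quality-filtered
# nonsynonymous mutations of each sample, then count clonal calls.
.clonal_tmb_by_sample <- function(mutations_ns, annotations, rule,
                                  samples) {
  key <- function(d) paste(d$sample_id, d$chromosome, d$position,
                           d$alt_allele, sep = "\r")
  ann <- annotations[key(annotations) %in% key(mutations_ns), , drop = FALSE]
  vapply(samples, function(s) {
    compute_clonal_tmb(ann[ann$sample_id == s, , drop = FALSE], rule = rule)
  }, integer(1))
}

#' Run the full benefit-score analysis
#'
#' Orchestrates scoring, clonal TMB, marker correlations, maximally
#' selected cutpoint stratification with Kaplan-Meier/log-rank summaries,
#' per-marker univariate and multivariate Cox fits, and immune-fraction
#' contrasts, producing a machine-readable report. Deterministic given
#' identical inputs. When `config$output_dir` is set the stage outputs are
#' also persisted as TSV/JSON via [write_report()].
#'
#' @param config An [analysis_config()].
#' @return List of class `analysis_report`: `scores` (with `clonal_tmb`
#'   column when annotations are supplied), `correlations`, `stratification`
#'   (per marker: `cutpoint`, `logrank`, `km` coordinates per group,
#'   `univariate_cox`), `cox` (multivariate, or `NULL`), `immune_contrasts`
#'   (or `NULL`), `exclusions`, `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  mutations <- if (is.character(config$mutations)) {
    read_maf(config$mutations, dialect = config$dialect)
  } else config$mutations
  clinical <- if (is.character(config$clinical)) {
    read_clinical(config$clinical)
  } else config$clinical
  clinical$event <- as.logical(clinical$event)
  clonal <- if (is.character(config$clonal)) {
    read_clonal_annotations(config$clonal)
  } else config$clonal
  immune <- if (is.character(config$immune)) {
    read_immune_fractions(config$immune)
  } else config$immune

  ## scores ------------------------------------------------------------------
  scores <- score_cohort(mutations, policy = config$policy,
                         min_mutations_for_math =
                           config$min_mutations_for_math)
  exclusions <- data.frame(
    sample_id = scores$sample_id[!scores$valid],
    reason = if (any(!scores$valid)) "math_inestimable" else character(0),
    stringsAsFactors = FALSE)
  if (!is.null(clonal)) {
    q <- apply_quality_filters(mutations, config$policy)
    ns <- suppressWarnings(select_nonsynonymous(q, config$policy))
    scores$clonal_tmb <- .clonal_tmb_by_sample(
      ns, clonal, config$clonal_rule, scores$sample_id)
  }

  ## correlations --------------------------------------------------------------
  ok <- scores$valid
  correlations <- list(
    tmb_math = spearman_corr(scores$tmb[ok], scores$math[ok]))
  if (!is.null(scores$clonal_tmb)) {
    correlations$benefit_clonal_tmb <-
      spearman_corr(scores$benefit_score[ok], scores$clonal_tmb[ok])
  }

  ## per-marker stratification -------------------------------------------------
  sc <- merge(scores[scores$valid, , drop = FALSE], clinical,
              by = "sample_id")
  missing_clinical <- setdiff(scores$sample_id[scores$valid],
                              clinical$sample_id)
  if (length(missing_clinical) > 0) {
    exclusions <- rbind(exclusions, data.frame(
      sample_id = missing_clinical, reason = "no_clinical_record",
      stringsAsFactors = FALSE))
  }
  stratification <- list()
  for (mk in config$markers) {
    marker <- stats::setNames(sc[[mk]], sc$sample_id)
    cp <- find_optimal_cutpoint(marker, sc$time, sc$event,
                                minprop = config$minprop)
    grp <- cp$group_assignment
    lr <- logrank_test(sc$time, sc$event, grp)
    km <- lapply(stats::setNames(nm = levels(grp)), function(lv) {
      km_estimate(sc$time[grp == lv], sc$event[grp == lv])
    })
    dd <- data.frame(time = sc$time, event = sc$event, group = grp)
    uc <- cox_fit(dd, "group", reference = list(group = "low"))
    stratification[[mk]] <- list(cutpoint = cp, logrank = lr, km = km,
                                 univariate_cox = uc)
  }

  ## multivariate Cox ----------------------------------------------------------
  cox <- NULL
  if (!is.null(config$covariates)) {
    mk1 <- config$markers[1]
    dd <- sc[, c("time", "event", config$covariates), drop = FALSE]
    # paper-style coding: "Low" score level against a high reference
    dd$score_group <- stratification[[mk1]]$cutpoint$group_assignment
    refs <- config$reference
    refs$score_group <- "high"
    cox <- cox_fit(dd, c(config$covariates, "score_group"),
                   reference = refs)
  }

  ## immune contrasts ----------------------------------------------------------
  immune_contrasts <- NULL
  if (!is.null(immune)) {
    mk1 <- if ("benefit_score" %in% config$markers) "benefit_score"
           else config$markers[1]
    groups <- stratification[[mk1]]$cutpoint$group_assignment
    immune_contrasts <- immune_contrast_table(immune, groups)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("benefitscore")),
    n_input_samples = length(unique(mutations$sample_id)),
    n_scored = sum(scores$valid),
    n_excluded = nrow(exclusions),
    markers = config$markers,
    minprop = config$minprop,
    min_mutations_for_math = config$min_mutations_for_math,
    filter_policy = unclass(config$policy)
  )
  report <- list(scores = scores, correlations = correlations,
                 stratification = stratification, cox = cox,
                 immune_contrasts = immune_contrasts,
                 exclusions = exclusions, manifest = manifest)
  class(report) <- "analysis_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Benefit-score analysis: %d samples scored, %d excluded\n",
              x$manifest$n_scored, x$manifest$n_excluded))
  cat(sprintf("  Spearman rho(TMB, MATH) = %.3f (p = %.3g)\n",
              x$correlations$tmb_math$rho, x$correlations$tmb_math$p_value))
  if (!is.null(x$correlations$benefit_clonal_tmb)) {
    cat(sprintf("  Spearman rho(benefit score, clonal TMB) = %.3f (p = %.3g)\n",
                x$correlations$benefit_clonal_tmb$rho,
                x$correlations$benefit_clonal_tmb$p_value))
  }
  print(compare_markers(x))
  invisible(x)
}

#' Side-by-side marker comparison
#'
#' Tabulates, for every stratified marker, the selected threshold, group
#' sizes, the naive and selection-adjusted log-rank p-values and the
#' univariate hazard ratio (high vs low). No winner is declared; rank by
#' whichever column answers your question.
#'
#' @param report An [run_analysis()] report with >= 1 stratified marker.
#' @return Data frame, one row per marker.
#' @export
compare_markers <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  if (length(report$stratification) == 0) stop("no stratified markers")
  rows <- lapply(names(report$stratification), function(mk) {
    s <- report$stratification[[mk]]
    uc <- s$univariate_cox$table
    hi <- grep("high$", uc$term)
    data.frame(marker = mk,
               threshold = s$cutpoint$threshold,
               n_high = s$cutpoint$n_high,
               n_low = s$cutpoint$n_low,
               chi_square = s$logrank$chi_square,
               naive_p = s$cutpoint$naive_logrank_p,
               adjusted_p = s$cutpoint$adjusted_p,
               hr_high_vs_low = uc$hr[hi],
               hr_ci_low = uc$ci_low[hi],
               hr_ci_high = uc$ci_high[hi],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Persist an analysis report as TSV/JSON stage outputs
#'
#' Writes `scores.tsv`, `correlations.json`, `cutpoints.json`,
#' `km_<marker>.tsv` (plotting coordinates per group), `cox.tsv`,
#' `marker_comparison.tsv`, `immune_contrasts.tsv`, `exclusions.tsv` and
#' `manifest.json` under `dir`.
#'
#' @param report An [run_analysis()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$scores, "scores.tsv")
  jsonlite::write_json(
    lapply(report$correlations, unclass),
    file.path(dir, "correlations.json"), auto_unbox = TRUE, digits = NA)
  cps <- lapply(report$stratification, function(s) {
    cp <- s$cutpoint
    list(threshold = cp$threshold, statistic = cp$statistic,
         naive_logrank_p = cp$naive_logrank_p, adjusted_p = cp$adjusted_p,
         n_high = cp$n_high, n_low = cp$n_low, minprop = cp$minprop)
  })
  jsonlite::write_json(cps, file.path(dir, "cutpoints.json"),
                       auto_unbox = TRUE, digits = NA)
  for (mk in names(report$stratification)) {
    km <- report$stratification[[mk]]$km
    coords <- do.call(rbind, lapply(names(km), function(lv) {
      data.frame(group = lv, km[[lv]], stringsAsFactors = FALSE)
    }))
    wt(coords, paste0("km_", mk, ".tsv"))
  }
  if (!is.null(report$cox)) wt(report$cox$table, "cox.tsv")
  wt(compare_markers(report), "marker_comparison.tsv")
  if (!is.null(report$immune_contrasts)) {
    wt(report$immune_contrasts, "immune_contrasts.tsv")
  }
  wt(report$exclusions, "exclusions.tsv")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
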