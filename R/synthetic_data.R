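#' Configuration for a synthetic ICI melanoma-like cohort
#'
#' Defaults emulate the structure of published melanoma checkpoint-blockade
#' cohorts: roughly a hundred patients, nonsynonymous-dominated exome
#' mutation counts spanning orders of magnitude (negative binomial),
#' clonal/subclonal architecture with read-sampled VAFs under a diploid
#' copy-neutral model (`E[vaf] = purity * CCF / 2`), exponential survival
#' whose hazard depends on a latent benefit group, uniform right censoring,
#' and Dirichlet immune-cell compositions with group-dependent shifts.
#'
#' The latent `high` group receives `high_tmb_multiplier` times the
#' negative-binomial mutation mean and draws its clone number from
#' `1:high_max_clones` (the `low` group draws from the full
#' `clones_range`), so that a high latent group carries both a higher
#' mutation load and lower heterogeneity — the joint signal the benefit
#' score targets.
#'
#' @param n_patients Cohort size.
#' @param clones_range Integer range of clones per tumor (first clone is
#'   truncal at CCF 1; the rest are subclones).
#' @param subclone_ccf_range Uniform range for subclone CCFs.
#' @param mutations_mu,mutations_size Negative-binomial mean and dispersion
#'   (size) of the per-tumor mutation count for the low group.
#' @param purity_range Uniform range of tumor purity.
#' @param depth_mean Poisson mean sequencing depth per site (reads).
#' @param nonsynonymous_fraction Probability a simulated mutation is
#'   protein-altering.
#' @param baseline_hazard Exponential hazard of the high group (per time
#'   unit, months).
#' @param group_log_hr Log hazard ratio applied to the low group: hazard =
#'   `baseline_hazard * exp(group_log_hr * I(group == "low"))`; positive
#'   values mean the low group dies faster (high-vs-low HR
#'   `exp(-group_log_hr)`).
#' @param censoring_window Uniform (min, max) censoring times, months.
#' @param high_tmb_multiplier Mutation-mean multiplier for the high group.
#' @param high_max_clones Maximum clones in the high group.
#' @param cell_types Immune cell types simulated.
#' @param immune_conc Baseline Dirichlet concentrations, one per cell type.
#' @param immune_shift_high Additive concentration shift in the high group
#'   (both timepoints); concentrations are floored at 0.2.
#' @param immune_on_shift_high Additional shift applied to the high group
#'   at the on-treatment timepoint only (e.g. a CD8 boost).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 100,
                              clones_range = c(1L, 4L),
                              subclone_ccf_range = c(0.1, 0.8),
                              mutations_mu = 120,
                              mutations_size = 1.2,
                              purity_range = c(0.4, 0.9),
                              depth_mean = 150,
                              nonsynonymous_fraction = 0.75,
                              baseline_hazard = 0.03,
                              group_log_hr = 0.7,
                              censoring_window = c(6, 48),
                              high_tmb_multiplier = 3,
                              high_max_clones = 2L,
                              cell_types = c("NK cells activated",
                                             "Macrophages M2",
                                             "T cells CD8",
                                             "Other"),
                              immune_conc = c(2, 6, 8, 44),
                              immune_shift_high = c(2, -3, 0, 0),
                              immune_on_shift_high = c(0, 0, 6, 0)) {
  cfg <- list(n_patients = as.integer(n_patients),
              clones_range = as.integer(clones_range),
              subclone_ccf_range = subclone_ccf_range,
              mutations_mu = mutations_mu,
              mutations_size = mutations_size,
              purity_range = purity_range,
              depth_mean = depth_mean,
              nonsynonymous_fraction = nonsynonymous_fraction,
              baseline_hazard = baseline_hazard,
              group_log_hr = group_log_hr,
              censoring_window = censoring_window,
              high_tmb_multiplier = high_tmb_multiplier,
              high_max_clones = as.integer(high_max_clones),
              cell_types = cell_types,
              immune_conc = immune_conc,
              immune_shift_high = immune_shift_high,
              immune_on_shift_high = immune_on_shift_high)
  with(cfg, {
    stopifnot(n_patients >= 2,
              length(clones_range) == 2, clones_range[1] >= 1,
              clones_range[2] >= clones_range[1],
              length(subclone_ccf_range) == 2,
              subclone_ccf_range[1] > 0, subclone_ccf_range[2] < 1,
              subclone_ccf_range[1] <= subclone_ccf_range[2],
              mutations_mu > 0, mutations_size > 0,
              purity_range[1] > 0, purity_range[2] <= 1,
              purity_range[1] <= purity_range[2],
              depth_mean > 0,
              nonsynonymous_fraction >= 0, nonsynonymous_fraction <= 1,
              baseline_hazard > 0,
              censoring_window[1] > 0,
              censoring_window[2] >= censoring_window[1],
              high_tmb_multiplier > 0,
              high_max_clones >= 1,
              length(immune_conc) == length(cell_types),
              length(immune_shift_high) == length(cell_types),
              length(immune_on_shift_high) == length(cell_types),
              all(immune_conc > 0))
  })
  class(cfg) <- "simulation_config"
  cfg
}

# Nonsynonymous class frequencies roughly matching exome MAFs.
.sim_nonsyn_classes <- c(Missense_Mutation = 0.72, Nonsense_Mutation = 0.08,
                         Splice_Site = 0.05, Frame_Shift_Del = 0.06,
                         Frame_Shift_Ins = 0.04, In_Frame_Del = 0.03,
                         In_Frame_Ins = 0.02)

# Dirichlet draws via normalised gammas; rows sum to 1 exactly.
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws, per tumor: a latent benefit group, purity, a clonal architecture
#' (truncal clone at CCF 1 plus subclones), mutation counts, per-mutation
#' clone assignment, Poisson depth and binomial alt reads at
#' `E[vaf] = purity * CCF / 2`; then per patient an exponential survival
#' time with group-dependent hazard under uniform censoring, clinical
#' covariates, noisy CCF annotations, and Dirichlet immune fractions at two
#' timepoints. Fully deterministic given `seed`; the seed fans out to four
#' independent per-stage generators (mutations, clonality, survival,
#' immune) so stages are individually reproducible.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List of class `simulated_cohort` with elements `mutations`
#'   (MAF-schema data frame), `clonal_annotations`, `survival` (clinical
#'   table with covariates), `immune_fractions` (long format), `truth`
#'   (per-sample data frame: group, purity, n_clones, true TMB and
#'   mutation count, clone CCFs as a list column), `config`, `seed`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  stage_seed <- sample.int(.Machine$integer.max - 1, 4)
  n <- config$n_patients
  ids <- sprintf("S%04d", seq_len(n))

  ## --- stage 1: tumors and mutations -------------------------------------
  set.seed(stage_seed[1])
  group <- sample(c("high", "low"), n, replace = TRUE)
  purity <- stats::runif(n, config$purity_range[1], config$purity_range[2])
  mu_i <- config$mutations_mu *
    ifelse(group == "high", config$high_tmb_multiplier, 1)
  n_mut <- pmax(1L, stats::rnbinom(n, size = config$mutations_size,
                                   mu = mu_i))
  max_clones <- ifelse(group == "high",
                       pmin(config$high_max_clones, config$clones_range[2]),
                       config$clones_range[2])
  lo_cl <- config$clones_range[1]
  n_clones <- vapply(seq_len(n), function(i) {
    if (max_clones[i] <= lo_cl) return(as.integer(max(lo_cl, max_clones[i])))
    sample(lo_cl:max_clones[i], 1)
  }, integer(1))
  clone_ccfs <- lapply(seq_len(n), function(i) {
    k <- n_clones[i]
    c(1, if (k > 1) stats::runif(k - 1, config$subclone_ccf_range[1],
                                 config$subclone_ccf_range[2]))
  })
  M <- sum(n_mut)
  pat <- rep(seq_len(n), n_mut)
  clone_of <- unlist(lapply(seq_len(n), function(i) {
    sample.int(n_clones[i], n_mut[i], replace = TRUE)
  }), use.names = FALSE)
  ccf_true <- unlist(lapply(seq_len(n), function(i) clone_ccfs[[i]]),
                     use.names = FALSE)[
    clone_of + rep(cumsum(c(0, n_clones[-n])), n_mut)]
  depth <- pmax(1L, stats::rpois(M, config$depth_mean))
  p_alt <- pmin(1, purity[pat] * ccf_true / 2)
  alt <- stats::rbinom(M, depth, p_alt)
  ref <- depth - alt
  is_ns <- stats::runif(M) < config$nonsynonymous_fraction
  vclass <- rep("Silent", M)
  vclass[is_ns] <- sample(names(.sim_nonsyn_classes), sum(is_ns),
                          replace = TRUE, prob = .sim_nonsyn_classes)
  bases <- c("A", "C", "G", "T")
  refa <- sample(bases, M, replace = TRUE)
  # uniform over the three non-reference bases, vectorised
  alta <- bases[(match(refa, bases) - 1 + sample.int(3, M, replace = TRUE)) %% 4 + 1]
  pos <- sample.int(2^28, M)        # without replacement: unique keys
  mutations <- data.frame(
    sample_id = ids[pat],
    gene_symbol = sprintf("G%04d", sample.int(5000, M, replace = TRUE)),
    chromosome = as.character(sample.int(22, M, replace = TRUE)),
    position = pos,
    ref_allele = refa,
    alt_allele = alta,
    variant_classification = vclass,
    t_alt_count = alt,
    t_ref_count = ref,
    stringsAsFactors = FALSE
  )
  mutations$coverage <- mutations$t_alt_count + mutations$t_ref_count
  mutations$vaf <- mutations$t_alt_count / mutations$coverage

  ## --- stage 2: clonality annotations ------------------------------------
  set.seed(stage_seed[2])
  ccf_hat <- pmin(1, pmax(0.01, ccf_true + stats::rnorm(M, 0, 0.03)))
  ccf_lower <- pmax(0, ccf_hat - stats::runif(M, 0.02, 0.08))
  p_clonal <- stats::plogis((ccf_hat - 0.85) * 25)
  clonal_annotations <- data.frame(
    sample_id = mutations$sample_id,
    chromosome = mutations$chromosome,
    position = mutations$position,
    alt_allele = mutations$alt_allele,
    ccf = ccf_hat,
    ccf_lower_ci = ccf_lower,
    p_clonal = p_clonal,
    p_subclonal = 1 - p_clonal,
    true_clone = clone_of,
    true_clonal = clone_of == 1L,
    stringsAsFactors = FALSE
  )

  ## --- stage 3: survival and clinical covariates -------------------------
  set.seed(stage_seed[3])
  hazard <- config$baseline_hazard *
    exp(config$group_log_hr * (group == "low"))
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::runif(n, config$censoring_window[1],
                         config$censoring_window[2])
  survival_tab <- data.frame(
    sample_id = ids,
    time = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    age = round(pmin(90, pmax(25, stats::rnorm(n, 62, 12)))),
    sex = sample(c("Male", "Female"), n, replace = TRUE, prob = c(0.6, 0.4)),
    stage = sample(c("III", "IV"), n, replace = TRUE, prob = c(0.3, 0.7)),
    prior_treatment = sample(c("Yes", "No"), n, replace = TRUE,
                             prob = c(0.35, 0.65)),
    braf = stats::runif(n) < 0.45,
    nf1 = stats::runif(n) < 0.12,
    ras = stats::runif(n) < 0.20,
    stringsAsFactors = FALSE
  )

  ## --- stage 4: immune fractions -----------------------------------------
  set.seed(stage_seed[4])
  k <- length(config$cell_types)
  conc_pre <- matrix(rep(config$immune_conc, each = n), nrow = n)
  hi <- group == "high"
  conc_pre[hi, ] <- sweep(conc_pre[hi, , drop = FALSE], 2,
                          config$immune_shift_high, `+`)
  conc_pre <- pmax(conc_pre, 0.2)
  conc_on <- conc_pre
  conc_on[hi, ] <- sweep(conc_on[hi, , drop = FALSE], 2,
                         config$immune_on_shift_high, `+`)
  conc_on <- pmax(conc_on, 0.2)
  draw_tp <- function(conc, tp) {
    g <- matrix(stats::rgamma(n * k, shape = as.vector(t(conc))),
                nrow = n, byrow = TRUE)
    fr <- g / rowSums(g)
    data.frame(sample_id = rep(ids, each = k),
               timepoint = tp,
               cell_type = rep(config$cell_types, times = n),
               fraction = as.vector(t(fr)),
               stringsAsFactors = FALSE)
  }
  immune <- rbind(draw_tp(conc_pre, "pre"), draw_tp(conc_on, "on"))

  ## --- ground truth -------------------------------------------------------
  true_tmb <- as.integer(rowsum((is_ns) + 0, pat)[, 1])
  truth <- data.frame(sample_id = ids, group = group, purity = purity,
                      n_clones = n_clones, n_mutations = n_mut,
                      true_tmb = true_tmb, stringsAsFactors = FALSE)
  truth$clone_ccfs <- clone_ccfs

  res <- list(mutations = mutations,
              clonal_annotations = clonal_annotations,
              survival = survival_tab,
              immune_fractions = immune,
              truth = truth,
              config = config,
              seed = as.integer(seed))
  class(res) <- "simulated_cohort"
  res
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulated cohort: %d patients, %d mutations (seed %d)\n",
    "  groups: %d high / %d low; generative log-HR (low vs high): %.3f\n"),
    nrow(x$truth), nrow(x$mutations), x$seed,
    sum(x$truth$group == "high"), sum(x$truth$group == "low"),
    x$config$group_log_hr))
  invisible(x)
}

#' Write a simulated cohort to disk in pipeline input formats
#'
#' Emits `mutations.tsv` (MAF-style, GDC headers), `clinical.tsv`,
#' `clonality.tsv`, `immune_fractions.tsv` and `truth.json` under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maf <- cohort$mutations
  names(maf)[match(
    c("sample_id", "gene_symbol", "chromosome", "position", "ref_allele",
      "alt_allele", "variant_classification"), names(maf))] <-
    c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome", "Start_Position",
      "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification")
  maf$vaf <- NULL; maf$coverage <- NULL
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(maf, "mutations.tsv")
  cl <- cohort$survival
  cl$event <- as.integer(cl$event)
  wt(cl, "clinical.tsv")
  wt(cohort$clonal_annotations, "clonality.tsv")
  wt(cohort$immune_fractions, "immune_fractions.tsv")
  truth <- cohort$truth
  truth_list <- list(
    samples = lapply(seq_len(nrow(truth)), function(i) {
      list(sample_id = truth$sample_id[i], group = truth$group[i],
           purity = truth$purity[i], n_clones = truth$n_clones[i],
           n_mutations = truth$n_mutations[i], true_tmb = truth$true_tmb[i],
           clone_ccfs = truth$clone_ccfs[[i]])
    }),
    group_log_hr = cohort$config$group_log_hr,
    baseline_hazard = cohort$config$baseline_hazard,
    seed = cohort$seed
  )
  jsonlite::write_json(truth_list, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Recovery of ground truth by the analysis pipeline
#'
#' Given a simulated cohort and the pipeline outputs computed from it,
#' reports (a) the Spearman correlation between computed TMB and the true
#' nonsynonymous mutation count, (b) the concordance between the
#' cutpoint-assigned high/low groups and the latent generative groups, and
#' (c) the bias of the estimated log hazard ratio (high vs low) relative
#' to the generative value `-group_log_hr`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param scores A [score_cohort()] table computed from it.
#' @param cutpoint Optional [find_optimal_cutpoint()] result whose
#'   `group_assignment` is named by sample.
#' @param cox Optional [cox_fit()] with a group term whose "high" level
#'   coefficient estimates the high-vs-low log-HR.
#' @return List of class `recovery_report`: `tmb_spearman_rho`,
#'   `group_concordance` (or `NA`), `estimated_loghr`, `generative_loghr`,
#'   `loghr_bias` (or `NA`), `n`.
#' @export
truth_recovery_report <- function(cohort, scores, cutpoint = NULL,
                                  cox = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  m <- merge(scores, cohort$truth[, c("sample_id", "group", "true_tmb")],
             by = "sample_id")
  if (nrow(m) == 0) stop("no overlap between scores and simulated truth")
  rho <- spearman_corr(m$tmb, m$true_tmb)$rho
  conc <- NA_real_
  if (!is.null(cutpoint)) {
    ga <- cutpoint$group_assignment
    if (is.null(names(ga))) stop("cutpoint group assignment must be named")
    common <- intersect(names(ga), cohort$truth$sample_id)
    if (length(common) == 0) stop("cutpoint groups do not match cohort samples")
    tg <- cohort$truth$group[match(common, cohort$truth$sample_id)]
    conc <- mean(as.character(ga[common]) == tg)
  }
  est <- NA_real_; bias <- NA_real_
  gen <- -cohort$config$group_log_hr   # high vs low
  if (!is.null(cox)) {
    row <- grep("high$", cox$table$term)
    if (length(row) != 1) {
      stop("cox fit has no unique 'high' group term to read the log-HR from")
    }
    est <- cox$table$coef[row]
    bias <- est - gen
  }
  res <- list(tmb_spearman_rho = rho, group_concordance = conc,
              estimated_loghr = est, generative_loghr = gen,
              loghr_bias = bias, n = nrow(m))
  class(res) <- "recovery_report"
  res
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Truth recovery (n = %d)\n",
    "  TMB Spearman rho vs truth: %.3f\n",
    "  group concordance: %s\n",
    "  estimated log-HR (high vs low): %s (generative %.3f, bias %s)\n"),
    x$n, x$tmb_spearman_rho,
    ifelse(is.na(x$group_concordance), "-",
           sprintf("%.3f", x$group_concordance)),
    ifelse(is.na(x$estimated_loghr), "-",
           sprintf("%.3f", x$estimated_loghr)),
    x$generative_loghr,
    ifelse(is.na(x$loghr_bias), "-", sprintf("%+.3f", x$loghr_bias))))
  invisible(x)
}
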