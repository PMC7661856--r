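test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_patients = 20, mutations_mu = 30)
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 43)
  expect_false(identical(a$mutations, c2$mutations))
})

test_that("config validation rejects invalid ranges", {
  expect_error(simulation_config(purity_range = c(0, 0.5)))
  expect_error(simulation_config(subclone_ccf_range = c(0.9, 0.2)))
  expect_error(simulation_config(censoring_window = c(-1, 5)))
  expect_error(simulation_config(depth_mean = 0))
})

test_that("observed VAFs obey the diploid expectation purity * CCF / 2", {
  # one truncal clone, purity 1, very high depth: mean VAF -> 0.5
  cfg <- simulation_config(n_patients = 10, clones_range = c(1, 1),
                           high_max_clones = 1, purity_range = c(1, 1),
                           depth_mean = 10000, mutations_mu = 80)
  co <- simulate_cohort(cfg, seed = 8)
  expect_lt(abs(mean(co$mutations$vaf) - 0.5), 0.005)

  # moderate depth: per-clone mean within 3 binomial standard errors
  cfg2 <- simulation_config(n_patients = 15, clones_range = c(2, 2),
                            high_max_clones = 2, depth_mean = 200,
                            mutations_mu = 100)
  co2 <- simulate_cohort(cfg2, seed = 9)
  ann <- co2$clonal_annotations
  for (i in sample(nrow(co2$truth), 5)) {
    s <- co2$truth$sample_id[i]
    pur <- co2$truth$purity[i]
    ccfs <- co2$truth$clone_ccfs[[i]]
    mut <- co2$mutations[co2$mutations$sample_id == s, ]
    clone <- ann$true_clone[ann$sample_id == s]
    for (k in unique(clone)) {
      v <- mut$vaf[clone == k]
      if (length(v) < 10) next
      p <- pur * ccfs[k] / 2
      se <- sqrt(p * (1 - p) / mean(mut$coverage[clone == k])) /
        sqrt(length(v))
      expect_lt(abs(mean(v) - p), 3 * se + 1e-3)
    }
  }
})

test_that("immune fractions sum to one per sample and timepoint", {
  co <- simulate_cohort(simulation_config(n_patients = 25,
                                          mutations_mu = 20), seed = 3)
  sums <- tapply(co$immune_fractions$fraction,
                 paste(co$immune_fractions$sample_id,
                       co$immune_fractions$timepoint),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("survival hazard depends on the latent group as configured", {
  cfg <- simulation_config(n_patients = 400, mutations_mu = 10,
                           group_log_hr = 1.2)
  co <- simulate_cohort(cfg, seed = 77)
  d <- merge(co$survival, co$truth[, c("sample_id", "group")],
             by = "sample_id")
  fit <- cox_fit(d, "group", reference = list(group = "low"))
  est <- fit$table$coef[grep("high$", fit$table$term)]
  expect_lt(abs(est - (-1.2)), 0.35)
})

test_that("written cohorts round-trip through the package readers", {
  co <- simulate_cohort(simulation_config(n_patients = 12,
                                          mutations_mu = 40), seed = 21)
  dir <- tempfile()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("mutations.tsv", "clinical.tsv", "clonality.tsv",
      "immune_fractions.tsv", "truth.json")))))
  maf <- read_maf(file.path(dir, "mutations.tsv"))
  expect_equal(nrow(maf), nrow(co$mutations))
  expect_equal(sort(unique(maf$sample_id)),
               sort(unique(co$mutations$sample_id)))
  sc_disk <- score_cohort(maf)
  sc_mem <- score_cohort(co$mutations)
  expect_equal(sc_disk$tmb, sc_mem$tmb)
  expect_equal(sc_disk$math, sc_mem$math, tolerance = 1e-9)
  cl <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(cl$time, co$survival$time, tolerance = 1e-6)
  expect_equal(cl$event, co$survival$event)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$samples), 12)
})

test_that("truth recovery reports perfect concordance in the identity case", {
  co <- simulate_cohort(simulation_config(n_patients = 60,
                                          mutations_mu = 40), seed = 10)
  sc <- suppressMessages(score_cohort(co$mutations))
  # marker built directly from the latent group, threshold between levels
  marker <- setNames(ifelse(co$truth$group == "high", 1, 0),
                     co$truth$sample_id)
  d <- merge(co$survival, co$truth, by = "sample_id")
  cp <- find_optimal_cutpoint(marker[d$sample_id], d$time, d$event,
                              minprop = 0.1)
  rr <- truth_recovery_report(co, sc, cutpoint = cp)
  expect_equal(rr$group_concordance, 1)
  expect_gt(rr$tmb_spearman_rho, 0.9)
})

test_that("high depth makes computed TMB track the true count almost exactly", {
  cfg <- simulation_config(n_patients = 25, clones_range = c(1, 1),
                           high_max_clones = 1, depth_mean = 2000,
                           purity_range = c(0.8, 1), mutations_mu = 60)
  co <- simulate_cohort(cfg, seed = 14)
  sc <- suppressMessages(score_cohort(co$mutations))
  rr <- truth_recovery_report(co, sc)
  expect_gt(rr$tmb_spearman_rho, 0.99)
})
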