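test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_corr(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_corr(1:4, c(8, 6, 4, 2))$rho, -1)
  # ties: rho equals Pearson on average ranks (rank-then-Pearson oracle)
  x <- c(1, 2, 2, 4); y <- c(3, 1, 5, 7)
  expect_equal(spearman_corr(x, y)$rho,
               unname(stats::cor(rank(x), rank(y))), tolerance = 1e-12)
  expect_error(spearman_corr(rep(2, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(3)
  x <- rnorm(30); y <- x + rnorm(30)
  base <- spearman_corr(x, y)
  tr <- spearman_corr(exp(x), y^3 + 10 * y)
  expect_equal(tr$rho, base$rho, tolerance = 1e-12)
  expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
})

test_that("between-group contrast reports exact tails and direction", {
  # identical multisets: no difference detectable
  fr <- make_immune_long(sprintf("S%02d", 1:8), "pre", "NK",
                         rep(c(0.1, 0.2, 0.3, 0.4), 2))
  groups <- setNames(rep(c("high", "low"), each = 4), fr$sample_id)
  r <- compare_fractions_between_groups(fr, groups, "NK")
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, 0)

  # complete separation, 8 vs 8: exact two-sided rank-sum tail
  fr2 <- make_immune_long(sprintf("T%02d", 1:16), "pre", "NK",
                          c(seq(0.5, 0.64, by = 0.02),
                            seq(0.1, 0.24, by = 0.02)))
  g2 <- setNames(rep(c("high", "low"), each = 8), fr2$sample_id)
  r2 <- compare_fractions_between_groups(fr2, g2, "NK")
  expect_equal(r2$p_value, 2 / choose(16, 8), tolerance = 1e-12)
  expect_equal(r2$direction, 1)
  expect_error(compare_fractions_between_groups(fr2[1:8, ], g2, "NK"),
               "low group")
})

test_that("rank-sum p is symmetric in group labels with flipped direction", {
  set.seed(15)
  fr <- make_immune_long(sprintf("S%02d", 1:20), "pre", "M2",
                         c(runif(10, 0.1, 0.3), runif(10, 0.15, 0.4)))
  g <- setNames(rep(c("high", "low"), each = 10), fr$sample_id)
  g_swap <- setNames(ifelse(g == "high", "low", "high"), names(g))
  a <- compare_fractions_between_groups(fr, g, "M2")
  b <- compare_fractions_between_groups(fr, g_swap, "M2")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$direction, -b$direction)
})

test_that("paired on-treatment change uses the signed-rank distribution", {
  ids <- sprintf("S%02d", 1:10)
  pre_v <- seq(0.10, 0.19, by = 0.01)
  shifts <- seq(0.03, 0.075, by = 0.005)    # distinct, all positive
  fr <- rbind(make_immune_long(ids, "pre", "CD8", pre_v),
              make_immune_long(ids, "on", "CD8", pre_v + shifts))
  r <- compare_on_treatment_change(fr, ids, "CD8")
  # every difference positive: the exact signed-rank two-sided minimum
  expect_equal(r$p_value, 2 / 2^10, tolerance = 1e-12)
  expect_equal(r$direction, 1)

  # antisymmetric differences: p at its maximum
  d <- c(-0.03, -0.02, -0.01, 0.01, 0.02, 0.03)
  ids6 <- sprintf("A%d", 1:6)
  fr2 <- rbind(make_immune_long(ids6, "pre", "CD8", rep(0.2, 6)),
               make_immune_long(ids6, "on", "CD8", 0.2 + d))
  r2 <- compare_on_treatment_change(fr2, ids6, "CD8")
  expect_gte(r2$p_value, 0.9)

  # unpaired sample excluded with a message
  fr3 <- rbind(fr, make_immune_long("S99", "pre", "CD8", 0.5))
  expect_message(r3 <- compare_on_treatment_change(fr3, c(ids, "S99"), "CD8"),
                 "without both timepoints")
  expect_equal(r3$n_pairs, 10)

  frz <- rbind(make_immune_long(ids6, "pre", "CD8", rep(0.2, 6)),
               make_immune_long(ids6, "on", "CD8", rep(0.2, 6)))
  expect_error(compare_on_treatment_change(frz, ids6, "CD8"),
               "zero")
})

test_that("rank-sum test holds its size on a simulated null", {
  set.seed(99)
  rej <- 0
  nsim <- 1000
  for (i in seq_len(nsim)) {
    p <- stats::wilcox.test(rnorm(12), rnorm(12))$p.value
    if (p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / nsim, 0.03)
  expect_lte(rej / nsim, 0.07)
})

test_that("immune contrast table covers cell types and contrasts with BH", {
  co <- simulate_cohort(simulation_config(n_patients = 40,
                                          mutations_mu = 30), seed = 5)
  groups <- setNames(ifelse(co$truth$group == "high", "high", "low"),
                     co$truth$sample_id)
  tab <- immune_contrast_table(co$immune_fractions, groups)
  expect_setequal(unique(tab$contrast),
                  c("between_groups_pre", "within_group_change"))
  expect_equal(sum(tab$contrast == "between_groups_pre"),
               length(unique(co$immune_fractions$cell_type)))
  expect_true(all(tab$p_adjusted_bh >= tab$p_value - 1e-12))
  expect_true(all(tab$p_adjusted_bh <= 1))
})

test_that("wide immune tables are stacked to long form", {
  wide <- data.frame(sample_id = c("S1", "S2"), timepoint = "pre",
                     `NK cells activated` = c(0.1, 0.2),
                     `Macrophages M2` = c(0.9, 0.8),
                     check.names = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  long <- read_immune_fractions(path, format = "wide")
  expect_equal(nrow(long), 4)
  expect_setequal(long$cell_type, c("NK cells activated", "Macrophages M2"))
  expect_equal(long$fraction[long$sample_id == "S1" &
                               long$cell_type == "NK cells activated"], 0.1)
})
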