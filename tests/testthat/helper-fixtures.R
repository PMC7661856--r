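# Fixture builders used across test files. All synthetic data is generated
# in code under fixed seeds; nothing is stored on disk.

make_mutations <- function(sample_id, vaf = NULL, coverage = 100,
                           variant_classification = "Missense_Mutation",
                           t_alt_count = NULL, t_ref_count = NULL) {
  n <- if (length(sample_id) == 0 &&
             length(vaf) + length(t_alt_count) == 0) {
    0L
  } else {
    max(length(sample_id), length(vaf), length(variant_classification),
        length(t_alt_count), length(t_ref_count))
  }
  sample_id <- rep_len(sample_id, n)
  coverage <- rep_len(coverage, n)
  variant_classification <- rep_len(variant_classification, n)
  if (is.null(t_alt_count)) {
    vaf <- rep_len(vaf, n)
    t_alt_count <- round(vaf * coverage)
    t_ref_count <- coverage - t_alt_count
  } else {
    t_alt_count <- rep_len(t_alt_count, n)
    t_ref_count <- rep_len(t_ref_count, n)
    coverage <- t_alt_count + t_ref_count
  }
  d <- data.frame(
    sample_id = sample_id,
    gene_symbol = sprintf("G%03d", seq_len(n)),
    chromosome = rep("1", n),
    position = seq_len(n) * 1000,
    ref_allele = rep("A", n),
    alt_allele = rep("T", n),
    variant_classification = variant_classification,
    t_alt_count = t_alt_count,
    t_ref_count = t_ref_count,
    stringsAsFactors = FALSE
  )
  d$coverage <- d$t_alt_count + d$t_ref_count
  d$vaf <- d$t_alt_count / d$coverage
  d
}

write_temp_maf <- function(df, gz = FALSE, comment = TRUE) {
  path <- tempfile(fileext = if (gz) ".maf.gz" else ".maf")
  hdr <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
           "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
           "Variant_Classification", "t_alt_count", "t_ref_count")
  out <- df[, c("sample_id", "gene_symbol", "chromosome", "position",
                "ref_allele", "alt_allele", "variant_classification",
                "t_alt_count", "t_ref_count")]
  names(out) <- hdr
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  if (comment) writeLines("#version 2.4", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

# Two-group exponential survival with uniform censoring; returns a data
# frame ready for cox_fit / logrank_test.
make_survival_groups <- function(n_per_group, hazard_a, hazard_b,
                                 cens = c(5, 60)) {
  tm <- c(stats::rexp(n_per_group, hazard_a),
          stats::rexp(n_per_group, hazard_b))
  cv <- stats::runif(2 * n_per_group, cens[1], cens[2])
  data.frame(time = pmin(tm, cv), event = tm <= cv,
             group = rep(c("a", "b"), each = n_per_group),
             stringsAsFactors = FALSE)
}

make_immune_long <- function(sample_id, timepoint, cell_type, fraction) {
  data.frame(sample_id = sample_id, timepoint = timepoint,
             cell_type = cell_type, fraction = fraction,
             stringsAsFactors = FALSE)
}
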