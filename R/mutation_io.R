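#' Column-name dialect for MAF-style mutation tables
#'
#' Maps the canonical field names used throughout the package to the column
#' headers of a particular MAF export. Defaults follow the GDC MAF
#' convention (`Tumor_Sample_Barcode`, `Variant_Classification`,
#' `t_alt_count`, `t_ref_count`); cohort supplements with other headers are
#' handled by overriding individual entries.
#'
#' @param sample_id,variant_classification,t_alt_count,t_ref_count Column
#'   names for the four required fields.
#' @param gene_symbol,chromosome,position,ref_allele,alt_allele Column names
#'   for optional fields; a missing column yields `NA` in the output.
#' @return A named list of class `maf_dialect`.
#' @export
maf_dialect <- function(sample_id = "Tumor_Sample_Barcode",
                        variant_classification = "Variant_Classification",
                        t_alt_count = "t_alt_count",
                        t_ref_count = "t_ref_count",
                        gene_symbol = "Hugo_Symbol",
                        chromosome = "Chromosome",
                        position = "Start_Position",
                        ref_allele = "Reference_Allele",
                        alt_allele = "Tumor_Seq_Allele2") {
  d <- list(sample_id = sample_id,
            variant_classification = variant_classification,
            t_alt_count = t_alt_count,
            t_ref_count = t_ref_count,
            gene_symbol = gene_symbol,
            chromosome = chromosome,
            position = position,
            ref_allele = ref_allele,
            alt_allele = alt_allele)
  class(d) <- "maf_dialect"
  d
}

# MAF variant classes counted as nonsynonymous (protein-altering).
.default_nonsynonymous <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins",
  "In_Frame_Del", "In_Frame_Ins", "Translation_Start_Site"
)

# Classes recognised as synonymous / non-coding; anything outside the union
# of this set and the nonsynonymous set triggers a warning when selecting.
.known_synonymous <- c(
  "Silent", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "IGR",
  "RNA", "Splice_Region", "lincRNA", "De_novo_Start_InFrame",
  "De_novo_Start_OutOfFrame"
)

#' Mutation filter policy
#'
#' Bundles the quality thresholds and the functional-class definition used
#' when deriving per-sample burden scores. Defaults: variants with allelic
#' fraction below 0.05 or total coverage of 30 reads or fewer are excluded,
#' and the standard protein-altering MAF classes count as nonsynonymous.
#'
#' @param min_vaf Minimum variant allele fraction retained (strict lower
#'   bound: records with `vaf < min_vaf` are removed).
#' @param min_coverage_exclusive Coverage must strictly exceed this number of
#'   reads (records with `coverage <= min_coverage_exclusive` are removed).
#' @param nonsynonymous_classes Character vector of `Variant_Classification`
#'   values counted as nonsynonymous.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(min_vaf = 0.05,
                          min_coverage_exclusive = 30,
                          nonsynonymous_classes = .default_nonsynonymous) {
  stopifnot(is.numeric(min_vaf), length(min_vaf) == 1,
            min_vaf >= 0, min_vaf <= 1,
            is.numeric(min_coverage_exclusive),
            length(min_coverage_exclusive) == 1,
            min_coverage_exclusive >= 0,
            is.character(nonsynonymous_classes),
            length(nonsynonymous_classes) > 0)
  p <- list(min_vaf = min_vaf,
            min_coverage_exclusive = min_coverage_exclusive,
            nonsynonymous_classes = nonsynonymous_classes)
  class(p) <- "filter_policy"
  p
}

#' Read a MAF-style somatic mutation table
#'
#' Reads a tab-separated mutation table (plain or gzip-compressed, `#`
#' comment lines skipped), resolves columns through a [maf_dialect()], and
#' derives per-record coverage (`t_alt_count + t_ref_count`) and variant
#' allele fraction (`t_alt_count / coverage`). Records with zero coverage
#' carry no allele-fraction information and are dropped with a message.
#'
#' @param path Path to the file.
#' @param dialect A [maf_dialect()] mapping canonical fields to headers.
#' @param provenance Free-text label stored on the result.
#' @return A data frame with columns `sample_id`, `gene_symbol`,
#'   `chromosome`, `position`, `ref_allele`, `alt_allele`,
#'   `variant_classification`, `t_alt_count`, `t_ref_count`, `vaf`,
#'   `coverage`, with attributes `provenance` and `n_dropped_zero_coverage`.
#' @export
read_maf <- function(path, dialect = maf_dialect(),
                     provenance = basename(path)) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  required <- c("sample_id", "variant_classification",
                "t_alt_count", "t_ref_count")
  for (f in required) {
    if (!dialect[[f]] %in% names(raw)) {
      stop("required column '", dialect[[f]], "' (", f,
           ") not found in ", path)
    }
  }
  pick <- function(f) {
    col <- dialect[[f]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  parse_count <- function(f) {
    x <- pick(f)
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
    if (length(bad) > 0) {
      stop("unparseable ", f, " in ", path, " at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (any(v < 0, na.rm = TRUE)) stop("negative ", f, " in ", path)
    v
  }
  out <- data.frame(
    sample_id = pick("sample_id"),
    gene_symbol = pick("gene_symbol"),
    chromosome = pick("chromosome"),
    position = suppressWarnings(as.numeric(pick("position"))),
    ref_allele = pick("ref_allele"),
    alt_allele = pick("alt_allele"),
    variant_classification = pick("variant_classification"),
    t_alt_count = parse_count("t_alt_count"),
    t_ref_count = parse_count("t_ref_count"),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$sample_id) | !nzchar(out$sample_id))) {
    stop("empty sample identifier in ", path)
  }
  out$coverage <- out$t_alt_count + out$t_ref_count
  zero <- which(!is.na(out$coverage) & out$coverage == 0)
  if (length(zero) > 0) {
    message("read_maf: dropping ", length(zero),
            " record(s) with zero coverage")
    out <- out[-zero, , drop = FALSE]
  }
  out$vaf <- ifelse(out$coverage > 0, out$t_alt_count / out$coverage,
                    NA_real_)
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  attr(out, "n_dropped_zero_coverage") <- length(zero)
  out
}

#' Apply VAF and coverage quality filters
#'
#' Retains records with `vaf >= min_vaf` and
#' `coverage > min_coverage_exclusive`. The removal counts are attached as a
#' `filter_report` attribute (`n_in`, `n_removed_vaf`, `n_removed_coverage`,
#' `n_out`); a record failing both thresholds is tallied under the VAF
#' count so the four numbers are additive.
#'
#' @param mutations A mutation table as returned by [read_maf()].
#' @param policy A [filter_policy()].
#' @return The filtered table, same schema, with a `filter_report`
#'   attribute; retrieve it with [filter_report()].
#' @export
apply_quality_filters <- function(mutations, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"),
            all(c("vaf", "coverage") %in% names(mutations)))
  if (any(is.na(mutations$vaf))) {
    stop("records with undefined vaf; drop zero-coverage records first")
  }
  fail_vaf <- mutations$vaf < policy$min_vaf
  fail_cov <- !fail_vaf & mutations$coverage <= policy$min_coverage_exclusive
  keep <- !fail_vaf & !fail_cov
  out <- mutations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(mutations, "provenance")
  attr(out, "filter_report") <- list(
    n_in = nrow(mutations),
    n_removed_vaf = sum(fail_vaf),
    n_removed_coverage = sum(fail_cov),
    n_out = nrow(out)
  )
  out
}

#' Retrieve the filter report of a filtered mutation table
#'
#' @param mutations A table returned by [apply_quality_filters()].
#' @return The report list, or `NULL` if none is attached.
#' @export
filter_report <- function(mutations) attr(mutations, "filter_report")

#' Write a filter report as JSON
#'
#' @param mutations A table returned by [apply_quality_filters()].
#' @param path Output path.
#' @export
write_filter_report <- function(mutations, path) {
  rep <- filter_report(mutations)
  if (is.null(rep)) stop("no filter report attached to this table")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Restrict a mutation table to nonsynonymous variants
#'
#' Keeps records whose `variant_classification` is in the policy's
#' nonsynonymous set. Classification values outside the recognised MAF
#' vocabulary are excluded with a warning.
#'
#' @inheritParams apply_quality_filters
#' @return The restricted table.
#' @export
select_nonsynonymous <- function(mutations, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"),
            "variant_classification" %in% names(mutations))
  vc <- mutations$variant_classification
  known <- union(policy$nonsynonymous_classes, .known_synonymous)
  unknown <- setdiff(unique(vc), known)
  if (length(unknown) > 0) {
    warning("unknown variant classification(s) excluded: ",
            paste(unknown, collapse = ", "))
  }
  out <- mutations[vc %in% policy$nonsynonymous_classes, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(mutations, "provenance")
  out
}
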