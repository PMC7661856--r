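#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (exact when sample size permits and no ties are present, asymptotic
#' otherwise).
#'
#' @param x,y Paired numeric vectors of equal length, n >= 3.
#' @return List of class `correlation_result`: `rho`, `p_value`, `n`.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("correlation undefined for a constant input vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  res <- list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
  class(res) <- "correlation_result"
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman correlation: rho = %.3f, p = %.4g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

# Validate / normalise a long-format immune fraction table.
.check_fractions <- function(fractions) {
  need <- c("sample_id", "timepoint", "cell_type", "fraction")
  miss <- setdiff(need, names(fractions))
  if (length(miss) > 0) {
    stop("immune fraction table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(fractions$fraction < 0 | fractions$fraction > 1, na.rm = TRUE)) {
    stop("fractions must lie in [0, 1]")
  }
  fractions
}

#' Compare a cell type's fraction between marker-defined groups
#'
#' Two-sided Wilcoxon rank-sum test on pre-treatment fractions between the
#' high and low score groups (exact when feasible without ties, normal
#' approximation with continuity correction otherwise). The reported
#' direction is the sign of `median(high) - median(low)`.
#'
#' @param fractions Long-format table: `sample_id`, `timepoint`,
#'   `cell_type`, `fraction`.
#' @param groups Named vector/factor of `"high"`/`"low"` per sample, or a
#'   data frame with columns `sample_id`, `group`.
#' @param cell_type Cell-type label to test.
#' @param timepoint Timepoint to test at (default `"pre"`).
#' @return One-row data frame: `cell_type`, `contrast`, `statistic`,
#'   `p_value`, `n_high`, `n_low`, `direction`.
#' @export
compare_fractions_between_groups <- function(fractions, groups, cell_type,
                                             timepoint = "pre") {
  fractions <- .check_fractions(fractions)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$sample_id)
  }
  sub <- fractions[fractions$cell_type == cell_type &
                     fractions$timepoint == timepoint, , drop = FALSE]
  g <- groups[sub$sample_id]
  hi <- sub$fraction[!is.na(g) & g == "high"]
  lo <- sub$fraction[!is.na(g) & g == "low"]
  if (length(hi) == 0) stop("no '", cell_type, "' fractions in the high group")
  if (length(lo) == 0) stop("no '", cell_type, "' fractions in the low group")
  wt <- suppressWarnings(stats::wilcox.test(hi, lo, alternative = "two.sided"))
  md <- stats::median(hi) - stats::median(lo)
  data.frame(cell_type = cell_type,
             contrast = "between_groups_pre",
             statistic = unname(wt$statistic),
             p_value = wt$p.value,
             n_high = length(hi), n_low = length(lo),
             direction = sign(md),
             stringsAsFactors = FALSE)
}

#' On-treatment change of a cell type's fraction within a group
#'
#' Two-sided Wilcoxon signed-rank test on per-patient (on - pre)
#' differences for the given samples; zero differences are dropped (the
#' standard signed-rank convention), and samples lacking either timepoint
#' are excluded with a message.
#'
#' @param fractions Long-format table covering both timepoints.
#' @param samples Sample IDs of the group to test within.
#' @param cell_type Cell-type label to test.
#' @return One-row data frame: `cell_type`, `contrast`, `statistic`,
#'   `p_value`, `n_pairs`, `direction`.
#' @export
compare_on_treatment_change <- function(fractions, samples, cell_type) {
  fractions <- .check_fractions(fractions)
  sub <- fractions[fractions$cell_type == cell_type &
                     fractions$sample_id %in% samples, , drop = FALSE]
  pre <- sub[sub$timepoint == "pre", ]
  on <- sub[sub$timepoint == "on", ]
  paired <- intersect(pre$sample_id, on$sample_id)
  n_dropped <- length(unique(sub$sample_id)) - length(paired)
  if (n_dropped > 0) {
    message("compare_on_treatment_change: excluded ", n_dropped,
            " sample(s) without both timepoints")
  }
  if (length(paired) < 2) stop("need >= 2 samples with both timepoints")
  d <- on$fraction[match(paired, on$sample_id)] -
    pre$fraction[match(paired, pre$sample_id)]
  if (all(d == 0)) stop("all paired differences are zero; test degenerate")
  wt <- suppressWarnings(stats::wilcox.test(d, alternative = "two.sided"))
  data.frame(cell_type = cell_type,
             contrast = "within_group_change",
             statistic = unname(wt$statistic),
             p_value = wt$p.value,
             n_pairs = length(paired),
             direction = sign(stats::median(d)),
             stringsAsFactors = FALSE)
}

#' Immune-contrast table across cell types
#'
#' Runs the between-group pre-treatment contrast for every cell type, and
#' the within-group on-treatment change separately in the high and the low
#' group. Raw p-values are primary; a Benjamini-Hochberg adjusted column
#' (within each contrast family) is emitted alongside, clearly labelled.
#'
#' @inheritParams compare_fractions_between_groups
#' @param cell_types Cell types to test; default: all present.
#' @param change If `TRUE` (default) also test on-treatment change when the
#'   table contains an `"on"` timepoint.
#' @return Data frame, one row per (cell type, contrast), columns as in the
#'   single-contrast functions plus `group` (for change contrasts) and
#'   `p_adjusted_bh`.
#' @export
immune_contrast_table <- function(fractions, groups, cell_types = NULL,
                                  change = TRUE) {
  fractions <- .check_fractions(fractions)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$sample_id)
  }
  if (is.null(cell_types)) cell_types <- unique(fractions$cell_type)
  rows <- list()
  for (ct in cell_types) {
    r <- compare_fractions_between_groups(fractions, groups, ct)
    r$group <- NA_character_
    r$n_pairs <- NA_integer_
    rows[[length(rows) + 1]] <- r
  }
  if (change && "on" %in% fractions$timepoint) {
    for (side in c("high", "low")) {
      members <- names(groups)[groups == side]
      for (ct in cell_types) {
        r <- tryCatch(
          compare_on_treatment_change(fractions, members, ct),
          error = function(e) NULL)
        if (is.null(r)) next
        r$group <- side
        r$n_high <- NA_integer_; r$n_low <- NA_integer_
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  cols <- c("cell_type", "contrast", "group", "statistic", "p_value",
            "n_high", "n_low", "n_pairs", "direction")
  out <- do.call(rbind, lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[, cols]
  }))
  out$p_adjusted_bh <- NA_real_
  for (fam in unique(out$contrast)) {
    i <- out$contrast == fam
    out$p_adjusted_bh[i] <- stats::p.adjust(out$p_value[i], method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Read an immune cell fraction table
#'
#' Long format has columns `sample_id`, `timepoint`, `cell_type`,
#' `fraction`; wide format has `sample_id`, `timepoint` and one column per
#' cell type, which is stacked to long form.
#'
#' @param path Path to the TSV.
#' @param format `"long"` (default) or `"wide"`.
#' @return Long-format data frame.
#' @export
read_immune_fractions <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "wide") {
    id <- c("sample_id", "timepoint")
    miss <- setdiff(id, names(tab))
    if (length(miss) > 0) {
      stop("wide immune table missing column(s): ",
           paste(miss, collapse = ", "))
    }
    cells <- setdiff(names(tab), id)
    tab <- data.frame(
      sample_id = rep(tab$sample_id, times = length(cells)),
      timepoint = rep(tab$timepoint, times = length(cells)),
      cell_type = rep(cells, each = nrow(tab)),
      fraction = as.numeric(unlist(tab[cells], use.names = FALSE)),
      stringsAsFactors = FALSE
    )
  }
  .check_fractions(tab)
}
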