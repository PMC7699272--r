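#' Validate a long-format qPCR CT table
#'
#' Expected columns: `sample` (id), `group` (`"bleomycin"` or `"control"`),
#' `day` (integer), `gene` (symbol), `ct` (threshold cycle). Reference
#' genes are identified either by an `is_reference` logical column or by
#' the `ref_genes` argument of the downstream functions (defaults B2M and
#' RLP13a).
#'
#' @param table data frame.
#' @return the table, invisibly, after checks.
#' @export
validate_ct_table <- function(table) {
  need <- c("sample", "group", "day", "gene", "ct")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("CT table is missing columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(table$ct)))
    stop("CT table contains non-finite CT values")
  if (any(table$ct <= 0 | table$ct >= 45))
    warning("CT values outside the usual (0, 45) cycle range")
  invisible(table)
}

#' Per-sample delta-CT against the geometric mean of two reference genes
#'
#' `dCT(sample, gene) = CT(gene) - mean(CT(ref1), CT(ref2))`. The
#' arithmetic mean of the reference CTs corresponds exactly to the
#' geometric mean of the reference expression levels on the `2^-CT` scale.
#'
#' @param table long-format CT table (see [validate_ct_table()]).
#' @param ref_genes the two reference gene symbols; if `NULL`, genes
#'   flagged by an `is_reference` column are used.
#' @return tibble of per-(sample, gene) rows with a `delta_ct` column;
#'   reference genes themselves are dropped from the output.
#' @export
delta_ct <- function(table, ref_genes = c("B2M", "RLP13a")) {
  validate_ct_table(table)
  table <- tibble::as_tibble(table)
  if (is.null(ref_genes)) {
    if (!"is_reference" %in% names(table))
      stop("ref_genes is NULL and the table has no is_reference column")
    ref_genes <- unique(table$gene[table$is_reference])
  }
  if (length(ref_genes) != 2L)
    stop("exactly two reference genes are required, got: ",
         paste(ref_genes, collapse = ", "))
  refs <- table[table$gene %in% ref_genes, ]
  ref_mean <- stats::aggregate(ct ~ sample, data = refs,
                               FUN = function(x) c(n = length(x), m = mean(x)))
  ref_tbl <- tibble::tibble(sample = ref_mean$sample,
                            n_ref = as.vector(ref_mean$ct[, "n"]),
                            ref_ct = as.vector(ref_mean$ct[, "m"]))
  targets <- table[!table$gene %in% ref_genes, ]
  bad <- setdiff(unique(targets$sample),
                 ref_tbl$sample[ref_tbl$n_ref == 2L])
  if (length(bad))
    stop("missing reference gene measurements for sample(s): ",
         paste(bad, collapse = ", "))
  out <- dplyr::left_join(targets, ref_tbl, by = "sample")
  out$delta_ct <- out$ct - out$ref_ct
  dplyr::select(out, dplyr::all_of(c("sample", "group", "day", "gene", "ct",
                                     "ref_ct", "delta_ct")))
}

#' Relative gene expression by the delta-delta-CT method
#'
#' Expression is referenced to the geometric mean of two reference genes
#' (see [delta_ct()]) and then normalised to the control group at the same
#' time point. The calibrator is applied on the linear expression scale:
#' `rel(sample) = 2^-dCT(sample) / mean(2^-dCT(controls, same gene & day))`,
#' so the control-group arithmetic mean is exactly 1 for every (gene, day).
#' The classical log-scale calibrator
#' `ddCT = dCT - mean(dCT controls)`, whose control geometric mean is 1,
#' is emitted alongside (`delta_delta_ct`, `rel_expression_classic`); with
#' a single control sample the two coincide.
#'
#' @param table long-format CT table.
#' @param ref_genes see [delta_ct()].
#' @return list with `samples` (per-sample tibble incl. `rel_expression`)
#'   and `summary` (per gene, group, day: mean, SEM on the fold-change
#'   scale, SEM of the log2 values, and n).
#' @export
relative_expression <- function(table, ref_genes = c("B2M", "RLP13a")) {
  d <- delta_ct(table, ref_genes)
  d$expression <- 2^(-d$delta_ct)
  ctrl <- d[d$group == "control", ]
  cal <- dplyr::summarise(
    dplyr::group_by(ctrl, .data$gene, .data$day),
    cal_expression = mean(.data$expression),
    cal_delta_ct = mean(.data$delta_ct), .groups = "drop")
  missing <- dplyr::anti_join(dplyr::distinct(d, .data$gene, .data$day),
                              cal, by = c("gene", "day"))
  if (nrow(missing))
    stop("no control samples for: ",
         paste(sprintf("%s day %s", missing$gene, missing$day),
               collapse = "; "))
  d <- dplyr::left_join(d, cal, by = c("gene", "day"))
  d$rel_expression <- d$expression / d$cal_expression
  d$delta_delta_ct <- d$delta_ct - d$cal_delta_ct
  d$rel_expression_classic <- 2^(-d$delta_delta_ct)
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  summary <- dplyr::summarise(
    dplyr::group_by(d, .data$gene, .data$group, .data$day),
    mean_rel = mean(.data$rel_expression),
    sem_rel = sem(.data$rel_expression),
    sem_log2 = sem(log2(.data$rel_expression)),
    n = dplyr::n(), .groups = "drop")
  list(samples = tibble::as_tibble(d), summary = summary)
}
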