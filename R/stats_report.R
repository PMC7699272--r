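#' Tiered significance symbols for the three comparison families
#'
#' Longitudinal bleomycin studies annotate three distinct families of
#' comparisons with distinct glyphs, each repeated once per significance
#' tier:
#'
#' * `vs_control_same_day`: bleomycin vs. saline control at the same time
#'   point — `*`
#' * `between_days_bleomycin`: different time points within the
#'   bleomycin-challenged group — `#`
#' * `vs_baseline_within_group`: a time point vs. baseline within one
#'   group (longitudinal measures) — `§`
#'
#' Tiers: p < 0.05 one glyph, p < 0.01 two, p < 0.001 three, p < 0.0001
#' four; p >= 0.05 yields an empty string.
#'
#' @param family one of the three family names (vectorised, recycled).
#' @param p p value(s) in `[0, 1]`.
#' @return character vector of symbol strings.
#' @examples
#' assign_symbol("vs_control_same_day", 0.004)        # "**"
#' assign_symbol("vs_baseline_within_group", 5e-5)    # four section signs
#' @export
assign_symbol <- function(family, p) {
  glyphs <- c(vs_control_same_day = "*", between_days_bleomycin = "#",
              vs_baseline_within_group = "§")
  family <- match.arg(family, names(glyphs), several.ok = TRUE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  n <- max(length(family), length(p))
  family <- rep_len(family, n)
  p <- rep_len(p, n)
  reps <- ifelse(p < 0.0001, 4L,
          ifelse(p < 0.001, 3L,
          ifelse(p < 0.01, 2L,
          ifelse(p < 0.05, 1L, 0L))))
  mapply(function(g, r) paste(rep(g, r), collapse = ""),
         glyphs[family], reps, USE.NAMES = FALSE)
}

#' Pairwise group comparisons with symbol annotation
#'
#' Compares a numeric readout between groups with either one-way ANOVA
#' followed by Bonferroni-adjusted pairwise post-hoc tests (pooled-SD
#' pairwise t tests, the classical Bonferroni post-hoc), or pairwise
#' Mann-Whitney (Wilcoxon rank-sum) tests. Statistical machinery is
#' delegated to the standard R routines; this function only orchestrates
#' the comparisons and applies the tiered symbol policy.
#'
#' @param table data frame with columns `value` and `group` (and
#'   optionally others, ignored).
#' @param family comparison family for the symbols (see
#'   [assign_symbol()]).
#' @param method `"anova_bonferroni"` or `"mann_whitney"`.
#' @return tibble with one row per group pair: `group1`, `group2`,
#'   `p_value` (Bonferroni-adjusted for the ANOVA path, raw for
#'   Mann-Whitney), `symbol`, `method`, `family`, plus the overall ANOVA
#'   `p_omnibus` where applicable.
#' @export
compare_groups <- function(table, family = "vs_control_same_day",
                           method = c("anova_bonferroni", "mann_whitney")) {
  method <- match.arg(method)
  stopifnot(all(c("value", "group") %in% names(table)))
  g <- factor(table$group)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(tabulate(g) < 2L)) stop("every group needs at least two values")
  v <- as.numeric(table$value)
  pairs <- utils::combn(levels(g), 2)
  p_omnibus <- NA_real_
  if (method == "anova_bonferroni") {
    fit <- aov(v ~ g)
    p_omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    pt <- pairwise.t.test(v, g, p.adjust.method = "bonferroni",
                          pool.sd = TRUE)$p.value
    p <- apply(pairs, 2, function(pr) {
      out <- pt[pr[2], pr[1]]
      if (is.na(out)) out <- pt[pr[1], pr[2]]
      out
    })
  } else {
    p <- apply(pairs, 2, function(pr) {
      wilcox.test(v[g == pr[1]], v[g == pr[2]], exact = FALSE)$p.value
    })
  }
  p <- pmin(p, 1)
  tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ], p_value = p,
                 symbol = assign_symbol(rep(family, length(p)), p),
                 method = method, family = family, p_omnibus = p_omnibus)
}
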