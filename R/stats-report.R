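#' Two-sided Mann-Whitney U comparison
#'
#' The package's group-comparison routine: a two-tailed Mann-Whitney
#' (Wilcoxon rank-sum) test, exact for small tie-free samples and
#' normal-approximated with tie correction otherwise (delegated to
#' [stats::wilcox.test()]). p-values below numeric resolution are flagged
#' as upper bounds.
#'
#' @param values_a,values_b Numeric vectors (each non-empty).
#' @param bound_threshold p-values below this are reported as upper
#'   bounds (default 1e-15).
#' @return List with `U` (statistic for the first sample), `p_value`,
#'   `p_is_upper_bound`, and group sizes.
#' @export
compare_groups <- function(values_a, values_b, bound_threshold = 1e-15) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  p <- if (wt$p.value < bound_threshold) bound_threshold else wt$p.value
  list(U = unname(wt$statistic), p_value = p,
       p_is_upper_bound = wt$p.value < bound_threshold,
       n_a = length(values_a), n_b = length(values_b))
}

#' Normalize values to a reference group
#'
#' Divides every value by the mean of the reference group -- the
#' "normalized to the mean of unperturbed control cells" convention used
#' by all intensity metrics.
#'
#' @param values Numeric vector.
#' @param reference_group Numeric vector with positive mean.
#' @return `values / mean(reference_group)`.
#' @export
normalize_to_reference <- function(values, reference_group) {
  if (length(reference_group) == 0) stop("empty reference group")
  ref <- mean(reference_group)
  if (ref <= 0) stop("reference mean must be > 0")
  values / ref
}

#' Group summary table with significance stars
#'
#' Per-group n and mean, plus the two-sided Mann-Whitney p-value of each
#' group against the reference group, annotated with the conventional
#' stars (NS > 0.05, * <= 0.05, ** <= 0.01, *** <= 0.001,
#' **** <= 0.0001).
#'
#' @param df data.frame with columns `value` and `group`.
#' @param reference_group Name of the reference group.
#' @return data.frame with `group`, `n`, `mean`, `p_value`, `stars`.
#' @export
group_summary <- function(df, reference_group) {
  ref <- df$value[df$group == reference_group]
  if (length(ref) == 0) stop("reference group absent")
  stars <- function(p) {
    if (p > 0.05) "NS" else if (p > 0.01) "*" else if (p > 0.001) "**"
    else if (p > 1e-4) "***" else "****"
  }
  out <- do.call(rbind, lapply(unique(df$group), function(gp) {
    v <- df$value[df$group == gp]
    p <- if (gp == reference_group) NA_real_
         else compare_groups(v, ref)$p_value
    data.frame(group = gp, n = length(v), mean = mean(v), p_value = p,
               stars = if (is.na(p)) "" else stars(p))
  }))
  rownames(out) <- NULL
  out
}
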