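#' Welch's unequal-variance t test
#'
#' Two-sided Welch test between two groups, as used for all scatter-plot
#' comparisons. Delegates to [stats::t.test()] (`var.equal = FALSE`) and
#' repackages `t`, the Welch-Satterthwaite degrees of freedom, and the
#' two-sided p value. Degenerate input (both variances zero) yields
#' `t = 0, p = 1` when the means agree and an error otherwise.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' welch_t(c(90, 92, 100), c(130, 140, 150))
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b),
                  n_a = length(a), n_b = length(b)))
    }
    stop("degenerate variances: both groups constant with unequal means")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Significance star label for a p value
#'
#' Conventional star tiers: `****` for p < 0.0001, `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p p value in `[0, 1]`.
#' @return character label.
#' @export
significance_label <- function(p) {
  stopifnot_scalar_num(p, "p")
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]")
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

category_schemes <- list(
  capture3 = c("none", "some", "most"),
  dependency3 = c("golgi_puncta", "secretion_sites", "hybrid")
)

#' Tabulate blinded categorical assignments
#'
#' Counts and fractions per condition for the visual-scoring assays. Two
#' schemes are built in: `capture3` (`none` / `some` / `most` of the
#' bud-neck cargo signal outside Golgi cisternae) and `dependency3`
#' (`golgi_puncta` / `secretion_sites` / `hybrid` localization patterns).
#' Cells that cannot be confidently assigned may be labeled `other` in
#' either scheme. Fractions sum to 1 within each condition.
#'
#' @param assignments data frame with columns `condition` and `category`
#'   (the human-assigned category per cell).
#' @param scheme `"capture3"` or `"dependency3"`.
#' @return tibble of class `category_table`: `condition`, `category`,
#'   `count`, `fraction`; attribute `scheme`.
#' @export
tabulate_categories <- function(assignments, scheme = c("capture3", "dependency3")) {
  scheme <- match.arg(scheme)
  cats <- c(category_schemes[[scheme]], "other")
  if (!all(c("condition", "category") %in% names(assignments)))
    stop("`assignments` needs columns `condition` and `category`")
  bad <- setdiff(unique(assignments$category), cats)
  if (length(bad))
    stop(sprintf("unknown category for scheme '%s': %s", scheme,
                 paste(bad, collapse = ", ")))
  out <- lapply(split(assignments, assignments$condition), function(d) {
    if (!nrow(d)) stop("empty condition")
    counts <- table(factor(d$category, levels = cats))
    tibble::tibble(condition = d$condition[1], category = cats,
                   count = as.integer(counts),
                   fraction = as.numeric(counts) / nrow(d))
  })
  res <- do.call(rbind, out)
  attr(res, "scheme") <- scheme
  class(res) <- c("category_table", class(res))
  res
}

#' Per-group mean, SD and n for scatter plots
#'
#' Sample mean, sample SD (n - 1 denominator) and n per group, the summary
#' drawn as thick (mean) and thin (SD) horizontal bars on scatter plots.
#' Single-value groups have no defined SD; it is reported as 0 with
#' `sd_defined = FALSE`.
#'
#' @param groups named list of numeric vectors, or a data frame with columns
#'   `group` and `value`.
#' @return tibble: `group`, `n`, `mean`, `sd`, `sd_defined`.
#' @export
summarize_scatter <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (length(v) < 1) stop(sprintf("group '%s' is empty", g))
    s <- if (length(v) > 1) sd(v) else 0
    tibble::tibble(group = g, n = length(v), mean = mean(v), sd = s,
                   sd_defined = length(v) > 1)
  })
  do.call(rbind, rows)
}
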