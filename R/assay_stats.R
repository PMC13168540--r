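#' Lysis fractions from viability counts
#'
#' Per replicate, the lysed fraction is `100 * pi_positive / total_cells`
#' (propidium-iodide-positive cells have compromised membranes); per group
#' the mean, SD, and replicate count are reported.
#'
#' @param records data.frame with columns `group`, `total_cells`,
#'   `pi_positive` (one row per replicate), as produced by
#'   [gen_viability_experiment()].
#' @return data.frame with columns `group`, `mean`, `sd`, `n` (percent).
#' @export
lysis_fraction <- function(records) {
  stopifnot(all(c("group", "total_cells", "pi_positive") %in% names(records)))
  if (any(records$total_cells <= 0))
    stop("total_cells must be > 0", call. = FALSE)
  if (any(records$pi_positive < 0 |
          records$pi_positive > records$total_cells))
    stop("pi_positive must lie in [0, total_cells]", call. = FALSE)
  pct <- 100 * records$pi_positive / records$total_cells
  out <- do.call(rbind, lapply(split(pct, records$group), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[match(unique(records$group), out$group), , drop = FALSE]
}

#' Internal-standard quantification
#'
#' `amount = (analyte_area / istd_area) * istd_amount / response_factor`,
#' the standard arithmetic for internal-standard-based GC-MS/LC-MS
#' quantification.
#'
#' @param analyte_area integrated analyte peak area (>= 0).
#' @param istd_area internal-standard peak area (> 0).
#' @param istd_amount known amount of internal standard added.
#' @param response_factor relative response factor (> 0), default 1.
#' @return analyte amount in the unit of `istd_amount`.
#' @export
quantify_internal_standard <- function(analyte_area, istd_area, istd_amount,
                                       response_factor = 1) {
  if (any(istd_area <= 0) || any(response_factor <= 0) ||
      any(istd_amount <= 0))
    stop("istd_area, istd_amount and response_factor must be > 0",
         call. = FALSE)
  if (any(analyte_area < 0)) stop("analyte_area must be >= 0", call. = FALSE)
  (analyte_area / istd_area) * istd_amount / response_factor
}

#' Partition (fraction-localization) profile
#'
#' Converts per-fraction amounts (LC-MS response or concentration) into
#' relative percentages summing to 100 per compound. The canonical fraction
#' order is free/supernatant, yeast wash, membrane wash, membrane.
#'
#' @param amounts named non-negative numeric vector of per-fraction amounts;
#'   at least one must be nonzero.
#' @return list of class `"partition_profile"`: `amounts`, `relative`
#'   (percent, sums to 100).
#' @export
fraction_profile <- function(amounts) {
  if (is.null(names(amounts)) || any(!nzchar(names(amounts))))
    stop("'amounts' must be a named vector of fractions", call. = FALSE)
  if (any(amounts < 0)) stop("amounts must be >= 0", call. = FALSE)
  total <- sum(amounts)
  if (total == 0)
    stop("undefined profile: all fraction amounts are zero", call. = FALSE)
  structure(list(amounts = amounts, relative = 100 * amounts / total),
            class = "partition_profile")
}

#' @export
print.partition_profile <- function(x, ...) {
  cat("partition_profile (%):\n")
  print(round(x$relative, 2))
  invisible(x)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

#' Compare groups by Welch t test or one-way ANOVA with Tukey HSD
#'
#' Two groups are compared by a two-sided Welch (unequal-variance)
#' independent t test; more than two by one-way ANOVA followed by a Tukey
#' HSD post hoc. Significance stars follow the usual thresholds:
#' `P < 0.05` (*), `P < 0.01` (**), `P < 0.001` (***), `ns` otherwise.
#' Groups with zero variance that are exactly identical yield p = 1 with a
#' warning rather than an error.
#'
#' @param values numeric observations.
#' @param group group labels, parallel to `values`; >= 2 groups with >= 2
#'   observations each.
#' @param design `"auto"` (default: by group count), `"two-sample"`, or
#'   `"oneway"`.
#' @param posthoc post hoc method for > 2 groups (only `"tukey"`).
#' @return list of class `"group_comparison"`: `method`, `p` (overall
#'   p-value), `stars`, and for ANOVA a `posthoc` data.frame with pairwise
#'   adjusted p-values and stars.
#' @export
compare_groups <- function(values, group,
                           design = c("auto", "two-sample", "oneway"),
                           posthoc = "tukey") {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  if (design == "auto")
    design <- if (nlevels(group) == 2L) "two-sample" else "oneway"

  if (all(tapply(values, group, stats::var) == 0)) {
    means <- tapply(values, group, mean)
    if (max(means) - min(means) == 0) {
      warning("all groups identical with zero variance; p reported as 1",
              call. = FALSE)
      return(structure(list(method = design, p = 1, stars = "ns",
                            posthoc = NULL), class = "group_comparison"))
    }
  }
  if (design == "two-sample") {
    if (nlevels(group) != 2L)
      stop("'two-sample' design requires exactly 2 groups", call. = FALSE)
    tt <- stats::t.test(values ~ group, var.equal = FALSE)
    return(structure(list(method = "Welch t test", p = tt$p.value,
                          stars = p_stars(tt$p.value), posthoc = NULL,
                          statistic = unname(tt$statistic)),
                     class = "group_comparison"))
  }
  fit <- stats::aov(values ~ group)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  ph <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                   p_adj = tk[, "p adj"], stars = p_stars(tk[, "p adj"]),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(method = "one-way ANOVA + Tukey HSD", p = p,
                 stars = p_stars(p), posthoc = ph,
                 statistic = summary(fit)[[1]][["F value"]][1]),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %s, p = %.4g (%s)\n", x$method, x$p,
              x$stars))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}
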