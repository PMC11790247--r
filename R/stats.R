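#' Iterated Grubbs outlier gate
#'
#' Repeatedly applies the two-sided single-outlier Grubbs test, removing the
#' most extreme value while it exceeds the critical value at `alpha`, as used
#' to gate STED-derived quantities before group comparison. Critical values
#' are computed from the t-distribution:
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level (default 0.05).
#' @return list with `retained`, `removed` (values, in removal order) and
#'   `log` (data.frame `value`, `G`, `G_crit`, `n` per removal test).
#' @export
grubbs_outliers <- function(values, alpha = 0.05) {
  x <- as.numeric(values)
  if (length(x) < 3L)
    ais_error("Grubbs test undefined for n < 3", "ais_bad_input")
  removed <- numeric(0)
  log <- data.frame(value = numeric(0), G = numeric(0),
                    G_crit = numeric(0), n = integer(0))
  repeat {
    n <- length(x)
    if (n < 3L) break
    s <- sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    tcrit <- qt(1 - alpha / (2 * n), n - 2)
    G_crit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    log <- rbind(log, data.frame(value = x[i], G = G, G_crit = G_crit, n = n))
    if (G <= G_crit) break
    removed <- c(removed, x[i])
    x <- x[-i]
  }
  list(retained = x, removed = removed, log = log)
}

group_summaries <- function(values, groups) {
  lv <- unique(groups)
  do.call(rbind, lapply(lv, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               median = median(v), sd = sd(v), stringsAsFactors = FALSE)
  }))
}

groups_normal <- function(values, groups, alpha = 0.05) {
  all(vapply(unique(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 3L || length(unique(v)) == 1L) return(TRUE)
    if (length(v) > 5000L) v <- sample(v, 5000L)
    shapiro.test(v)$p.value >= alpha
  }, TRUE))
}

# Dunn's post-hoc test on the joint ranks of a Kruskal-Wallis design, with
# tie correction and Bonferroni adjustment over all pairwise contrasts.
dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- unique(groups)
  pairs <- t(combn(length(lv), 2))
  m <- nrow(pairs)
  do.call(rbind, lapply(seq_len(m), function(k) {
    gi <- lv[pairs[k, 1]]; gj <- lv[pairs[k, 2]]
    ri <- r[groups == gi]; rj <- r[groups == gj]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / length(ri) + 1 / length(rj)))
    z <- (mean(ri) - mean(rj)) / se
    data.frame(contrast = paste(gi, "-", gj), z = z,
               p_adj = min(1, 2 * pnorm(-abs(z)) * m),
               stringsAsFactors = FALSE)
  }))
}

#' Normality-gated group comparison
#'
#' Implements the branching test scheme used throughout: per-group normality
#' is assessed by Shapiro-Wilk at `normality_alpha`; two normal groups get a
#' t-test (paired when `pairing_ids` are supplied), two non-normal groups the
#' Mann-Whitney test (paired: Wilcoxon signed-rank); more than two groups get
#' one-way ANOVA with Tukey's post-hoc when normal, Kruskal-Wallis with
#' Dunn's post-hoc (Bonferroni-adjusted) otherwise. The branch taken is
#' recorded in `test_name`.
#'
#' @param values numeric measurements.
#' @param groups group label per value (>= 2 groups, each n >= 2).
#' @param pairing_ids optional pairing identifiers; paired analyses require
#'   complete pairs across exactly two groups.
#' @param normality_alpha Shapiro-Wilk level (default 0.05). Groups too small
#'   to test (n < 3) are treated as normal.
#' @param force_test override the gate: `"t"`, `"mw"`, `"anova"`,
#'   `"kruskal"`, or `NULL` (gate decides).
#' @return a `comparison_result`: list with `test_name`, `statistic`,
#'   `p_value`, `group_summaries` (data.frame) and `posthoc` (data.frame or
#'   NULL).
#' @export
compare_groups <- function(values, groups, pairing_ids = NULL,
                           normality_alpha = 0.05, force_test = NULL) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  if (length(values) != length(groups))
    ais_error("values and groups differ in length", "ais_bad_input")
  lv <- unique(groups)
  if (length(lv) < 2L) ais_error("need >= 2 groups", "ais_bad_input")
  if (any(table(groups) < 2L)) ais_error("each group needs n >= 2", "ais_bad_input")
  paired <- !is.null(pairing_ids)
  if (paired) {
    if (length(lv) != 2L)
      ais_error("paired analysis requires exactly 2 groups", "ais_bad_input")
    a <- values[groups == lv[1]][order(pairing_ids[groups == lv[1]])]
    b <- values[groups == lv[2]][order(pairing_ids[groups == lv[2]])]
    if (length(a) != length(b) ||
        !identical(sort(pairing_ids[groups == lv[1]]),
                   sort(pairing_ids[groups == lv[2]])))
      ais_error("unequal pair structure in paired mode", "ais_bad_input")
  }
  normal <- groups_normal(values, groups, normality_alpha)
  branch <- if (!is.null(force_test)) force_test
  else if (length(lv) == 2L) (if (normal) "t" else "mw")
  else (if (normal) "anova" else "kruskal")
  summaries <- group_summaries(values, groups)
  posthoc <- NULL
  if (branch == "t") {
    if (paired && sd(a - b) == 0) {
      # zero-variance differences: the paired statistic is undefined
      return(structure(list(test_name = "paired t-test (degenerate differences)",
                            statistic = NA_real_, p_value = NA_real_,
                            group_summaries = summaries, posthoc = NULL),
                       class = "comparison_result"))
    }
    ht <- if (paired) t.test(a, b, paired = TRUE)
    else t.test(values[groups == lv[1]], values[groups == lv[2]],
                var.equal = TRUE)
    name <- if (paired) "paired t-test" else "unpaired t-test"
    stat <- unname(ht$statistic); p <- ht$p.value
  } else if (branch == "mw") {
    ht <- if (paired) suppressWarnings(wilcox.test(a, b, paired = TRUE))
    else suppressWarnings(wilcox.test(values[groups == lv[1]],
                                      values[groups == lv[2]]))
    name <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
    stat <- unname(ht$statistic); p <- ht$p.value
  } else if (branch == "anova") {
    d <- data.frame(v = values, g = factor(groups))
    fit <- aov(v ~ g, data = d)
    av <- summary(fit)[[1]]
    stat <- av[["F value"]][1]; p <- av[["Pr(>F)"]][1]
    name <- "one-way ANOVA + Tukey"
    tk <- TukeyHSD(fit)$g
    posthoc <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE)
  } else if (branch == "kruskal") {
    ht <- kruskal.test(values, factor(groups))
    stat <- unname(ht$statistic); p <- ht$p.value
    name <- "Kruskal-Wallis + Dunn"
    posthoc <- dunn_posthoc(values, groups)
  } else ais_error("unknown test branch", "ais_bad_input")
  structure(list(test_name = name, statistic = stat, p_value = p,
                 group_summaries = summaries, posthoc = posthoc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  print(x$group_summaries, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("post-hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Paired longitudinal analysis of AIS lengths
#'
#' For repeated measurements of the same AIS (e.g. two imaging sessions one
#' week apart): a paired t-test on the within-AIS differences plus an
#' ordinary least-squares regression of the second session on the first with
#' its r². Identical sessions give zero-variance differences: the paired
#' test is then degenerate and flagged rather than computed.
#'
#' @param week1,week2 numeric length vectors, same order.
#' @param pairs optional pair identifiers (defaults to index pairing).
#' @return list with `comparison` (a `comparison_result`; `test_name`
#'   `"paired t-test (degenerate differences)"` with `p_value = NA` when the
#'   differences have zero variance) and `regression` (list `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`).
#' @export
longitudinal_analysis <- function(week1, week2, pairs = seq_along(week1)) {
  if (length(week1) != length(week2))
    ais_error("week1 and week2 differ in length", "ais_bad_input")
  if (anyDuplicated(pairs)) ais_error("pair ids must be unique", "ais_bad_input")
  n <- length(week1)
  d <- week2 - week1
  summaries <- group_summaries(c(week1, week2),
                               rep(c("week1", "week2"), each = n))
  if (sd(d) == 0) {
    comparison <- structure(list(
      test_name = "paired t-test (degenerate differences)",
      statistic = NA_real_, p_value = NA_real_,
      group_summaries = summaries, posthoc = NULL),
      class = "comparison_result")
  } else {
    comparison <- compare_groups(c(week1, week2),
                                 rep(c("week1", "week2"), each = n),
                                 pairing_ids = c(pairs, pairs),
                                 force_test = "t")
  }
  if (var(week1) == 0) {
    regression <- list(slope = NA_real_, intercept = NA_real_,
                       r_squared = if (var(week2) == 0) 1 else NA_real_,
                       p_value = NA_real_, n = n)
  } else {
    fit <- lm(week2 ~ week1)
    sm <- suppressWarnings(summary(fit))  # perfect fits are handled above
    regression <- list(slope = unname(coef(fit)[2]),
                       intercept = unname(coef(fit)[1]),
                       r_squared = sm$r.squared,
                       p_value = unname(sm$coefficients[2, 4]),
                       n = n)
  }
  list(comparison = comparison, regression = regression)
}

#' Condition-level plasticity summary
#'
#' Aggregates per-AIS measurements to the statistical unit of the plasticity
#' design (the culture): per condition the mean of per-OTC means, the SD
#' across OTC means, the median, and n = number of OTCs; then compares
#' conditions on the per-OTC means (unpaired t-test for two conditions,
#' one-way ANOVA + Tukey for more). A condition with fewer than two OTCs is
#' summarized but excluded from comparison, with a note.
#'
#' @param measurements data.frame with columns `condition`, `otc` and a
#'   measurement column.
#' @param value column name of the measurement (default `"length"`).
#' @param unit aggregation unit: `"otc"` (default) or `"ais"` (pool AIS,
#'   non-default).
#' @return list with `table` (per-condition summary data.frame),
#'   `comparison` (a `comparison_result` or NULL), `notes` (character).
#' @export
plasticity_summary <- function(measurements, value = "length",
                               unit = c("otc", "ais")) {
  unit <- match.arg(unit)
  need <- c("condition", "otc", value)
  if (!all(need %in% names(measurements)))
    ais_error(sprintf("measurements must have columns %s",
                      paste(need, collapse = ", ")), "ais_bad_input")
  v <- measurements[[value]]
  ok <- !is.na(v)
  measurements <- measurements[ok, ]
  v <- v[ok]
  if (unit == "otc") {
    agg <- aggregate(v, by = list(condition = measurements$condition,
                                  otc = measurements$otc), FUN = mean)
    names(agg)[3] <- "value"
  } else {
    agg <- data.frame(condition = measurements$condition,
                      otc = measurements$otc, value = v)
  }
  tab <- do.call(rbind, lapply(unique(agg$condition), function(cn) {
    u <- agg$value[agg$condition == cn]
    data.frame(condition = cn, n = length(u), mean = mean(u),
               median = median(u), sd = sd(u), stringsAsFactors = FALSE)
  }))
  notes <- character(0)
  usable <- tab$condition[tab$n >= 2]
  comparison <- NULL
  if (length(usable) < length(tab$condition))
    notes <- c(notes, sprintf("condition(s) excluded from comparison (n < 2): %s",
                              paste(setdiff(tab$condition, usable),
                                    collapse = ", ")))
  if (length(usable) >= 2L) {
    sel <- agg$condition %in% usable
    comparison <- compare_groups(agg$value[sel], agg$condition[sel],
                                 force_test = if (length(usable) == 2L) "t"
                                 else "anova")
  } else {
    notes <- c(notes, "comparison refused: fewer than 2 conditions with n >= 2")
  }
  list(table = tab, comparison = comparison, notes = notes)
}
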