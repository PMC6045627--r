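# Per-animal aggregation and group-comparison statistics. The statistical
# unit is the animal: per-object measurements are averaged within animal
# before testing, avoiding pseudoreplication across objects of one mouse.

#' Significance stars for a p-value
#'
#' Thresholds 0.05 / 0.01 / 0.001 / 0.0001 mapped to * / ** / *** / ****;
#' "ns" otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes.
#' @export
significanceStars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

# fetch the (g1, g2) entries of a pairwise.*.test p-value matrix, whichever
# triangle they live in
.pairwise_lookup <- function(m, pairs) {
  vapply(seq_len(nrow(pairs)), function(k) {
    g1 <- pairs[k, 1]; g2 <- pairs[k, 2]
    v <- c(if (g2 %in% rownames(m) && g1 %in% colnames(m)) m[g2, g1] else NA,
           if (g1 %in% rownames(m) && g2 %in% colnames(m)) m[g1, g2] else NA)
    v[!is.na(v)][1]
  }, 0)
}

#' Aggregate per-object records to a long per-animal table
#'
#' Objects (bronchioles, airspaces, sections) measured within one animal are
#' averaged first, so each animal contributes one value per metric. Rows
#' with the same (group, animal, metric) key are reduced to their mean;
#' aggregation is invariant to row order.
#'
#' @param records \code{data.frame} of per-object measurements carrying an
#'   \code{animal_id} column plus numeric metric columns (e.g. the CSVs
#'   emitted by the morphometry, collagen and emphysema modules, joined with
#'   animal ids).
#' @param groups \code{data.frame} with columns \code{animal_id} and
#'   \code{group} assigning each animal to an exposure group.
#' @param metrics character vector of metric column names; defaults to all
#'   numeric columns of \code{records} except ids.
#' @param level aggregation level; only "animal" is supported as the default
#'   statistical unit, "object" keeps every object as one row (exploratory).
#' @return long \code{data.frame}: group, animal_id, metric, value.
#' @export
aggregateByAnimal <- function(records, groups, metrics = NULL,
                              level = c("animal", "object")) {
  level <- match.arg(level)
  if (!"animal_id" %in% names(records)) stop("records need an animal_id column")
  if (!all(c("animal_id", "group") %in% names(groups)))
    stop("groups need animal_id and group columns")
  if (is.null(metrics)) {
    num <- vapply(records, is.numeric, logical(1))
    metrics <- setdiff(names(records)[num],
                       c("animal_id", "bronchiole_id", "airspace_id",
                         "n_measures"))
  }
  miss <- setdiff(unique(records$animal_id), groups$animal_id)
  if (length(miss))
    stop("missing group labels for animal(s): ", paste(miss, collapse = ", "))
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(animal_id = records$animal_id, metric = m,
               value = records[[m]], stringsAsFactors = FALSE)
  }))
  if (level == "animal") {
    agg <- stats::aggregate(value ~ animal_id + metric, long, mean)
  } else agg <- long
  agg$group <- groups$group[match(agg$animal_id, groups$animal_id)]
  agg[order(agg$metric, agg$group, agg$animal_id),
      c("group", "animal_id", "metric", "value")]
}

#' Per-group mean and standard error of the mean
#'
#' @param table long table from \code{\link{aggregateByAnimal}}.
#' @param metric metric name to summarize.
#' @return \code{data.frame}: group, n, mean, sem.
#' @export
groupSummary <- function(table, metric) {
  tb <- table[table$metric == metric, ]
  if (!nrow(tb)) stop("metric not found: ", metric)
  out <- do.call(rbind, lapply(split(tb$value, tb$group), function(v)
    data.frame(n = length(v), mean = mean(v),
               sem = if (length(v) > 1) .sem(v) else NA_real_)))
  data.frame(group = rownames(out), out, row.names = NULL)
}

#' Compare exposure groups for one metric
#'
#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons (pooled-SD t
#' tests, each raw p multiplied by the number of comparisons and capped at
#' 1), or the Kruskal-Wallis rank test with Bonferroni-adjusted pairwise
#' Wilcoxon tests for non-parametric data. Data are summarized as mean plus
#' or minus SEM per group; pairs are starred at the 0.05 / 0.01 / 0.001 /
#' 0.0001 thresholds.
#'
#' When every group has zero within-group variance and all group means are
#' equal the F statistic is undefined; the comparison is reported as
#' non-significant with a warning rather than failing.
#'
#' @param table long table from \code{\link{aggregateByAnimal}}.
#' @param metric metric name to test.
#' @param test "anova_bonferroni" (default) or "kruskal_wallis".
#' @return list of class \code{"ComparisonResult"}: metric, test,
#'   \code{overall} (statistic, p), \code{pairwise} (\code{data.frame}:
#'   group1, group2, p_adj, stars), \code{groups} (mean +/- SEM table).
#' @export
compareGroups <- function(table, metric,
                          test = c("anova_bonferroni", "kruskal_wallis")) {
  test <- match.arg(test)
  tb <- table[table$metric == metric, ]
  if (!nrow(tb)) stop("metric not found: ", metric)
  tb$group <- factor(tb$group)
  if (nlevels(tb$group) < 2L) stop("need at least 2 groups")
  if (any(tabulate(tb$group) < 2L)) stop("need at least 2 animals per group")
  gstats <- groupSummary(tb, metric)
  lv <- levels(tb$group)
  pairs <- t(utils::combn(lv, 2L))
  degenerate <- all(vapply(split(tb$value, tb$group), stats::sd, 0) == 0) &&
    length(unique(tb$value)) == 1L
  if (degenerate) {
    warning("zero within-group variance with equal means: F undefined; ",
            "reported as non-significant")
    pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                     p_adj = 1, stars = "ns")
    overall <- c(statistic = NA_real_, p = 1)
  } else if (test == "anova_bonferroni") {
    fit <- stats::aov(value ~ group, data = tb)
    sm <- summary(fit)[[1]]
    overall <- c(statistic = sm$`F value`[1], p = sm$`Pr(>F)`[1])
    pt <- stats::pairwise.t.test(tb$value, tb$group, pool.sd = TRUE,
                                 p.adjust.method = "bonferroni")
    padj <- .pairwise_lookup(pt$p.value, pairs)
    pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                     p_adj = padj, stars = significanceStars(padj))
  } else {
    kt <- stats::kruskal.test(value ~ group, data = tb)
    overall <- c(statistic = unname(kt$statistic), p = kt$p.value)
    pt <- suppressWarnings(
      stats::pairwise.wilcox.test(tb$value, tb$group,
                                  p.adjust.method = "bonferroni"))
    padj <- .pairwise_lookup(pt$p.value, pairs)
    pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                     p_adj = padj, stars = significanceStars(padj))
  }
  structure(list(metric = metric, test = test, overall = overall,
                 pairwise = pw, groups = gstats),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("Group comparison for '%s' (%s)\n", x$metric, x$test))
  cat(sprintf("  overall: statistic %.4g, p = %.4g\n",
              x$overall["statistic"], x$overall["p"]))
  cat("  groups (mean +/- SEM):\n")
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("    %-10s n=%d  %.4g +/- %.4g\n", x$groups$group[i],
                x$groups$n[i], x$groups$mean[i], x$groups$sem[i]))
  cat("  pairwise (Bonferroni-adjusted):\n")
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("    %s vs %s: p_adj = %.4g %s\n", x$pairwise$group1[i],
                x$pairwise$group2[i], x$pairwise$p_adj[i],
                x$pairwise$stars[i]))
  invisible(x)
}
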