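## Group statistics: one-way ANOVA (raw values or printed summary
## statistics), pooled-variance pairwise t tests with Benjamini-Hochberg
## FDR adjustment and Cohen's d, Pearson correlation, questionnaire domain
## scoring, and the composite group-comparison report.

#' One-way ANOVA on raw values
#'
#' @param values numeric outcome.
#' @param groups group membership (factor or character), >= 2 groups with
#'   n >= 2 each.
#' @return List of class \code{msTestResult}: \code{statistic} (F),
#'   \code{df} (c(k-1, N-k)), \code{p}.
#' @export
anovaOneway <- function(values, groups) {
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) stop("at least 2 groups required")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  if (all(tapply(values, groups, var) == 0))
    stop("zero within-group variance everywhere: F is undefined")
  fit <- anova(lm(values ~ groups))
  out <- list(statistic = fit$`F value`[1],
              df = as.numeric(c(fit$Df[1], fit$Df[2])), p = fit$`Pr(>F)`[1])
  class(out) <- "msTestResult"
  out
}

#' One-way ANOVA from printed group summaries
#'
#' Recovers the F statistic from per-group means, standard deviations and
#' sizes via the standard decomposition: between-group sum of squares
#' SSb = sum n_i (m_i - m)^2 and within SSw = sum (n_i - 1) sd_i^2, with
#' F = [SSb / (k-1)] / [SSw / (N-k)]. Lets printed summary tables be checked
#' without the raw data.
#'
#' @param means,sds,ns per-group mean, SD and size vectors.
#' @return An \code{msTestResult} as in \code{\link{anovaOneway}}.
#' @export
anovaFromSummary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k)
    stop("means, sds, ns must have one entry per group, >= 2 groups")
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("standard deviations must be nonnegative")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0) stop("zero within-group variance everywhere: F is undefined")
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  out <- list(statistic = f, df = c(k - 1, N - k),
              p = pf(f, k - 1, N - k, lower.tail = FALSE))
  class(out) <- "msTestResult"
  out
}

#' @export
print.msTestResult <- function(x, ...) {
  if (length(x$df) == 2)
    cat(sprintf("F(%d, %d) = %.4g, p = %.4g\n", x$df[1], x$df[2],
                x$statistic, x$p))
  else
    cat(sprintf("t(%g) = %.4g, p = %.4g\n", x$df, x$statistic, x$p))
  invisible(x)
}

#' Independent-samples t test for one pair of groups
#'
#' Pooled-variance (Student) by default; Welch by flag. Two-sided p.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param variant "pooled" (default) or "welch".
#' @return An \code{msTestResult} with \code{statistic} (t), \code{df},
#'   \code{p}.
#' @export
pairwiseT <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("n >= 2 required in each group")
  tt <- t.test(a, b, var.equal = (variant == "pooled"))
  out <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value)
  class(out) <- "msTestResult"
  out
}

#' Cohen's d for two independent groups
#'
#' (mean(a) - mean(b)) divided by the pooled standard deviation with
#' (n_i - 1) weights; the a-minus-b ordering fixes the sign.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return Effect size d.
#' @export
cohensD <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("n >= 2 required in each group")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
         (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled variance: d is undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (via \code{p.adjust}) and the rejection set at
#' level alpha.
#'
#' @param p raw p values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return List with \code{p_adjusted} and logical \code{rejected}.
#' @export
fdrBH <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= alpha)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors, n >= 3, nonzero variance.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
pearsonCorr <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("n >= 3 required")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Default 30-item to 10-domain questionnaire mapping
#'
#' Consecutive triplets of the 30 resting-state items, in the inventory's
#' domain order. The mapping is a configuration: pass a modified copy to
#' \code{\link{arsqDomains}} for instruments with a different item order.
#'
#' @return Named list: domain name -> integer item indices.
#' @export
arsqDefaultMapping <- function() {
  domains <- c("discontinuity_of_mind", "theory_of_mind", "self", "planning",
               "sleepiness", "comfort", "somatic_awareness", "health_concern",
               "visual_thought", "verbal_thought")
  setNames(lapply(seq_along(domains),
                  function(d) (d - 1L) * 3L + 1:3), domains)
}

#' Resting-state questionnaire domain scores
#'
#' Sums each subject's three 1-5 Likert items per domain, yielding ten
#' domain scores in [3, 15].
#'
#' @param itemTable data.frame/matrix with 30 item columns (named item01..
#'   item30 or given by the mapping); extra id columns are carried through.
#' @param mapping domain -> item-index list (default
#'   \code{\link{arsqDefaultMapping}}).
#' @return data.frame of id columns plus one score column per domain.
#' @export
arsqDomains <- function(itemTable, mapping = arsqDefaultMapping()) {
  itemCols <- grep("^item[0-9]+$", names(itemTable), value = TRUE)
  if (length(itemCols) != 30)
    stop("expected 30 item columns (item01..item30), found ",
         length(itemCols))
  items <- as.matrix(itemTable[, sort(itemCols)])
  bad <- which(items < 1 | items > 5 | items != round(items), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("item value out of 1-5 range: row %d, %s",
                 bad[1, 1], sort(itemCols)[bad[1, 2]]))
  idCols <- setdiff(names(itemTable), itemCols)
  out <- itemTable[, idCols, drop = FALSE]
  for (d in names(mapping))
    out[[d]] <- rowSums(items[, mapping[[d]], drop = FALSE])
  out
}

#' Composite group-comparison report
#'
#' For every (parameter, state) cell of a metrics table: the one-way ANOVA
#' across groups, followed by all pairwise pooled-variance t tests with
#' Cohen's d; pairwise p values are FDR-adjusted within the cell's family
#' of pairwise tests (per-parameter families, matching figure-wise
#' reporting; set \code{family = "global"} to pool all pairwise tests).
#'
#' @param metrics a metrics data.frame from \code{\link{metricsTable}} with
#'   a non-NA \code{group} column.
#' @param parameters metric columns to analyze (default the four temporal
#'   parameters).
#' @param family "per-parameter" (default) or "global" FDR family.
#' @param alpha FDR level (default 0.05).
#' @return data.frame with one ANOVA row and one row per group pair for
#'   each (state, parameter): test, state, parameter, group_a, group_b,
#'   statistic, df1, df2, p_raw, p_fdr, cohens_d.
#' @export
groupComparisonReport <- function(metrics,
                                  parameters = c("gev_pct", "duration_ms",
                                                 "coverage_pct",
                                                 "occurrence_per_s"),
                                  family = c("per-parameter", "global"),
                                  alpha = 0.05) {
  family <- match.arg(family)
  if (all(is.na(metrics$group))) stop("metrics table carries no groups")
  states <- unique(metrics$state)
  grps <- unique(metrics$group)
  if (length(grps) < 2) stop("at least 2 groups required")
  pairs <- utils::combn(grps, 2, simplify = FALSE)
  rows <- list()
  for (param in parameters) for (st in states) {
    sub <- metrics[metrics$state == st, ]
    vals <- sub[[param]]; g <- sub$group
    an <- anovaOneway(vals, g)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "anova", state = st, parameter = param,
      group_a = NA, group_b = NA, statistic = an$statistic,
      df1 = an$df[1], df2 = an$df[2], p_raw = an$p, p_fdr = NA,
      cohens_d = NA, stringsAsFactors = FALSE)
    for (pr in pairs) {
      a <- vals[g == pr[1]]; b <- vals[g == pr[2]]
      tt <- pairwiseT(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "pairwise_t", state = st, parameter = param,
        group_a = pr[1], group_b = pr[2], statistic = tt$statistic,
        df1 = tt$df, df2 = NA, p_raw = tt$p, p_fdr = NA,
        cohens_d = cohensD(a, b), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  pw <- out$test == "pairwise_t"
  if (family == "global") {
    out$p_fdr[pw] <- fdrBH(out$p_raw[pw], alpha)$p_adjusted
  } else {
    for (param in parameters) for (st in states) {
      sel <- pw & out$parameter == param & out$state == st
      out$p_fdr[sel] <- fdrBH(out$p_raw[sel], alpha)$p_adjusted
    }
  }
  out
}
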