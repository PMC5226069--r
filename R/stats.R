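# Cohort statistics: Shapiro-Wilk normality, equal-variance unpaired
# t-tests, Pearson chi-squared without continuity correction, one-way ANOVA
# with Bonferroni adjustment, two-way random absolute-agreement ICC, and
# assembly of the four group-comparison report tables.

#' Two-group comparison of one variable
#'
#' Continuous variables: Shapiro-Wilk normality per group (reported, not
#' acted on) followed by an unpaired two-sided equal-variance (Student)
#' t-test.  Categorical variables: Pearson chi-squared without continuity
#' correction on the group-by-category table.
#'
#' @param values numeric vector (continuous) or category labels
#'   (categorical).
#' @param groups group labels, two levels.
#' @param type "continuous" or "categorical".
#' @param welch use the Welch (unequal-variance) t-test instead.
#' @return One-row data frame: summaries per group, test name, statistic,
#'   p-value, plus Shapiro-Wilk p-values for continuous variables.
#' @export
compareGroups <- function(values, groups,
                          type = c("continuous", "categorical"),
                          welch = FALSE) {
  type <- match.arg(type)
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  lv <- levels(g)
  if (type == "continuous") {
    x <- values[g == lv[1]]; y <- values[g == lv[2]]
    if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
    swp <- vapply(list(x, y), function(v)
      if (length(v) >= 3L && length(v) <= 5000L && var(v) > 0)
        shapiro.test(v)$p.value else NA_real_, numeric(1))
    if (var(x) == 0 && var(y) == 0) {
      tt <- list(statistic = c(t = if (mean(x) == mean(y)) 0 else Inf),
                 parameter = c(df = length(x) + length(y) - 2L),
                 p.value = if (mean(x) == mean(y)) 1 else 0)
    } else {
      tt <- t.test(x, y, var.equal = !welch)
    }
    data.frame(
      test = if (welch) "welch_t" else "student_t",
      summary_1 = sprintf("%.3g ± %.3g", mean(x), sd(x)),
      summary_2 = sprintf("%.3g ± %.3g", mean(y), sd(y)),
      mean_1 = mean(x), sd_1 = sd(x), mean_2 = mean(y), sd_2 = sd(y),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, shapiro_p_1 = swp[1], shapiro_p_2 = swp[2],
      stringsAsFactors = FALSE)
  } else {
    tab <- table(g, factor(values))
    exp0 <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp0 < 1))
      warning("expected cell count below 1; chi-squared approximation poor")
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    data.frame(test = "chi_squared",
               summary_1 = paste(tab[1, ], collapse = "/"),
               summary_2 = paste(tab[2, ], collapse = "/"),
               mean_1 = NA_real_, sd_1 = NA_real_,
               mean_2 = NA_real_, sd_2 = NA_real_,
               statistic = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value, shapiro_p_1 = NA_real_, shapiro_p_2 = NA_real_,
               stringsAsFactors = FALSE)
  }
}

#' One-way ANOVA with Bonferroni adjustment
#'
#' One-way ANOVA across groups with the raw p-value Bonferroni-multiplied by
#' \code{m} comparisons (capped at 1), plus Bonferroni-adjusted post hoc
#' pairwise Student t-tests.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 levels, each n >= 2).
#' @param m number of comparisons in the Bonferroni family (default:
#'   1, i.e. no family correction beyond this test).
#' @return List: \code{F}, \code{df}, \code{p}, \code{p_adj}, and
#'   \code{posthoc} (pairwise data frame).
#' @export
anovaBonferroni <- function(values, groups, m = 1L) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("at least two groups are required")
  if (any(table(g) < 2L)) stop("each group needs n >= 2")
  res <- .onewayF(values, g)
  pairs <- utils::combn(levels(g), 2)
  nPairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(nPairs), function(j) {
    a <- values[g == pairs[1, j]]; b <- values[g == pairs[2, j]]
    tt <- if (var(a) == 0 && var(b) == 0) {
      list(statistic = 0, p.value = if (mean(a) == mean(b)) 1 else 0)
    } else t.test(a, b, var.equal = TRUE)
    data.frame(group_1 = pairs[1, j], group_2 = pairs[2, j],
               t = unname(tt$statistic), p = tt$p.value,
               p_adj = min(1, tt$p.value * nPairs),
               stringsAsFactors = FALSE)
  }))
  list(F = res$F, df = c(nlevels(g) - 1L, length(values) - nlevels(g)),
       p = res$p, p_adj = min(1, res$p * m), posthoc = posthoc)
}

#' Two-way random absolute-agreement intraclass correlation
#'
#' Single-rater ICC(A,1): a two-way random-effects model with absolute
#' agreement, estimated from the mean squares of the subjects-by-raters
#' decomposition, with the F-based 95\% confidence interval.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns; no
#'   missing entries.
#' @param conf confidence level (default 0.95).
#' @return List: \code{icc}, \code{ci} (low, high), \code{model}.
#' @export
iccTwoWayRandom <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("at least 5 subjects are required")
  if (k < 2L) stop("at least 2 raters are required")
  if (any(!complete.cases(ratings)))
    stop("missing entries are not supported (no imputation)")
  gm <- mean(ratings)
  rowM <- rowMeans(ratings); colM <- colMeans(ratings)
  MSR <- k * sum((rowM - gm)^2) / (n - 1)
  MSC <- n * sum((colM - gm)^2) / (k - 1)
  SSE <- sum((ratings - outer(rowM, colM, "+") + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf
  if (MSE < 1e-300 && MSC < 1e-300) {
    ci <- c(icc, icc)
  } else {
    r <- icc
    a <- k * r / (n * (1 - r)); b <- 1 + k * r * (n - 1) / (n * (1 - r))
    nu <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, nu)
    FU <- qf(1 - alpha / 2, nu, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(max(-1, lo), min(1, hi))
  }
  list(icc = icc, ci = ci,
       model = "two-way random, absolute agreement, single rater ICC(A,1)")
}

# one stratified comparison block of continuous variables
.statBlock <- function(df, vars, groupCol = "group") {
  do.call(rbind, lapply(vars, function(v) {
    ok <- is.finite(df[[v]])
    row <- compareGroups(df[[v]][ok], df[[groupCol]][ok], "continuous")
    cbind(data.frame(variable = v, stringsAsFactors = FALSE),
          row, data.frame(significant = row$p < 0.05))
  }))
}

#' Assemble the four cohort report tables
#'
#' Builds the demographic, volumetric, geometric and strain group-comparison
#' tables (mean +/- SD per group, equal-variance t-tests for continuous
#' rows, chi-squared for categorical rows, stratified Total / Stage I /
#' Stage II where stage labels exist, significance flagged at p < 0.05).
#'
#' @param cohortTable cohort data frame from [generateCohort()].
#' @param geometry per-subject geometry data frame (one row per subject,
#'   containing the indexed measurements, with \code{subject_id}).
#' @param strainPeaks per-subject strain peak data frame (subject_id, level,
#'   direction, peaks).
#' @return Named list of data frames \code{table1} .. \code{table4}.
#' @export
buildReportTables <- function(cohortTable, geometry = NULL,
                              strainPeaks = NULL) {
  ct <- cohortTable
  strata <- list(Total = rep(TRUE, nrow(ct)))
  if (!is.null(ct$stage) && !any(is.na(ct$stage))) {
    strata$`Stage I` <- ct$stage == "I"
    strata$`Stage II` <- ct$stage == "II"
  } else warning("missing stage labels: stratified blocks omitted")
  single <- length(unique(ct$group)) < 2L

  stratify <- function(df, vars, joinTable = NULL) {
    if (!is.null(joinTable))
      df <- merge(ct[, c("subject_id", "group", "stage")], df,
                  by = "subject_id")
    out <- do.call(rbind, lapply(names(strata), function(sn) {
      sel <- if (sn == "Total") rep(TRUE, nrow(df)) else
        df$stage == sub("Stage ", "", sn)
      sub <- df[sel, , drop = FALSE]
      if (single || length(unique(sub$group)) < 2L) {
        data.frame(stratum = sn, variable = vars,
                   test = NA_character_, summary_1 = NA, summary_2 = NA,
                   mean_1 = vapply(vars, function(v) mean(sub[[v]], na.rm = TRUE),
                                   numeric(1)),
                   sd_1 = vapply(vars, function(v) sd(sub[[v]], na.rm = TRUE),
                                 numeric(1)),
                   mean_2 = NA_real_, sd_2 = NA_real_, statistic = NA_real_,
                   df = NA_real_, p = NA_real_, shapiro_p_1 = NA_real_,
                   shapiro_p_2 = NA_real_, significant = NA,
                   stringsAsFactors = FALSE)
      } else {
        cbind(stratum = sn, .statBlock(sub, vars))
      }
    }))
    rownames(out) <- NULL
    out
  }

  table1 <- {
    vars <- c("weight_kg", "height_cm", "bsa_m2")
    cont <- stratify(ct, vars)
    cat1 <- if (!single) {
      rbind(
        cbind(stratum = "Total", variable = "tr_grade",
              compareGroups(as.character(gradeTR(ct$tr_fraction)), ct$group,
                            "categorical"),
              significant = NA),
        cbind(stratum = "Total", variable = "lv_shape",
              compareGroups(ct$lv_shape, ct$group, "categorical"),
              significant = NA))
    } else NULL
    rbind(cont, cat1)
  }

  table2 <- if (!is.null(geometry))
    stratify(geometry, c("iedv", "iesv", "isv", "ef_pct"), joinTable = ct)
  else NULL
  table3 <- if (!is.null(geometry))
    stratify(geometry,
             intersect(c("imass", "ilength", "icav_diam", "iepi_diam",
                         "sphericity_ratio", "iwall_max", "iseptal_sd"),
                       names(geometry)), joinTable = ct)
  else NULL
  table4 <- if (!is.null(strainPeaks)) {
    sp <- strainPeaks
    sp$variable <- paste(sp$level, sp$direction, sep = "_")
    ids <- unique(sp$subject_id)
    wide <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
    for (v in unique(sp$variable)) {
      sub <- sp[sp$variable == v, , drop = FALSE]
      m <- match(ids, sub$subject_id)
      wide[[paste0(v, "_strain_pct")]] <- sub$systolic_strain_pct[m]
      wide[[paste0(v, "_sys_rate_per_s")]] <- sub$systolic_rate_per_s[m]
      wide[[paste0(v, "_dia_rate_per_s")]] <- sub$diastolic_rate_per_s[m]
    }
    vars <- setdiff(names(wide), "subject_id")
    stratify(wide, vars, joinTable = ct)
  } else NULL

  list(table1 = table1, table2 = table2, table3 = table3, table4 = table4)
}
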