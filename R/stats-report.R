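## Group-comparison layer: Grubbs one-outlier-per-group screening and the
## t test / ANOVA (+ Tukey or Bonferroni post hoc) designs used on the
## assay and imaging readouts, plus an end-to-end report chaining
## pipeline -> outlier rule -> test.

#' Grubbs test statistic and critical value
#'
#' Two-sided single-outlier test for approximately normal samples:
#' G = max|x - mean| / sd, compared against the closed-form critical value
#' ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)) with
#' t = qt(1 - alpha/(2n), n - 2).
#'
#' @param x numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @return list: \code{G}, \code{critical}, \code{index} (of the most
#'   extreme point), \code{outlier} (logical: G > critical).
#' @examples
#' grubbsTest(c(1, 1.2, 0.9, 1.1, 100))$outlier   # TRUE
#' @export
grubbsTest <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3L) stop("Grubbs test requires at least 3 values")
  s <- stats::sd(x)
  if (s == 0) return(list(G = 0, critical = NA_real_, index = NA_integer_,
                          outlier = FALSE))
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  G <- dev[i] / s
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  list(G = G, critical = crit, index = i, outlier = G > crit)
}

#' Remove at most one Grubbs outlier per group
#'
#' Applies the two-sided Grubbs test within each group and removes the
#' single most extreme point if it exceeds the critical value — never more
#' than one per group, and never silently: every removal is returned.
#' Groups with fewer than 3 values are passed through with a warning (the
#' test is undefined there).
#'
#' @param table data.frame with a value and a group column.
#' @param valueCol,groupCol column names (defaults "value", "group").
#' @param alpha Grubbs significance level (default 0.05).
#' @return list: \code{table} (rows surviving), \code{removed} (data.frame
#'   of removed rows with the G statistic and critical value; zero rows if
#'   nothing was removed).
#' @examples
#' t <- data.frame(value = c(1, 1, 1, 1, 100), group = "a")
#' removeOneOutlierPerGroup(t)$removed$value   # 100
#' @export
removeOneOutlierPerGroup <- function(table, valueCol = "value",
                                     groupCol = "group", alpha = 0.05) {
  stopifnot(all(c(valueCol, groupCol) %in% names(table)))
  keep <- rep(TRUE, nrow(table))
  removed <- list()
  for (g in unique(table[[groupCol]])) {
    idx <- which(table[[groupCol]] == g)
    if (length(idx) < 3L) {
      warning("group '", g, "' has fewer than 3 values: Grubbs test ",
              "undefined, group left untouched")
      next
    }
    res <- grubbsTest(table[[valueCol]][idx], alpha = alpha)
    if (res$outlier) {
      drop <- idx[res$index]
      keep[drop] <- FALSE
      removed[[length(removed) + 1L]] <- data.frame(
        group = g, value = table[[valueCol]][drop], row = drop,
        G = res$G, critical = res$critical, stringsAsFactors = FALSE)
    }
  }
  removedDf <- if (length(removed)) do.call(rbind, removed)
    else data.frame(group = character(0), value = numeric(0),
                    row = integer(0), G = numeric(0), critical = numeric(0))
  list(table = table[keep, , drop = FALSE], removed = removedDf)
}

# Type II sums of squares for a two-factor design with interaction,
# by nested-model comparison (each main effect adjusted for the other,
# interaction last).
.anova2TypeII <- function(value, A, B) {
  dat <- data.frame(value = value, A = factor(A), B = factor(B))
  full <- stats::lm(value ~ A * B, data = dat)
  addl <- stats::lm(value ~ A + B, data = dat)
  noA <- stats::lm(value ~ B, data = dat)
  noB <- stats::lm(value ~ A, data = dat)
  rss <- function(m) sum(stats::residuals(m)^2)
  dfres <- stats::df.residual(full)
  mse <- rss(full) / dfres
  if (mse == 0) stop("degenerate data: zero residual variance everywhere")
  ss <- c(A = rss(noA) - rss(addl),
          B = rss(noB) - rss(addl),
          `A:B` = rss(addl) - rss(full))
  df <- c(A = nlevels(dat$A) - 1L, B = nlevels(dat$B) - 1L,
          `A:B` = (nlevels(dat$A) - 1L) * (nlevels(dat$B) - 1L))
  Fv <- (ss / df) / mse
  p <- stats::pf(Fv, df, dfres, lower.tail = FALSE)
  list(F = Fv, df = df, dfres = dfres, p = p, mse = mse, data = dat)
}

#' Compare groups with the study's test designs
#'
#' Runs one of: unpaired two-tailed Student's t test (pooled variance by
#' default, Welch selectable), one-way ANOVA with Tukey HSD post hoc, or
#' two-way ANOVA (Type II sums of squares) with Bonferroni-adjusted
#' pairwise comparisons of the first factor within each level of the
#' second. Significance is called at p < 0.05.
#'
#' @param table data.frame with value/group columns (and a second factor
#'   column for the two-way design).
#' @param design \code{"t_test"}, \code{"anova1_tukey"} or
#'   \code{"anova2_bonferroni"}.
#' @param valueCol,groupCol,factor2Col column names.
#' @param varEqual pooled-variance t test when TRUE (default, the common
#'   graphing-software default); FALSE gives Welch.
#' @param alpha significance level for the post-hoc flags (default 0.05).
#' @return A [TestResult-class].
#' @examples
#' d <- data.frame(value = c(rnorm(10), rnorm(10, 5)),
#'                 group = rep(c("a", "b"), each = 10))
#' compareGroups(d, "t_test")
#' @export
compareGroups <- function(table,
                          design = c("t_test", "anova1_tukey",
                                     "anova2_bonferroni"),
                          valueCol = "value", groupCol = "group",
                          factor2Col = "factor2", varEqual = TRUE,
                          alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(all(c(valueCol, groupCol) %in% names(table)))
  v <- table[[valueCol]]
  g <- factor(table[[groupCol]])
  if (nlevels(g) < 2L)
    stop("design mismatch: '", design, "' needs at least 2 groups, got ",
         nlevels(g))
  if (any(tabulate(g) < 2L))
    stop("every group needs at least 2 values")

  if (design == "t_test") {
    if (nlevels(g) != 2L)
      stop("design mismatch: t_test needs exactly 2 groups, got ",
           nlevels(g))
    if (stats::var(v[g == levels(g)[1]]) == 0 &&
        stats::var(v[g == levels(g)[2]]) == 0 &&
        diff(tapply(v, g, mean)) == 0)
      stop("degenerate data: zero variance everywhere")
    tt <- stats::t.test(v ~ g, var.equal = varEqual)
    return(new("TestResult", testName = "t_test",
               statistic = c(t = unname(tt$statistic)),
               df = c(df = unname(tt$parameter)),
               pValue = c(p = tt$p.value),
               postHoc = data.frame(pair = character(0),
                                    estimate = numeric(0),
                                    p_adjusted = numeric(0),
                                    significant = logical(0))))
  }

  if (design == "anova1_tukey") {
    dat <- data.frame(value = v, group = g)
    fit <- stats::aov(value ~ group, data = dat)
    if (sum(stats::residuals(fit)^2) == 0 &&
        stats::var(tapply(v, g, mean)) == 0)
      stop("degenerate data: zero variance everywhere")
    at <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, "group")$group
    ph <- data.frame(pair = rownames(tk),
                     estimate = tk[, "diff"],
                     p_adjusted = tk[, "p adj"],
                     significant = tk[, "p adj"] < alpha,
                     row.names = NULL)
    return(new("TestResult", testName = "anova1_tukey",
               statistic = c(F = at[["F value"]][1]),
               df = c(df1 = at[["Df"]][1], df2 = at[["Df"]][2]),
               pValue = c(p = at[["Pr(>F)"]][1]),
               postHoc = ph))
  }

  # two-way ANOVA with Bonferroni post hoc
  if (!factor2Col %in% names(table))
    stop("design mismatch: anova2_bonferroni needs a '", factor2Col,
         "' column")
  res <- .anova2TypeII(v, g, table[[factor2Col]])
  dat <- res$data
  # pairwise comparisons of factor A within each level of B, pooled MSE
  pairsA <- utils::combn(levels(dat$A), 2, simplify = FALSE)
  rows <- list()
  for (b in levels(dat$B)) {
    for (pr in pairsA) {
      x1 <- dat$value[dat$A == pr[1] & dat$B == b]
      x2 <- dat$value[dat$A == pr[2] & dat$B == b]
      if (!length(x1) || !length(x2)) next
      diffm <- mean(x2) - mean(x1)
      se <- sqrt(res$mse * (1 / length(x1) + 1 / length(x2)))
      tstat <- diffm / se
      praw <- 2 * stats::pt(abs(tstat), res$dfres, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste0(pr[2], "-", pr[1], " @ ", b),
        estimate = diffm, p_raw = praw, stringsAsFactors = FALSE)
    }
  }
  ph <- do.call(rbind, rows)
  m <- nrow(ph)
  ph$p_adjusted <- pmin(1, ph$p_raw * m)
  ph$significant <- ph$p_adjusted < alpha
  ph$p_raw <- NULL
  new("TestResult", testName = "anova2_bonferroni",
      statistic = c(F_A = unname(res$F["A"]), F_B = unname(res$F["B"]),
                    F_AB = unname(res$F["A:B"])),
      df = c(df_A = unname(res$df["A"]), df_B = unname(res$df["B"]),
             df_AB = unname(res$df["A:B"]), df_res = res$dfres),
      pValue = c(p_A = unname(res$p["A"]), p_B = unname(res$p["B"]),
                 p_AB = unname(res$p["A:B"])),
      postHoc = ph)
}

#' End-to-end report: images (or values) -> outlier rule -> test
#'
#' Chains the SRS pipeline over per-group image sets (one value per image:
#' the image-level mean lipid ratio, or the cell-normalized ratio), applies
#' the one-outlier-per-group Grubbs rule, runs the requested comparison,
#' and returns a single structured report with per-group summaries and
#' provenance (a hash of the resolved configuration and the seed, if any).
#' Identical inputs and configuration give an identical report.
#'
#' @param x either a named list of groups, each a list of
#'   [IntensityImage-class] images, or a data.frame with value/group
#'   columns.
#' @param design passed to [compareGroups()].
#' @param config [PipelineConfig-class] used when \code{x} holds images.
#' @param metric \code{"lipid_ratio"} (default) or \code{"normalized"}.
#' @param removeOutliers apply [removeOneOutlierPerGroup()] first (default
#'   TRUE, matching the one-outlier-per-group rule).
#' @param alpha significance level (default 0.05).
#' @param seed optional integer recorded in the provenance block.
#' @return list of class \code{"srsReport"}: \code{values} (per-image/per-
#'   well table), \code{removed}, \code{groupSummary}, \code{test} (a
#'   [TestResult-class]), \code{provenance}.
#' @seealso [writeReport()]
#' @export
endToEndReport <- function(x, design = "anova1_tukey",
                           config = pipelineConfig(),
                           metric = c("lipid_ratio", "normalized"),
                           removeOutliers = TRUE, alpha = 0.05,
                           seed = NA_integer_) {
  metric <- match.arg(metric)
  if (is.data.frame(x)) {
    values <- x
    stopifnot(all(c("value", "group") %in% names(values)))
  } else {
    stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
    rows <- list()
    for (grp in names(x)) {
      imgs <- x[[grp]]
      for (i in seq_along(imgs)) {
        s <- runSrsPipeline(imgs[[i]], config)
        val <- if (metric == "lipid_ratio") s@meanLipidRatio
               else s@meanNormalizedRatio
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp, image = i, value = val,
          n_fovs_included = s@nFovsIncluded, stringsAsFactors = FALSE)
      }
    }
    values <- do.call(rbind, rows)
    if (any(is.na(values$value)))
      warning("image(s) with no included FOVs contribute NA values")
  }
  if (length(unique(values$group)) < 2L)
    stop("design mismatch: group comparison needs at least 2 groups")
  screened <- if (removeOutliers)
    removeOneOutlierPerGroup(values, "value", "group", alpha = alpha)
  else list(table = values, removed = data.frame())
  tbl <- screened$table[!is.na(screened$table$value), , drop = FALSE]
  test <- compareGroups(tbl, design, alpha = alpha)
  gs <- do.call(rbind, lapply(split(tbl$value, tbl$group), function(v)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_)))
  gs <- cbind(group = rownames(gs), gs)
  rownames(gs) <- NULL
  cfgList <- .configAsList(config)
  prov <- list(
    config = cfgList,
    config_hash = .hashObject(list(cfgList, design, metric,
                                   removeOutliers, alpha)),
    design = design, metric = metric, seed = seed,
    package_version = as.character(utils::packageVersion("SRSquant")))
  structure(list(values = values, removed = screened$removed,
                 groupSummary = gs, test = test, provenance = prov),
            class = "srsReport")
}

#' @export
print.srsReport <- function(x, ...) {
  cat("SRS experiment report (", x$provenance$design, ")\n", sep = "")
  print(x$groupSummary, row.names = FALSE)
  if (nrow(x$removed))
    cat("Outliers removed:", nrow(x$removed), "\n")
  show(x$test)
  invisible(x)
}

.configAsList <- function(config) {
  nm <- slotNames(config)
  stats::setNames(lapply(nm, function(s) slot(config, s)), nm)
}

# md5 of a canonical (deparsed) representation; stable across sessions.
.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}
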