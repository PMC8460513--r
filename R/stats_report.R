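# Nonparametric statistics layer: Anderson-Darling normality screen,
# Kruskal-Wallis group comparisons (tie-corrected H, chi-squared p, exact
# permutation p for small samples), median/IQR summaries, and Pearson
# correlations with strength labels; plus the cohort-level group analysis.

#' Anderson-Darling normality test
#'
#' Composite normality test (mean and variance estimated from the sample)
#' with the usual small-sample correction; the decision is taken at
#' `alpha` (default 0.05).
#'
#' @param sample numeric vector, n >= 5, non-degenerate.
#' @param alpha significance level for the decision.
#' @return list with `A2` (corrected statistic), `p_value`, `reject`
#'   (TRUE = non-normal at `alpha`), `n`.
#' @export
anderson_darling_normality <- function(sample, alpha = 0.05) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 5) stop("Anderson-Darling test needs n >= 5")
  if (stats::sd(sample) == 0) stop("degenerate sample (zero variance)")
  t <- nortest::ad.test(sample)
  list(A2 = unname(t$statistic), p_value = t$p.value,
       reject = t$p.value < alpha, n = length(sample))
}

# tie-corrected Kruskal-Wallis H for a pooled sample + group sizes layout
.kw_h <- function(values, grp) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, grp, sum)^2 / tabulate(grp)) -
    3 * (n + 1)
  ties <- table(values)
  cf <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (cf <= 0) return(0)
  h / cf
}

#' Kruskal-Wallis H test with exact small-sample option
#'
#' Tie-corrected H with the chi-squared approximation (df = groups - 1);
#' for small total n an exact permutation p-value is available by full
#' enumeration of the group assignments. Identical pooled values give
#' H = 0, p = 1.
#'
#' @param groups list of numeric samples (>= 2 groups, total n >= 3).
#' @param exact `"auto"` (enumerate when total n <= 10), `"always"`, or
#'   `"never"`.
#' @return a `kw_test` list: `H`, `df`, `p_value` (chi-squared),
#'   `p_exact` (NA unless enumerated), `medians`, `iqrs`, `n`,
#'   `significant` (chi-squared p < 0.05; exact p when enumerated).
#' @export
kruskal_wallis <- function(groups, exact = c("auto", "always", "never")) {
  exact <- match.arg(exact)
  if (length(groups) < 2) stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 1) || sum(ns) < 3) stop("each group n >= 1, total n >= 3")
  values <- unlist(groups, use.names = FALSE)
  grp <- rep(seq_along(groups), ns)
  df <- length(groups) - 1L
  if (stats::var(values) == 0) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, factor(grp))
    H <- unname(kt$statistic); p <- kt$p.value
  }
  p_exact <- NA_real_
  do_exact <- exact == "always" || (exact == "auto" && sum(ns) <= 10)
  if (do_exact && stats::var(values) > 0) {
    perms <- .group_assignments(ns)
    Hobs <- .kw_h(values, grp)
    Hp <- vapply(perms, function(g) .kw_h(values, g), numeric(1))
    p_exact <- mean(Hp >= Hobs - 1e-12)
  }
  med <- vapply(groups, stats::median, numeric(1))
  iqr <- t(vapply(groups, function(g)
    stats::quantile(g, c(0.25, 0.75), type = 7), numeric(2)))
  p_eff <- if (!is.na(p_exact)) p_exact else p
  structure(list(H = H, df = df, p_value = p, p_exact = p_exact,
                 medians = med, iqrs = iqr, n = ns,
                 significant = p_eff < 0.05),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g (df = %d), p = %.4g%s%s\n",
              x$H, x$df, x$p_value,
              if (!is.na(x$p_exact)) sprintf(", exact p = %.4g", x$p_exact) else "",
              if (x$significant) " *" else ""))
  for (i in seq_along(x$medians))
    cat(sprintf("  group %d (n = %d): median %.4g, IQR %.4g-%.4g\n",
                i, x$n[i], x$medians[i], x$iqrs[i, 1], x$iqrs[i, 2]))
  invisible(x)
}

# all distinct assignments of n = sum(ns) items into groups of sizes ns
.group_assignments <- function(ns) {
  n <- sum(ns)
  out <- list()
  recur <- function(remaining, gi, assignment) {
    if (gi == length(ns)) {
      assignment[remaining] <- gi
      out[[length(out) + 1L]] <<- assignment
      return(invisible())
    }
    cmb <- utils::combn(remaining, ns[gi])
    for (j in seq_len(ncol(cmb))) {
      a <- assignment
      a[cmb[, j]] <- gi
      recur(setdiff(remaining, cmb[, j]), gi + 1L, a)
    }
  }
  recur(seq_len(n), 1L, integer(n))
  out
}

#' Median and interquartile range
#'
#' Linear-interpolation (type-7) quantiles, the convention recorded in all
#' report output.
#'
#' @param sample numeric vector (n >= 1).
#' @return named numeric: `median`, `q25`, `q75`.
#' @export
median_iqr <- function(sample) {
  sample <- sample[is.finite(sample)]
  if (!length(sample)) stop("empty sample")
  q <- stats::quantile(sample, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Pearson correlation with a strength label
#'
#' The label is assigned from |r|: below 0.3 none/very weak, 0.3-0.5 weak,
#' 0.5-0.7 moderate, above 0.7 strong; boundary values go to the higher
#' bin (0.5 is "moderate"), and the sign is reported separately.
#'
#' @param x,y numeric vectors (n >= 3, both non-constant).
#' @return list with `r`, `strength`, `sign` (`"positive"`/`"negative"`),
#'   `n`.
#' @export
pearson_with_strength <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  list(r = r, strength = correlation_strength(r),
       sign = if (r >= 0) "positive" else "negative", n = length(x))
}

#' @rdname pearson_with_strength
#' @param r correlation coefficient.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  if (a >= 0.7) "strong"
  else if (a >= 0.5) "moderate"
  else if (a >= 0.3) "weak"
  else "none_or_very_weak"
}

# ---------------------------------------------------------------- cohort --

#' Paired per-week rates from a long-format cohort table
#'
#' Affected (MMC) subjects use their own pre/post scans; the two
#' cross-sectional control groups are paired by gestational-age rank
#' (i-th youngest early control with i-th youngest late control), the
#' package's surrogate for the age-matched control pairing. Subjects with
#' a missing pre or post scan are excluded with a warning.
#'
#' @param table long-format data.frame with columns `subject_id`, `group`,
#'   `timepoint`, `ga_weeks`, `metric`, `value` (see [generate_cohort()]).
#' @return data.frame: `pair_id`, `group` (`mmc`/`control`), `metric`,
#'   `pre`, `post`, `ga_pre`, `ga_post`, `rate`.
#' @export
cohort_paired_rates <- function(table) {
  need <- c("subject_id", "group", "timepoint", "ga_weeks", "metric", "value")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  rows <- list()
  add_rate <- function(pair_id, group, metric, pre, post, ga_pre, ga_post) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pair_id = pair_id, group = group, metric = metric, pre = pre,
      post = post, ga_pre = ga_pre, ga_post = ga_post,
      rate = (post - pre) / (ga_post - ga_pre), stringsAsFactors = FALSE)
  }
  mmc <- table[table$group == "mmc", ]
  for (sid in unique(mmc$subject_id)) {
    s <- mmc[mmc$subject_id == sid, ]
    pre <- s[s$timepoint == "pre", ]; post <- s[s$timepoint == "post", ]
    if (!nrow(pre) || !nrow(post)) {
      warning("subject ", sid, " lacks a pre or post scan; excluded")
      next
    }
    for (m in intersect(unique(pre$metric), unique(post$metric)))
      add_rate(sid, "mmc", m, pre$value[pre$metric == m][1],
               post$value[post$metric == m][1],
               pre$ga_weeks[1], post$ga_weeks[1])
  }
  early <- table[table$group == "control_early", ]
  late <- table[table$group == "control_late", ]
  if (nrow(early) && nrow(late)) {
    eid <- unique(early[, c("subject_id", "ga_weeks")])
    lid <- unique(late[, c("subject_id", "ga_weeks")])
    eid <- eid[order(eid$ga_weeks), ]; lid <- lid[order(lid$ga_weeks), ]
    np <- min(nrow(eid), nrow(lid))
    for (i in seq_len(np)) {
      e <- early[early$subject_id == eid$subject_id[i], ]
      l <- late[late$subject_id == lid$subject_id[i], ]
      if (l$ga_weeks[1] <= e$ga_weeks[1]) next
      for (m in intersect(unique(e$metric), unique(l$metric)))
        add_rate(paste0(eid$subject_id[i], "-", lid$subject_id[i]),
                 "control", m, e$value[e$metric == m][1],
                 l$value[l$metric == m][1], e$ga_weeks[1], l$ga_weeks[1])
    }
  }
  do.call(rbind, rows)
}

#' Full nonparametric group analysis of a cohort table
#'
#' For every metric: per-week paired rates compared between the affected
#' and control groups (Kruskal-Wallis), absolute-value contrasts
#' (affected-pre vs early controls, affected-post vs late controls),
#' median/IQR summaries, an Anderson-Darling normality screen of the
#' pooled rates, and Pearson correlations (with strength labels) between
#' the biometric metrics and the volumetric/shape metrics.
#'
#' @param table long-format cohort table (see [cohort_paired_rates()]).
#' @param contrasts which contrasts to run (subset of `"rates"`,
#'   `"pre_vs_early"`, `"post_vs_late"`).
#' @param biometrics metric names treated as biometrics in the correlation
#'   block.
#' @param alpha significance level.
#' @return a `group_analysis` list: `tests` (one row per metric x
#'   contrast: H, p, exact p when enumerated, group medians/IQRs,
#'   significance), `rates`, `normality`, `correlations`.
#' @export
run_group_analysis <- function(table,
                               contrasts = c("rates", "pre_vs_early",
                                             "post_vs_late"),
                               biometrics = c("tcd_mm", "vw_mm"),
                               alpha = 0.05) {
  metrics <- unique(table$metric)
  rates <- cohort_paired_rates(table)
  tests <- list(); normality <- list()
  add_test <- function(metric, contrast, g1, g2) {
    if (!length(g1) || !length(g2)) return(invisible())
    kt <- kruskal_wallis(list(g1, g2))
    tests[[length(tests) + 1L]] <<- data.frame(
      metric = metric, contrast = contrast, H = kt$H,
      p_value = kt$p_value, p_exact = kt$p_exact,
      median_1 = kt$medians[1], q25_1 = kt$iqrs[1, 1], q75_1 = kt$iqrs[1, 2],
      median_2 = kt$medians[2], q25_2 = kt$iqrs[2, 1], q75_2 = kt$iqrs[2, 2],
      n_1 = length(g1), n_2 = length(g2),
      significant = kt$significant, stringsAsFactors = FALSE)
  }
  for (m in metrics) {
    if ("rates" %in% contrasts && !is.null(rates)) {
      r <- rates[rates$metric == m, ]
      add_test(m, "rate_mmc_vs_control", r$rate[r$group == "mmc"],
               r$rate[r$group == "control"])
      pooled <- r$rate[is.finite(r$rate)]
      if (length(pooled) >= 5 && stats::sd(pooled) > 0)
        normality[[m]] <- anderson_darling_normality(pooled, alpha)
    }
    w <- table[table$metric == m, ]
    if ("pre_vs_early" %in% contrasts)
      add_test(m, "mmc_pre_vs_early_control",
               w$value[w$group == "mmc" & w$timepoint == "pre"],
               w$value[w$group == "control_early"])
    if ("post_vs_late" %in% contrasts)
      add_test(m, "mmc_post_vs_late_control",
               w$value[w$group == "mmc" & w$timepoint == "post"],
               w$value[w$group == "control_late"])
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  # biometry x volumetry/shape correlations across all scans
  correlations <- NULL
  others <- setdiff(metrics, biometrics)
  wide <- stats::reshape(table[, c("subject_id", "timepoint", "metric", "value")],
                         idvar = c("subject_id", "timepoint"),
                         timevar = "metric", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  for (b in intersect(biometrics, metrics)) for (o in others) {
    x <- wide[[b]]; y <- wide[[o]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    pw <- pearson_with_strength(x[ok], y[ok])
    correlations <- rbind(correlations, data.frame(
      biometric = b, metric = o, r = pw$r, strength = pw$strength,
      sign = pw$sign, n = pw$n, stringsAsFactors = FALSE))
  }
  structure(list(tests = tests, rates = rates, normality = normality,
                 correlations = correlations, alpha = alpha,
                 quantile_type = 7),
            class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, ...) {
  cat("group_analysis\n")
  if (!is.null(x$tests)) {
    sig <- x$tests[x$tests$significant, ]
    cat(sprintf("  %d tests, %d significant at alpha = %g\n",
                nrow(x$tests), nrow(sig), x$alpha))
  }
  if (!is.null(x$correlations)) {
    mod <- x$correlations[x$correlations$strength %in% c("moderate", "strong"), ]
    if (nrow(mod)) {
      cat("  moderate-or-stronger correlations:\n")
      for (i in seq_len(nrow(mod)))
        cat(sprintf("    %s ~ %s: r = %.2f (%s %s)\n", mod$biometric[i],
                    mod$metric[i], mod$r[i], mod$strength[i], mod$sign[i]))
    }
  }
  invisible(x)
}

#' Write a group analysis to CSV/JSON files
#'
#' @param ga a `group_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_group_analysis <- function(ga, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(ga$tests))
    utils::write.csv(ga$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  if (!is.null(ga$rates))
    utils::write.csv(ga$rates, file.path(dir, "rates.csv"), row.names = FALSE)
  if (!is.null(ga$correlations))
    utils::write.csv(ga$correlations, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(alpha = ga$alpha, quantile_type = ga$quantile_type,
                            normality = ga$normality),
                       file.path(dir, "run_log.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
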