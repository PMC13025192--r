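#' Mixed-design repeated-measures two-way ANOVA
#'
#' Classical decomposition for one between-subject factor (e.g. diagnostic
#' group) crossed with one within-subject factor (binarization method or
#' quadrant): the between-subjects sum of squares splits into the group
#' effect and subjects-within-groups error, the within-subjects sum of
#' squares into the within factor, the interaction and the residual.
#' Sphericity of the within-factor covariance is corrected with the
#' Greenhouse-Geisser epsilon, which multiplies the within-effect and
#' interaction degrees of freedom before the p-value lookup; for a
#' two-level within factor epsilon is exactly 1.
#'
#' @param data Long-format `data.frame`.
#' @param response,between,within,subject Column names of the response,
#'   the between factor, the within factor and the subject identifier.
#' @return Object of class `rm_anova`: the effect table (`$table` with
#'   `ss`, `df`, `ms`, `F`, `epsilon`, `df1_corr`, `df2_corr`, `p`), the
#'   Greenhouse-Geisser `$epsilon`, cell/group/level means, and the error
#'   terms needed by the post hoc routines.
#' @export
rm_anova <- function(data, response, between, within, subject) {
  y <- data[[response]]
  grp <- droplevels(factor(data[[between]]))
  w <- droplevels(factor(data[[within]]))
  subj <- droplevels(factor(data[[subject]]))
  if (nlevels(w) < 2) stop("within factor must have at least 2 levels")
  tab <- table(subj, w)
  bad <- rownames(tab)[rowSums(tab != 1) > 0]
  if (length(bad))
    stop(sprintf("incomplete within-subject design for subjects: %s",
                 paste(bad, collapse = ", ")))
  k <- nlevels(w)
  N <- nlevels(subj)
  # subject x within response matrix and each subject's group
  Y <- matrix(NA_real_, N, k, dimnames = list(levels(subj), levels(w)))
  Y[cbind(as.integer(subj), as.integer(w))] <- y
  sgroup <- factor(tapply(as.character(grp), subj, `[`, 1)[levels(subj)],
                   levels = levels(grp))
  a <- nlevels(grp)
  n_g <- as.integer(table(sgroup))
  if (any(n_g < 2)) stop("each group needs at least 2 subjects")

  GM <- mean(Y)
  M_s <- rowMeans(Y)
  M_w <- colMeans(Y)
  M_g <- tapply(M_s, sgroup, mean)
  M_gw <- rowsum(Y, sgroup) / n_g

  ss_bs <- k * sum((M_s - GM)^2)
  ss_A <- k * sum(n_g * (M_g - GM)^2)
  ss_errB <- ss_bs - ss_A
  ss_W <- N * sum((M_w - GM)^2)
  ss_int <- sum(n_g * (M_gw - outer(as.numeric(M_g), rep(1, k)) -
                         outer(rep(1, a), as.numeric(M_w)) + GM)^2)
  resid <- Y - M_gw[as.integer(sgroup), , drop = FALSE] -
    (M_s - as.numeric(M_g)[as.integer(sgroup)])
  ss_errW <- sum(resid^2)

  df <- c(A = a - 1, errB = N - a, W = k - 1,
          int = (a - 1) * (k - 1), errW = (N - a) * (k - 1))
  ms <- c(A = ss_A, errB = ss_errB, W = ss_W, int = ss_int, errW = ss_errW) /
    pmax(df, 1)
  ms[df == 0] <- 0

  eps <- gg_epsilon(Y, sgroup)

  f_of <- function(ss_eff, ms_eff, ms_err) {
    if (ss_eff <= 0) 0 else if (ms_err == 0) Inf else ms_eff / ms_err
  }
  F_A <- if (a > 1) f_of(ss_A, ms["A"], ms["errB"]) else NA_real_
  F_W <- f_of(ss_W, ms["W"], ms["errW"])
  F_int <- if (a > 1) f_of(ss_int, ms["int"], ms["errW"]) else NA_real_

  p_of <- function(F, df1, df2) {
    if (is.na(F)) NA_real_
    else if (F == 0) 1
    else if (!is.finite(F)) 0
    else stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  table <- data.frame(
    effect = c(between, "subjects_within_groups", within,
               paste0(between, ":", within), "within_error"),
    ss = unname(c(ss_A, ss_errB, ss_W, ss_int, ss_errW)),
    df = unname(df),
    ms = unname(ms),
    F = unname(c(F_A, NA, F_W, F_int, NA)),
    epsilon = c(1, NA, eps, eps, NA),
    df1_corr = c(df[["A"]], NA, eps * df[["W"]], eps * df[["int"]], NA),
    df2_corr = c(df[["errB"]], NA, eps * df[["errW"]], eps * df[["errW"]], NA),
    p = c(p_of(F_A, df[["A"]], df[["errB"]]), NA,
          p_of(F_W, eps * df[["W"]], eps * df[["errW"]]),
          p_of(F_int, eps * df[["int"]], eps * df[["errW"]]), NA),
    stringsAsFactors = FALSE)

  structure(list(table = table, epsilon = eps, k = k, N = N,
                 between = between, within = within,
                 group_means = M_g, group_n = stats::setNames(n_g, levels(grp)),
                 within_means = M_w, cell_means = M_gw,
                 ms_errB = unname(ms["errB"]), df_errB = unname(df["errB"]),
                 ms_errW = unname(ms["errW"]), df_errW = unname(df["errW"]),
                 subject_means = M_s, subject_group = sgroup),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: between = %s, within = %s (GG epsilon = %.4f)\n",
              x$between, x$within, x$epsilon))
  tab <- x$table
  for (i in c(1, 3, 4)) {
    if (is.na(tab$F[i])) next
    cat(sprintf("  %-28s F(%.3f, %.1f) = %.4g, p = %.4g\n", tab$effect[i],
                tab$df1_corr[i], tab$df2_corr[i], tab$F[i], tab$p[i]))
  }
  invisible(x)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the k repeated measures, via normalized orthogonal contrasts.
gg_epsilon <- function(Y, sgroup) {
  k <- ncol(Y)
  if (k == 2) return(1)
  centered <- Y - (rowsum(Y, sgroup) / as.integer(table(sgroup)))[as.integer(sgroup), ,
                                                                  drop = FALSE]
  S <- crossprod(centered) / (nrow(Y) - nlevels(sgroup))
  C <- t(qr.Q(qr(stats::contr.helmert(k))))    # (k-1) x k orthonormal contrasts
  E <- C %*% S %*% t(C)
  denom <- (k - 1) * sum(E^2)
  if (denom == 0) return(1)
  eps <- sum(diag(E))^2 / denom
  min(1, max(1 / (k - 1), eps))
}

#' Tukey pairwise comparisons from level means and an error term
#'
#' The studentized-range statistic is
#' `q = |m_i - m_j| / sqrt(mse / n_h)` with `n_h` the harmonic mean of the
#' two level sizes (Tukey-Kramer for unequal groups); adjusted p-values
#' come from the studentized-range distribution with (`nlevels`,
#' `df_error`). Comparisons are returned ordered by adjusted p, with
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param means Named vector of level means.
#' @param ns Named vector of per-level sizes (recycled if length 1).
#' @param mse Error mean square on the scale of the observations behind
#'   `means`.
#' @param df_error Error degrees of freedom.
#' @return `data.frame` with `level1`, `level2`, `diff`, `q`, `p_adj`,
#'   `stars`.
#' @export
tukey_pairs <- function(means, ns, mse, df_error) {
  lv <- names(means)
  if (length(ns) == 1) ns <- stats::setNames(rep(ns, length(lv)), lv)
  cmb <- utils::combn(lv, 2)
  out <- data.frame(level1 = cmb[1, ], level2 = cmb[2, ],
                    diff = NA_real_, q = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb))) {
    l1 <- cmb[1, i]; l2 <- cmb[2, i]
    d <- means[[l1]] - means[[l2]]
    n_h <- 2 / (1 / ns[[l1]] + 1 / ns[[l2]])
    if (mse <= 0) {
      if (d != 0) {
        warning("zero error variance with unequal means: adjusted p set to 0")
        out$q[i] <- Inf; out$p_adj[i] <- 0
      } else {
        out$q[i] <- 0; out$p_adj[i] <- 1
      }
    } else {
      q <- abs(d) / sqrt(mse / n_h)
      out$q[i] <- q
      out$p_adj[i] <- stats::ptukey(q, length(lv), df_error, lower.tail = FALSE)
    }
    out$diff[i] <- d
  }
  out$stars <- ifelse(out$p_adj < 0.001, "***",
                      ifelse(out$p_adj < 0.01, "**",
                             ifelse(out$p_adj < 0.05, "*", "")))
  out[order(out$p_adj), , drop = FALSE]
}

#' Tukey post hoc for the factors of a repeated-measures ANOVA
#'
#' For the between factor the comparison runs on subject means with error
#' term `MS(subjects within groups) / k` and `N - a` degrees of freedom;
#' for the within factor on within-level means with the within residual
#' and its degrees of freedom.
#'
#' @param fit An [rm_anova] fit.
#' @param factor `"between"` or `"within"`.
#' @return See [tukey_pairs].
#' @export
tukey_posthoc <- function(fit, factor = c("between", "within")) {
  factor <- match.arg(factor)
  if (factor == "between") {
    tukey_pairs(fit$group_means, fit$group_n,
                mse = fit$ms_errB / fit$k, df_error = fit$df_errB)
  } else {
    tukey_pairs(fit$within_means, stats::setNames(rep(fit$N, fit$k),
                                                  names(fit$within_means)),
                mse = fit$ms_errW, df_error = fit$df_errW)
  }
}

#' One-way Tukey comparisons across groups
#'
#' Pooled within-group variance is the error term (the between-subjects
#' error for a single response column), df `N - a`.
#'
#' @param values Numeric response.
#' @param groups Factor of group labels.
#' @return See [tukey_pairs].
#' @export
tukey_oneway <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  ns <- as.integer(table(groups))
  means <- tapply(values, groups, mean)
  ss_w <- sum((values - means[as.integer(groups)])^2)
  df_w <- length(values) - nlevels(groups)
  tukey_pairs(means, stats::setNames(ns, levels(groups)),
              mse = ss_w / df_w, df_error = df_w)
}

#' Run the group-comparison study on a density table
#'
#' `design = "method_comparison"` fits the group x binarization-method
#' ANOVA on the parafoveal ring density; when the group main effect is
#' significant at 0.05 the post hoc stage adds the overall group Tukey
#' table plus per-method one-way group comparisons (the per-method
#' pattern reported alongside the omnibus test). `design = "quadrant"`
#' fits one group x quadrant ANOVA per method and, under the same
#' significance rule, per-quadrant one-way group comparisons.
#'
#' @param records Wide density table from [process_cohort] /
#'   [run_subject].
#' @param design `"method_comparison"` or `"quadrant"`.
#' @param alpha Significance level gating the post hoc stage (default
#'   0.05).
#' @return A list of class `anova_report`.
#' @export
run_study <- function(records, design = c("method_comparison", "quadrant"),
                      alpha = 0.05) {
  design <- match.arg(design)
  records$group <- factor(records$group, levels = GROUP_LEVELS)
  single_group <- nlevels(droplevels(records$group)) < 2
  if (design == "method_comparison") {
    fit <- rm_anova(records, "vd_ring", "group", "method", "subject_id")
    res <- list(design = design, anova = fit, tukey = list())
    p_group <- fit$table$p[1]
    if (single_group || is.na(p_group)) {
      res$note <- "single-group cohort: between-subject comparisons skipped"
    } else if (p_group < alpha) {
      res$tukey$group <- tukey_posthoc(fit, "between")
      for (m in unique(records$method)) {
        sub <- records[records$method == m, ]
        res$tukey[[paste0("group_within_", m)]] <-
          tukey_oneway(sub$vd_ring, sub$group)
      }
    }
    if (!is.na(fit$table$p[3]) && fit$table$p[3] < alpha)
      res$tukey$method <- tukey_posthoc(fit, "within")
    structure(res, class = "anova_report")
  } else {
    long <- density_long(records)
    res <- list(design = design, anova = list(), tukey = list())
    for (m in unique(records$method)) {
      sub <- long[long$method == m, ]
      fit <- rm_anova(sub, "vd_percent", "group", "quadrant", "subject_id")
      res$anova[[m]] <- fit
      p_group <- fit$table$p[1]
      if (single_group || is.na(p_group)) {
        res$note <- "single-group cohort: between-subject comparisons skipped"
      } else if (p_group < alpha) {
        res$tukey[[paste0(m, "_group")]] <- tukey_posthoc(fit, "between")
        for (qn in QUADRANTS) {
          qsub <- sub[sub$quadrant == qn, ]
          res$tukey[[paste0(m, "_group_", qn)]] <-
            tukey_oneway(qsub$vd_percent, qsub$group)
        }
      }
      if (!is.na(fit$table$p[3]) && fit$table$p[3] < alpha)
        res$tukey[[paste0(m, "_quadrant")]] <- tukey_posthoc(fit, "within")
    }
    structure(res, class = "anova_report")
  }
}

#' Write an ANOVA report as CSV tables plus a plain-text summary
#'
#' @param report An `anova_report` from [run_study].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
save_study <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (report$design == "method_comparison") {
    wr(report$anova$table, "anova_method.csv")
  } else {
    for (m in names(report$anova))
      wr(report$anova[[m]]$table, sprintf("anova_quadrant_%s.csv", m))
  }
  for (nm in names(report$tukey))
    wr(report$tukey[[nm]], sprintf("tukey_%s.csv", nm))
  txt <- file.path(dir, "summary.txt")
  con <- file(txt, "w"); on.exit(close(con))
  fits <- if (report$design == "method_comparison") list(method = report$anova) else report$anova
  for (nm in names(fits)) {
    tab <- fits[[nm]]$table
    writeLines(sprintf("[%s]", nm), con)
    for (i in c(1, 3, 4)) {
      if (is.na(tab$F[i])) next
      writeLines(sprintf("  %s: F(%.3f, %.1f) = %.4g, p = %.4g", tab$effect[i],
                         tab$df1_corr[i], tab$df2_corr[i], tab$F[i], tab$p[i]), con)
    }
  }
  for (nm in names(report$tukey)) {
    tk <- report$tukey[[nm]]
    sig <- tk[tk$p_adj < 0.05, , drop = FALSE]
    writeLines(sprintf("[tukey %s] significant pairs:%s", nm,
                       if (nrow(sig) == 0) " none" else ""), con)
    for (i in seq_len(nrow(sig)))
      writeLines(sprintf("  %s vs %s: diff = %.3f, p adj = %.4g %s",
                         sig$level1[i], sig$level2[i], sig$diff[i],
                         sig$p_adj[i], sig$stars[i]), con)
  }
  invisible(c(paths, txt))
}
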