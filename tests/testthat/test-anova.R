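sim_long <- function(n_per_group = 3, k = 4, seed = 1, effect = 0,
                     groups = c("control", "noDR", "NPDR", "PDR")) {
  set.seed(seed)
  a <- length(groups)
  subj <- sprintf("s%02d", seq_len(a * n_per_group))
  grp <- rep(groups, each = n_per_group)
  shift <- rep(effect * (seq_len(a) - 1), each = n_per_group)
  do.call(rbind, lapply(seq_along(subj), function(i) {
    data.frame(subject_id = subj[i], group = grp[i],
               w = paste0("w", seq_len(k)),
               vd = rnorm(k, 10 + shift[i] + rnorm(1), 1),
               stringsAsFactors = FALSE)
  }))
}

test_that("the mixed-design decomposition matches aov's Error-stratum tables", {
  d <- sim_long(n_per_group = 3, k = 4, seed = 7, effect = 1.5)
  fit <- rm_anova(d, "vd", "group", "w", "subject_id")
  d$group <- factor(d$group); d$w <- factor(d$w); d$subject_id <- factor(d$subject_id)
  ref <- summary(aov(vd ~ group * w + Error(subject_id / w), data = d))
  s1 <- ref[["Error: subject_id"]][[1]]
  s2 <- ref[["Error: subject_id:w"]][[1]]
  tab <- fit$table
  expect_equal(tab$ss[tab$effect == "group"], s1["group", "Sum Sq"], tolerance = 1e-8)
  expect_equal(tab$ss[tab$effect == "subjects_within_groups"],
               s1["Residuals", "Sum Sq"], tolerance = 1e-8)
  expect_equal(tab$ss[tab$effect == "w"], s2["w", "Sum Sq"], tolerance = 1e-8)
  expect_equal(tab$ss[tab$effect == "group:w"], s2["group:w", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(tab$ss[tab$effect == "within_error"], s2["Residuals", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "group"], s1["group", "F value"], tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "w"], s2["w", "F value"], tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "group:w"], s2["group:w", "F value"],
               tolerance = 1e-8)
})

test_that("epsilon is exactly 1 for two-level within factors and bounded otherwise", {
  d <- sim_long(k = 2, seed = 8)
  fit <- rm_anova(d, "vd", "group", "w", "subject_id")
  expect_identical(fit$epsilon, 1)
  expect_equal(fit$table$df1_corr[fit$table$effect == "w"], 1)

  for (s in 1:10) {
    k <- sample(3:6, 1)
    d <- sim_long(n_per_group = 4, k = k, seed = 100 + s)
    # impose a random covariance structure via correlated noise
    fit <- rm_anova(d, "vd", "group", "w", "subject_id")
    expect_gte(fit$epsilon, 1 / (k - 1))
    expect_lte(fit$epsilon, 1)
  }
})

test_that("independent epsilon check: double-centered covariance eigenvalues", {
  d <- sim_long(n_per_group = 5, k = 4, seed = 9)
  fit <- rm_anova(d, "vd", "group", "w", "subject_id")
  Y <- matrix(NA_real_, 20, 4)
  d$idx <- as.integer(factor(d$subject_id))
  d$widx <- as.integer(factor(d$w))
  Y[cbind(d$idx, d$widx)] <- d$vd
  grp <- tapply(as.character(d$group), factor(d$subject_id), `[`, 1)
  centered <- Y - apply(Y, 2, ave, grp)[, ]
  S <- crossprod(centered) / (20 - 4)
  A <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  eps_ref <- sum(lam)^2 / ((4 - 1) * sum(lam^2))
  expect_equal(fit$epsilon, eps_ref, tolerance = 1e-10)
})

test_that("a constant response gives zero F and p = 1", {
  d <- sim_long(seed = 10)
  d$vd <- 5
  fit <- rm_anova(d, "vd", "group", "w", "subject_id")
  expect_equal(fit$table$F[c(1, 3, 4)], c(0, 0, 0))
  expect_equal(fit$table$p[c(1, 3, 4)], c(1, 1, 1))
})

test_that("incomplete designs and degenerate factors are rejected with context", {
  d <- sim_long(seed = 11)
  expect_error(rm_anova(d[-1, ], "vd", "group", "w", "subject_id"),
               "incomplete.*s01")
  d1 <- d[d$w == "w1", ]
  expect_error(rm_anova(d1, "vd", "group", "w", "subject_id"), "at least 2 levels")
})

test_that("Tukey pairs: null differences, two-level equivalence with the t distribution", {
  tk <- tukey_pairs(c(a = 3, b = 3, c = 3), c(a = 5, b = 5, c = 5),
                    mse = 2, df_error = 12)
  expect_equal(tk$q, rep(0, 3))
  expect_equal(tk$p_adj, rep(1, 3))

  # with two levels the studentized range is t * sqrt(2)
  m <- c(a = 1.0, b = 2.3); ns <- c(a = 6, b = 6)
  tk2 <- tukey_pairs(m, ns, mse = 1.4, df_error = 10)
  tstat <- abs(m["a"] - m["b"]) / sqrt(1.4 * (1 / 6 + 1 / 6))
  expect_equal(tk2$q, unname(tstat * sqrt(2)), tolerance = 1e-12)
  expect_equal(tk2$p_adj, 2 * stats::pt(-tstat, 10), tolerance = 1e-7,
               ignore_attr = TRUE)

  expect_warning(tk3 <- tukey_pairs(c(a = 1, b = 2), c(a = 3, b = 3),
                                    mse = 0, df_error = 4),
                 "zero error variance")
  expect_equal(tk3$p_adj, 0)
})

test_that("Tukey output is ordered by adjusted p with the star convention", {
  set.seed(12)
  d <- sim_long(n_per_group = 6, k = 4, seed = 13, effect = 2)
  fit <- rm_anova(d, "vd", "group", "w", "subject_id")
  tk <- tukey_posthoc(fit, "between")
  expect_true(!is.unsorted(tk$p_adj))
  expect_true(all(tk$stars[tk$p_adj < 0.001] == "***"))
  expect_true(all(tk$stars[tk$p_adj >= 0.05] == ""))
})

test_that("one-way Tukey agrees with TukeyHSD on a balanced design", {
  set.seed(14)
  values <- rnorm(24, rep(c(0, 1, 3), each = 8))
  groups <- factor(rep(c("g1", "g2", "g3"), each = 8))
  tk <- tukey_oneway(values, groups)
  ref <- TukeyHSD(aov(values ~ groups))$groups
  for (i in seq_len(nrow(tk))) {
    pair <- paste(tk$level2[i], tk$level1[i], sep = "-")
    alt <- paste(tk$level1[i], tk$level2[i], sep = "-")
    row <- if (pair %in% rownames(ref)) ref[pair, ] else ref[alt, ]
    expect_equal(tk$p_adj[i], row[["p adj"]], tolerance = 1e-7)
  }
})

test_that("run_study gates post hoc tests on the omnibus p-value and handles one group", {
  set.seed(15)
  records <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(subject_id = sprintf("s%d", i), group = "control",
               method = c("global_mean", "phansalkar"),
               vd_ring = rnorm(2, 30), vd_superior = 0, vd_inferior = 0,
               vd_nasal = 0, vd_temporal = 0, stringsAsFactors = FALSE)
  }))
  rep1 <- run_study(records, "method_comparison")
  expect_match(rep1$note, "single-group")
  expect_null(rep1$tukey$group)
})
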