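test_that("RM-ANOVA matches the hand sums-of-squares oracle", {
  df <- crafted_design()
  res <- rm_anova(df, "value", c("condition", "session"))
  orc <- rm_oracle(df)
  for (nm in c("condition", "session")) {
    row <- res[res$effect == nm, ]
    expect_equal(row$F, unname(orc[[nm]]["F"]), tolerance = 1e-10)
    expect_equal(row$df_num, unname(orc[[nm]]["df1"]))
    expect_equal(row$df_den, unname(orc[[nm]]["df2"]))
    expect_equal(row$partial_eta_sq, unname(orc[[nm]]["peta"]),
                 tolerance = 1e-10)
  }
  inter <- res[res$effect == "condition:session", ]
  expect_equal(inter$F, unname(orc$interaction["F"]), tolerance = 1e-10)
  expect_equal(inter$partial_eta_sq, unname(orc$interaction["peta"]),
               tolerance = 1e-10)
  # internal consistency of F and the SS decomposition
  expect_equal(inter$F,
               (inter$ss_effect / inter$df_num) /
                 (inter$ss_error / inter$df_den), tolerance = 1e-12)
})

test_that("constant responses give F = 0 for every effect", {
  df <- crafted_design()
  df$value <- 7
  res <- rm_anova(df, "value", c("condition", "session"))
  expect_equal(res$F, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  expect_equal(res$partial_eta_sq, rep(0, 3))
})

test_that("F is invariant to subject relabeling and constant shifts", {
  df <- crafted_design()
  res <- rm_anova(df, "value", c("condition", "session"))
  shifted <- df; shifted$value <- shifted$value + 100
  expect_equal(rm_anova(shifted, "value", c("condition", "session"))$F,
               res$F, tolerance = 1e-9)
  relabeled <- df
  relabeled$subject <- c(7, 9, 8)[relabeled$subject]
  expect_equal(rm_anova(relabeled, "value", c("condition", "session"))$F,
               res$F, tolerance = 1e-9)
})

test_that("a planted task effect is detected while sessions stay null", {
  df <- crafted_design(seed = 11, n_subj = 9, task_effect = 4)
  res <- rm_anova_2x4(df, "value")
  expect_lt(res$p[res$effect == "condition"], 0.01)
  expect_gt(res$p[res$effect == "session"], 0.05)
})

test_that("incomplete designs are rejected with the missing cells", {
  df <- crafted_design()
  expect_error(rm_anova(df[-1, ], "value", c("condition", "session")),
               "not balanced")
})

test_that("Greenhouse-Geisser epsilon is 1 for two levels and <= 1 always", {
  df <- crafted_design(n_subj = 6)
  res <- rm_anova(df, "value", c("condition", "session"), gg = TRUE)
  expect_equal(res$gg_epsilon[res$effect == "condition"], 1)
  expect_true(all(res$gg_epsilon > 0 & res$gg_epsilon <= 1))
  # corrected p is the F tail probability at epsilon-shrunk dfs
  expect_equal(res$p_gg,
               pf(res$F, res$gg_epsilon * res$df_num,
                  res$gg_epsilon * res$df_den, lower.tail = FALSE))
  # a two-level factor needs no correction
  expect_equal(res$p_gg[res$effect == "condition"],
               res$p[res$effect == "condition"])
})

test_that("one-way behavioral ANOVA matches its oracle and nulls out", {
  scores <- expand.grid(subject = 1:5, block = 1:4)
  set.seed(9)
  scores$score <- round(rnorm(20, 10, 4))
  res <- behavioral_anova(scores)
  # one-way within oracle via the two-factor machinery collapses to:
  y <- scores$score
  m <- mean(y)
  m_b <- tapply(y, scores$block, mean); m_s <- tapply(y, scores$subject, mean)
  ss_B <- 5 * sum((m_b - m)^2)
  ss_BS <- sum((y - m_b[scores$block] - m_s[scores$subject] + m)^2)
  expect_equal(res$F, (ss_B / 3) / (ss_BS / 12), tolerance = 1e-10)
  flat <- scores; flat$score <- 3
  expect_equal(behavioral_anova(flat)$F, 0)
})

test_that("behavioral ANOVA holds its nominal size under the null", {
  set.seed(19)
  pvals <- replicate(300, {
    sc <- expand.grid(subject = 1:9, block = 1:4)
    sc$score <- rnorm(36)
    behavioral_anova(sc)$p
  })
  rej <- mean(pvals <= 0.05)
  expect_lt(abs(rej - 0.05), 2.58 * sqrt(0.05 * 0.95 / 300) + 1e-9)
})


test_that("the mixed model recovers a planted metric effect", {
  tab <- sim_mixed_tab(seed = 31, beta_K = 10, phi = 0.4)
  fit <- fit_performance_model(tab)
  k <- fit$coefficients[fit$coefficients$term == "K", ]
  expect_lt(abs(k$B - 10), qt(0.975, k$df) * k$SE)
  expect_lt(k$p, 0.001)
  expect_true(k$SE > 0)
})

test_that("null metrics give small coefficients and calibrated p-values", {
  res <- t(vapply(1:25, function(i) {
    fit <- fit_performance_model(sim_mixed_tab(seed = 100 + i))
    k <- fit$coefficients[fit$coefficients$term == "K", ]
    c(B = k$B, p = k$p)
  }, c(B = 0, p = 0)))
  expect_lt(abs(mean(res[, "B"])), 0.5)
  expect_gt(mean(res[, "p"] > 0.05), 0.8)
})

test_that("the AR(1) parameter is recovered without gross bias", {
  phis0 <- vapply(1:15, function(i)
    fit_performance_model(sim_mixed_tab(seed = 200 + i, phi = 0))$ar1_phi,
    numeric(1))
  expect_lt(abs(mean(phis0)), 0.3)
  phis7 <- vapply(1:15, function(i)
    fit_performance_model(sim_mixed_tab(seed = 300 + i, phi = 0.7,
                                        sd_subj = 0.5))$ar1_phi,
    numeric(1))
  expect_gt(mean(phis7), 0.3)
})

test_that("degenerate mixed-model input is rejected informatively", {
  tab <- sim_mixed_tab(seed = 41)
  expect_error(fit_performance_model(tab[tab$session == 1, ]),
               "2 observations per subject")
})
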