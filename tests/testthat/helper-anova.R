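# oracle helpers for the repeated-measures and mixed-model tests

# independent textbook sums-of-squares decomposition for a balanced
# two-within-factor repeated-measures design
rm_oracle <- function(df) {
  y <- df$value
  m <- mean(y)
  a <- length(unique(df$condition)); b <- length(unique(df$session))
  s <- length(unique(df$subject))
  m_a <- tapply(y, df$condition, mean)
  m_b <- tapply(y, df$session, mean)
  m_s <- tapply(y, df$subject, mean)
  m_ab <- tapply(y, list(df$condition, df$session), mean)
  m_as <- tapply(y, list(df$condition, df$subject), mean)
  m_bs <- tapply(y, list(df$session, df$subject), mean)
  ss_A <- b * s * sum((m_a - m)^2)
  ss_AS <- b * sum((m_as - outer(m_a, rep(1, s)) -
                      outer(rep(1, a), m_s) + m)^2)
  ss_B <- a * s * sum((m_b - m)^2)
  ss_BS <- a * sum((m_bs - outer(m_b, rep(1, s)) -
                      outer(rep(1, b), m_s) + m)^2)
  ss_AB <- s * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + m)^2)
  resid <- y
  for (i in seq_along(y)) {
    ai <- as.character(df$condition[i]); bi <- as.character(df$session[i])
    si <- as.character(df$subject[i])
    resid[i] <- y[i] - m_ab[ai, bi] - m_as[ai, si] - m_bs[bi, si] +
      m_a[ai] + m_b[bi] + m_s[si] - m
  }
  ss_ABS <- sum(resid^2)
  list(
    condition = c(F = (ss_A / (a - 1)) / (ss_AS / ((a - 1) * (s - 1))),
                  df1 = a - 1, df2 = (a - 1) * (s - 1),
                  peta = ss_A / (ss_A + ss_AS)),
    session = c(F = (ss_B / (b - 1)) / (ss_BS / ((b - 1) * (s - 1))),
                df1 = b - 1, df2 = (b - 1) * (s - 1),
                peta = ss_B / (ss_B + ss_BS)),
    interaction = c(F = (ss_AB / ((a - 1) * (b - 1))) /
                      (ss_ABS / ((a - 1) * (b - 1) * (s - 1))),
                    df1 = (a - 1) * (b - 1),
                    df2 = (a - 1) * (b - 1) * (s - 1),
                    peta = ss_AB / (ss_AB + ss_ABS)))
}

crafted_design <- function(seed = 101, n_subj = 3, task_effect = 0,
                           session_effect = 0) {
  set.seed(seed)
  df <- expand.grid(subject = seq_len(n_subj), condition = c("rest", "IGT"),
                    session = 1:4)
  df$value <- round(rnorm(nrow(df), 10, 2), 2) +
    task_effect * (df$condition == "IGT") +
    session_effect * df$session
  df
}


sim_mixed_tab <- function(seed, beta_K = 0, phi = 0, sd_subj = 3, sd_e = 4) {
  set.seed(seed)
  tab <- expand.grid(subject = 1:9, session = 1:4)
  tab <- tab[order(tab$subject, tab$session), ]
  tab$K <- rnorm(36, 20, 2)
  tab$E_loc <- rnorm(36, 0.6, 0.05)
  tab$E_glob <- rnorm(36, 0.2, 0.03)
  b <- rnorm(9, 0, sd_subj)
  e <- as.vector(vapply(1:9, function(s) {
    x <- numeric(4); x[1] <- rnorm(1, 0, sd_e)
    for (t in 2:4) x[t] <- phi * x[t - 1] + rnorm(1, 0, sd_e * sqrt(1 - phi^2))
    x
  }, numeric(4)))
  tab$score <- 5 + beta_K * tab$K + b[tab$subject] + e
  tab
}
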