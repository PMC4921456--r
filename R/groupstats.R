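check_balanced <- function(data, subject, within) {
  cells <- table(data[c(subject, within)])
  if (any(cells != 1)) {
    bad <- which(cells != 1, arr.ind = TRUE)
    labs <- apply(bad, 1, function(r)
      paste(mapply(function(d, i) dimnames(cells)[[d]][i],
                   seq_along(r), r), collapse = "/"))
    stop("design is not balanced/complete; offending cells: ",
         paste(utils::head(labs, 10), collapse = ", "))
  }
  invisible(TRUE)
}

## Greenhouse-Geisser epsilon for one within-subject effect, from the
## subject x cell matrix and an orthonormal contrast matrix for that effect
gg_epsilon <- function(Y, M) {
  V <- M %*% stats::cov(Y) %*% t(M)
  d <- nrow(M)
  if (d < 2) return(1)
  min(1, (sum(diag(V)))^2 / (d * sum(V * V)))
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  qr.Q(qr(C))  # k x (k-1), orthonormal, orthogonal to the unit vector
}

#' Repeated-measures ANOVA (one or two within-subject factors)
#'
#' Classic within-subject sums-of-squares decomposition: each effect is tested
#' against its own subject-by-effect error stratum, and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` from the same decomposition. Reported
#' degrees of freedom are uncorrected by default; `gg = TRUE` adds
#' Greenhouse-Geisser-corrected p-values.
#'
#' @param data long-format data.frame.
#' @param dv name of the response column.
#' @param within character vector of 1 or 2 within-subject factor columns.
#' @param subject name of the subject column.
#' @param gg also report Greenhouse-Geisser corrected p-values.
#' @return data.frame of class `anova_result`: one row per effect with
#'   `effect`, `df_num`, `df_den`, `ss_effect`, `ss_error`, `F`, `p`,
#'   `partial_eta_sq` (and `gg_epsilon`, `p_gg` when requested).
#' @export
rm_anova <- function(data, dv, within, subject = "subject", gg = FALSE) {
  stopifnot(length(within) %in% 1:2, dv %in% names(data),
            all(c(within, subject) %in% names(data)))
  df <- data.frame(.y = data[[dv]], .s = factor(data[[subject]]))
  for (i in seq_along(within)) df[[paste0(".f", i)]] <- factor(data[[within[i]]])
  check_balanced(df, ".s", paste0(".f", seq_along(within)))
  fterm <- paste(paste0(".f", seq_along(within)), collapse = "*")
  form <- stats::as.formula(paste0(".y ~ ", fterm, " + Error(.s/(", fterm, "))"))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    for (r in which(rn != "Residuals")) {
      res <- which(rn == "Residuals")
      out[[length(out) + 1]] <- data.frame(
        effect = gsub("\\.f1", within[1],
                      gsub("\\.f2", if (length(within) > 1) within[2] else ".f2",
                           rn[r])),
        df_num = tab$Df[r], df_den = tab$Df[res],
        ss_effect = tab$`Sum Sq`[r], ss_error = tab$`Sum Sq`[res],
        F = tab$`F value`[r], p = tab$`Pr(>F)`[r],
        partial_eta_sq = tab$`Sum Sq`[r] / (tab$`Sum Sq`[r] + tab$`Sum Sq`[res]))
    }
  }
  out <- do.call(rbind, out)
  ## a zero-variance effect explains nothing: report F = 0, not 0/0 or
  ## floating-point noise ratios
  tot <- sum((df$.y - mean(df$.y))^2)
  thr <- 1e-12 * max(tot, mean(df$.y)^2)
  degenerate <- out$ss_effect <= thr | is.nan(out$F)
  if (any(degenerate)) {
    out$F[degenerate] <- 0
    out$p[degenerate] <- 1
    out$partial_eta_sq[degenerate] <- 0
  }
  if (gg) {
    ## subject x cell means in a fixed cell order
    cell <- interaction(df[paste0(".f", seq_along(within))], lex.order = TRUE)
    Y <- tapply(df$.y, list(df$.s, cell), mean)
    ks <- vapply(paste0(".f", seq_along(within)),
                 function(f) nlevels(df[[f]]), integer(1))
    Ms <- list()
    if (length(within) == 1) {
      Ms[[within[1]]] <- t(orthonormal_contrasts(ks[1]))
    } else {
      C1 <- t(orthonormal_contrasts(ks[1])); C2 <- t(orthonormal_contrasts(ks[2]))
      j1 <- matrix(1 / sqrt(ks[1]), 1, ks[1]); j2 <- matrix(1 / sqrt(ks[2]), 1, ks[2])
      Ms[[within[1]]] <- kronecker(C1, j2)
      Ms[[within[2]]] <- kronecker(j1, C2)
      Ms[[paste0(within[1], ":", within[2])]] <- kronecker(C1, C2)
    }
    out$gg_epsilon <- NA_real_
    out$p_gg <- NA_real_
    for (i in seq_len(nrow(out))) {
      M <- Ms[[out$effect[i]]]
      if (!is.null(M)) {
        eps <- gg_epsilon(Y, M)
        out$gg_epsilon[i] <- eps
        out$p_gg[i] <- stats::pf(out$F[i], eps * out$df_num[i],
                                 eps * out$df_den[i], lower.tail = FALSE)
      }
    }
  }
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Two-by-four repeated-measures ANOVA on a network metric
#'
#' Convenience wrapper for the 2 (condition) x 4 (session) within-subject
#' design: one row per subject/condition/session cell of `metric_name`.
#'
#' @param table long data.frame with columns `subject`, `condition`, `session`,
#'   `metric_name`, `value` (or a ready `value` column named by `metric_name`).
#' @param metric_name which metric to analyze.
#' @param ... passed to [rm_anova()].
#' @return an `anova_result`.
#' @export
rm_anova_2x4 <- function(table, metric_name, ...) {
  if ("metric_name" %in% names(table)) {
    table <- table[table$metric_name == metric_name, ]
    dv <- "value"
  } else {
    dv <- metric_name
  }
  if (nrow(table) == 0) stop("no rows for metric '", metric_name, "'")
  rm_anova(table, dv = dv, within = c("condition", "session"),
           subject = "subject", ...)
}

#' One-way repeated-measures ANOVA on behavioral scores
#'
#' Tests for score differences across task blocks within subjects.
#'
#' @param scores data.frame with columns `subject`, `block`, `score`.
#' @param ... passed to [rm_anova()].
#' @return an `anova_result`.
#' @export
behavioral_anova <- function(scores, ...) {
  rm_anova(scores, dv = "score", within = "block", subject = "subject", ...)
}

#' Mixed model predicting task performance from network metrics
#'
#' REML fit of `score ~ K + E_loc + E_glob` with a subject random intercept
#' and AR(1) within-subject error correlation over session order — the
#' regional connectivity-performance model.
#'
#' @param table data.frame with columns `subject`, `session`, `score`, and the
#'   metric columns.
#' @param metrics names of the fixed-effect metric columns.
#' @return list of class `mixed_model_result`: `coefficients` (data.frame with
#'   `term`, `B`, `SE`, `df`, `t`, `p`), `ar1_phi` (estimated serial
#'   correlation), `model` (the nlme fit).
#' @export
fit_performance_model <- function(table,
                                  metrics = c("K", "E_loc", "E_glob")) {
  stopifnot(all(c("subject", "session", "score", metrics) %in% names(table)))
  if (min(table(table$subject)) < 2)
    stop("need at least 2 observations per subject")
  form <- stats::as.formula(paste("score ~", paste(metrics, collapse = " + ")))
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | subject,
              correlation = nlme::corAR1(form = ~ session | subject),
              data = table, method = "REML",
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                         opt = "optim")),
    error = function(e)
      stop("mixed model failed to converge: ", conditionMessage(e),
           " (n = ", nrow(table), " rows, ",
           length(unique(table$subject)), " subjects)", call. = FALSE))
  tt <- summary(fit)$tTable
  coefs <- data.frame(term = rownames(tt), B = tt[, "Value"],
                      SE = tt[, "Std.Error"], df = tt[, "DF"],
                      t = tt[, "t-value"], p = tt[, "p-value"],
                      row.names = NULL)
  phi <- tryCatch(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE),
                  error = function(e) NA_real_)
  structure(list(coefficients = coefs, ar1_phi = unname(phi), model = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result> AR(1) phi =", signif(x$ar1_phi, 3), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
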