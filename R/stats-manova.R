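#' MANOVA with Wilks' lambda and gated univariate follow-ups
#'
#' The two electrode-group amplitudes (frontal, parietal) are the dependent
#' variables of a factorial MANOVA over saccade size and subject group.
#' Assumption handling mirrors the analysis plan: multivariate outliers are
#' removed by Mahalanobis distance (chi-squared cutoff), the DV correlation
#' is screened against the moderate band (r in \[0.3, 0.6\]; failure is a
#' warning, not an abort), and univariate follow-ups run only when the
#' MANOVA is significant. Residual normality per DV is checked with the
#' Lilliefors-corrected Kolmogorov-Smirnov test; a failing DV is followed
#' up with a nonparametric (aligned-rank-transform) ANOVA instead of the
#' parametric one.
#'
#' @param data Data.frame with the two DV columns and the factor columns.
#' @param dvs Character vector of exactly two DV column names.
#' @param factors Character vector of factor column names (crossed).
#' @param alpha Significance gate.
#' @param outlier_p Chi-squared tail probability for Mahalanobis outlier
#'   removal; default 0.001.
#' @param cor_limits Correlation screen band.
#' @param nonparametric `"art"` (aligned rank transform, default) or
#'   `"rank"` (plain rank transform) for non-normal follow-ups.
#' @return List of class `manova_result`: `wilks` (per-term data.frame with
#'   `term`, `wilks_lambda`, `F`, `df1`, `df2`, `p`), `significant`,
#'   `correlation` (r and screen flag), `n_outliers_removed`, `normality`
#'   (per-DV Lilliefors p), and `univariate` (per-DV ANOVA tables, only
#'   when gated open).
#' @export
manova_then_univariate <- function(data, dvs = c("frontal", "parietal"),
                                   factors = c("size_class", "group"),
                                   alpha = 0.05, outlier_p = 0.001,
                                   cor_limits = c(0.3, 0.6),
                                   nonparametric = c("art", "rank")) {
  nonparametric <- match.arg(nonparametric)
  if (length(dvs) < 2) stop("need at least two dependent variables")
  for (f in factors) data[[f]] <- factor(data[[f]])
  Y <- as.matrix(data[, dvs])

  # multivariate outlier removal (skipped when the DV covariance is
  # singular; the correlation screen below reports the degeneracy)
  keep <- tryCatch({
    d2 <- stats::mahalanobis(Y, colMeans(Y), stats::cov(Y))
    d2 <= stats::qchisq(1 - outlier_p, df = length(dvs))
  }, error = function(e) rep(TRUE, nrow(Y)))
  n_out <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]

  r <- stats::cor(Y[, 1], Y[, 2])
  screen_ok <- !is.na(r) && r >= cor_limits[1] && r <= cor_limits[2]
  if (!screen_ok)
    warning(sprintf(
      "DV correlation r = %.2f outside the moderate band [%.1f, %.1f]",
      r, cor_limits[1], cor_limits[2]))

  if (qr(scale(Y, scale = FALSE))$rank < length(dvs)) {
    # perfectly collinear DVs: the multivariate model is unidentifiable
    return(structure(list(wilks = NULL, significant = FALSE,
                          correlation = list(r = r, screen_ok = screen_ok),
                          n_outliers_removed = n_out,
                          normality = NULL, univariate = NULL),
                     class = "manova_result"))
  }

  rhs <- paste(factors, collapse = " * ")
  mform <- stats::as.formula(paste0("cbind(", paste(dvs, collapse = ", "),
                                    ") ~ ", rhs))
  fit <- stats::manova(mform, data = data)
  sm <- summary(fit, test = "Wilks")$stats
  terms <- rownames(sm)
  terms <- terms[terms != "Residuals"]
  wilks <- data.frame(term = terms,
                      wilks_lambda = sm[terms, "Wilks"],
                      F = sm[terms, "approx F"],
                      df1 = sm[terms, "num Df"],
                      df2 = sm[terms, "den Df"],
                      p = sm[terms, "Pr(>F)"])
  rownames(wilks) <- NULL
  significant <- any(wilks$p < alpha, na.rm = TRUE)

  normality <- vapply(dvs, function(v) {
    res <- stats::residuals(stats::lm(stats::as.formula(paste(v, "~", rhs)),
                                      data = data))
    if (length(res) < 5 || stats::sd(res) == 0) return(NA_real_)
    nortest::lillie.test(res)$p.value
  }, numeric(1))

  univariate <- NULL
  if (significant) {
    univariate <- lapply(dvs, function(v) {
      normal <- is.na(normality[[v]]) || normality[[v]] >= alpha
      if (normal) {
        f <- stats::lm(stats::as.formula(paste(v, "~", rhs)), data = data)
        tab <- car::Anova(f, type = 3)
        list(dv = v, method = "parametric", table = tab)
      } else {
        tab <- art_anova(data, dv = v, factors = factors,
                         method = nonparametric)
        list(dv = v, method = paste0("nonparametric-", nonparametric),
             table = tab)
      }
    })
    names(univariate) <- dvs
  }

  structure(list(wilks = wilks, significant = significant,
                 correlation = list(r = r, screen_ok = screen_ok),
                 n_outliers_removed = n_out, normality = normality,
                 univariate = univariate),
            class = "manova_result")
}

#' Nonparametric factorial ANOVA by aligned rank transform
#'
#' For each effect of a two-factor design, the response is aligned by
#' subtracting the cell-mean estimates of every *other* effect, the aligned
#' values are ranked, and a standard factorial ANOVA on the ranks supplies
#' that effect's test. `method = "rank"` skips alignment and ranks the raw
#' response once (the plain rank-transform ANOVA).
#'
#' @param data Data.frame.
#' @param dv Response column name.
#' @param factors Exactly two factor column names.
#' @param method `"art"` or `"rank"`.
#' @return Data.frame with `effect`, `F`, `df1`, `df2`, `p`.
#' @export
art_anova <- function(data, dv, factors, method = c("art", "rank")) {
  method <- match.arg(method)
  stopifnot(length(factors) == 2)
  a <- factor(data[[factors[1]]]); b <- factor(data[[factors[2]]])
  y <- data[[dv]]
  mu <- mean(y)
  m_a <- stats::ave(y, a) - mu
  m_b <- stats::ave(y, b) - mu
  m_ab <- stats::ave(y, interaction(a, b)) - mu - m_a - m_b
  rhs <- paste(factors, collapse = " * ")
  effects <- c(factors, paste0(factors[1], ":", factors[2]))
  aligned <- list(y - mu - m_b - m_ab,   # keeps main effect of a
                  y - mu - m_a - m_ab,   # keeps main effect of b
                  y - mu - m_a - m_b)    # keeps interaction
  rows <- lapply(seq_along(effects), function(k) {
    yr <- if (method == "art") rank(aligned[[k]]) else rank(y)
    d2 <- data.frame(yr = yr, a = a, b = b)
    names(d2)[2:3] <- factors
    tab <- stats::anova(stats::lm(stats::as.formula(paste("yr ~", rhs)),
                                  data = d2))
    hit <- trimws(rownames(tab)) == effects[k]
    data.frame(effect = effects[k], F = tab[hit, "F value"],
               df1 = tab[hit, "Df"],
               df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
               p = tab[hit, "Pr(>F)"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
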