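#' Holm-Sidak step-down adjustment
#'
#' Orders the raw p-values, applies the Sidak correction with a step-down
#' exponent (`1 - (1 - p_(i))^(m - i + 1)`), and enforces monotonicity.
#' Adjusted values are never below the raw ones.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-factor repeated-measures ANOVA with least-square means
#'
#' Mixed design: a between-subjects group factor and a within-subjects
#' measure factor, one observation per subject x measure cell (average
#' replicate AOIs first). Fits the classical univariate repeated-measures
#' ANOVA (`aov` with `Error(subject/within)` strata, exact under compound
#' symmetry) and reports F, df and p for the group main effect, the
#' within-factor main effect and their interaction. When the interaction is
#' significant at `alpha`, least-square means with SEM per group x measure
#' cell and Holm-Sidak-adjusted pairwise group comparisons within each
#' measure are attached.
#'
#' @param data Long-format data.frame.
#' @param dv,between,within,subject Column names.
#' @param alpha Gate for the post-hoc block; default 0.05.
#' @return List of class `rm_anova_result`: `effects` (data.frame with
#'   `effect`, `F`, `df1`, `df2`, `p`), and when gated, `lsm` (emmeans
#'   grid with SE) and `posthoc` (pairwise contrasts with raw and adjusted
#'   p).
#' @export
rm_anova <- function(data, dv = "value", between = "group",
                     within = "variable", subject = "subject",
                     alpha = 0.05) {
  data[[between]] <- factor(data[[between]])
  data[[within]] <- factor(data[[within]])
  data[[subject]] <- factor(data[[subject]])
  if (nlevels(data[[between]]) < 2)
    stop("need at least two groups for the between factor")
  form <- stats::as.formula(
    paste(dv, "~", between, "*", within,
          "+ Error(", subject, "/", within, ")"))
  # embed the literal formula in the call so downstream re-evaluation
  # (emmeans) does not depend on this function's frame
  fit <- do.call(stats::aov, list(form, data = data))
  s <- summary(fit)

  pull <- function(term) {
    for (stratum in s) {
      tab <- stratum[[1]]
      hit <- trimws(rownames(tab)) == term
      if (any(hit) && !is.na(tab[hit, "F value"])) {
        res <- which(trimws(rownames(tab)) == "Residuals")
        return(data.frame(effect = term, F = tab[hit, "F value"],
                          df1 = tab[hit, "Df"], df2 = tab[res, "Df"],
                          p = tab[hit, "Pr(>F)"]))
      }
    }
    NULL
  }
  inter <- paste0(between, ":", within)
  effects <- do.call(rbind, list(pull(between), pull(within), pull(inter)))
  rownames(effects) <- NULL

  out <- list(effects = effects)
  p_int <- effects$p[effects$effect == inter]
  if (length(p_int) == 1 && !is.na(p_int) && p_int < alpha) {
    emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", between, "|", within)),
                            data = data)
    out$lsm <- as.data.frame(emm)
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "none"))
    prs$p_holm_sidak <- holm_sidak(prs$p.value)
    out$posthoc <- prs
  }
  structure(out, class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("Repeated-measures ANOVA\n")
  for (i in seq_len(nrow(x$effects)))
    cat(sprintf("  %-24s F(%g, %g) = %.2f, p = %.4g\n",
                x$effects$effect[i], x$effects$df1[i], x$effects$df2[i],
                x$effects$F[i], x$effects$p[i]))
  if (!is.null(x$lsm)) {
    cat("Least-square means (significant interaction):\n")
    print(x$lsm, ...)
  }
  invisible(x)
}
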