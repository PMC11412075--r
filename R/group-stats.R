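# Two-way fixed-effects ANOVA (Treatment x Family + Block) per trait, with
# Shapiro-Wilk normality and Brown-Forsythe (median-centred Levene)
# homoscedasticity checks on the residuals.

#' Two-way ANOVA of a trait: Treatment, Family, interaction, Block
#'
#' Fits `value ~ treatment * family + block` (block as an additive fixed
#' effect; split-plot whole-plot error strata are deliberately not
#' modelled) for one trait and phase, and tests every term against the
#' residual mean square with sequential (Type I) sums of squares. With a
#' balanced design the factors are orthogonal, so the order does not affect
#' the sums of squares. Residual assumption checks are run via
#' [check_assumptions()] with treatment x family cells as groups.
#'
#' @param table A `trait_table`.
#' @param trait A single trait name.
#' @param phase `"stress"` or `"recovery"`.
#' @return An object of class `anova_result`: `$table` (rows `Treatment`,
#'   `Family`, `Treatment x Family`, `Block`, `Residuals`; columns `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p`, `stars`), `$assumptions` (from
#'   [check_assumptions()]), `$trait`, `$phase`.
#' @export
two_way_anova <- function(table, trait, phase = c("recovery", "stress")) {
  phase <- match.arg(phase)
  stopifnot(inherits(table, "trait_table"), length(trait) == 1L)
  x <- table[table$trait == trait & table$phase == phase, , drop = FALSE]
  if (nrow(x) == 0L) stop("no observations for trait ", trait,
                          " in phase ", phase)
  x$treatment <- factor(x$treatment, levels = c("WW", "WS"))
  x$family <- factor(x$family, levels = sort_family_codes(unique(x$family)))
  x$block <- factor(x$block)

  cells <- table(x$treatment, x$family)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)[1L, ]
    stop(sprintf("cell (%s, family %s) has fewer than 2 observations",
                 rownames(cells)[bad[1L]], colnames(cells)[bad[2L]]))
  }

  has_block <- nlevels(x$block) > 1L
  form <- if (has_block) value ~ treatment * family + block
          else value ~ treatment * family
  fit <- stats::lm(form, data = x)
  a <- stats::anova(fit)

  terms_map <- c(treatment = "Treatment", family = "Family",
                 `treatment:family` = "Treatment x Family", block = "Block",
                 Residuals = "Residuals")
  out <- data.frame(term = terms_map[rownames(a)],
                    df = a$Df, sum_sq = a$`Sum Sq`, mean_sq = a$`Mean Sq`,
                    F = a$`F value`, p = a$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  # fixed presentation order
  order_terms <- c("Treatment", "Family", "Treatment x Family", "Block",
                   "Residuals")
  out <- out[order(match(out$term, order_terms)), ]
  rownames(out) <- NULL
  out$stars <- significance_stars(out$p)

  assum <- check_assumptions(stats::residuals(fit),
                             interaction(x$treatment, x$family, drop = TRUE))
  structure(list(table = out, assumptions = assum, trait = trait,
                 phase = phase, fit = fit),
            class = "anova_result")
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' @export
print.anova_result <- function(x, digits = 4, ...) {
  cat(sprintf("Two-way ANOVA of %s (%s phase)\n", x$trait, x$phase))
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("Shapiro-Wilk W = %.4f (p = %.3g); Levene (Brown-Forsythe) F = %.4f (p = %.3g)\n",
              x$assumptions$shapiro_W, x$assumptions$shapiro_p,
              x$assumptions$levene_F, x$assumptions$levene_p))
  invisible(x)
}

#' Normality and homoscedasticity checks
#'
#' Shapiro-Wilk on the residual vector (delegated to
#' [stats::shapiro.test()]) and a Brown-Forsythe Levene test: a one-way
#' ANOVA F test on the absolute deviations of the residuals from their
#' group medians.
#'
#' @param residuals Numeric vector (at least 3 values, not constant).
#' @param groups Group labels, one per residual (at least 2 groups).
#' @return A list: `shapiro_W`, `shapiro_p`, `levene_F`, `levene_df1`,
#'   `levene_df2`, `levene_p`.
#' @export
check_assumptions <- function(residuals, groups) {
  if (length(residuals) < 3L) stop("need at least 3 residuals")
  groups <- factor(groups)
  if (length(groups) != length(residuals)) {
    stop("groups must match residuals in length")
  }
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups")
  if (stats::var(residuals) == 0) {
    stop("constant residual vector: assumption tests undefined")
  }
  sw <- stats::shapiro.test(residuals)

  med <- tapply(residuals, groups, stats::median)
  z <- abs(residuals - med[groups])
  if (stats::var(z) == 0) {
    stop("zero deviations from group medians: Levene test undefined")
  }
  lev <- stats::anova(stats::lm(z ~ groups))
  list(shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
       levene_F = lev$`F value`[1L], levene_df1 = lev$Df[1L],
       levene_df2 = lev$Df[2L], levene_p = lev$`Pr(>F)`[1L])
}
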