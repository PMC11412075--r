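# Log-linear stomatal dose-response: -ln(g_wv) = a0 + a_i + (b0 + b_i) Psi_pd
# with family-specific intercept and slope increments, fitted by OLS.

#' Fit the family-specific log-linear stomatal model
#'
#' Pairs each seedling's end-of-stress stomatal conductance `g_wv` with its
#' predawn water potential `Psi_pd` and fits, by ordinary least squares,
#' `-ln(g_wv) ~ Psi_pd * family` (common intercept and slope plus per-family
#' increments, reference = lowest family code). Composite per-family
#' coefficients `alpha(f) = a0 + a_f` and `beta(f) = b0 + b_f` and their
#' 95% t-based confidence intervals are computed from the full coefficient
#' covariance, so they do not depend on the reference parameterization.
#'
#' @param table A `trait_table` with stress-phase `g_wv` and `Psi_pd`.
#' @param level Confidence level for the coefficient intervals (default 0.95).
#' @return An object of class `loglinear_fit`: the underlying `lm` fit
#'   (`$fit`), a per-family coefficient table (`$coefficients`: `family`,
#'   `alpha`, `alpha_se`, `alpha_lo`, `alpha_hi`, `beta`, `beta_se`,
#'   `beta_lo`, `beta_hi`, `alpha_letters`, `beta_letters`), residual df and
#'   the data used.
#' @export
fit_loglinear <- function(table, level = 0.95) {
  stopifnot(inherits(table, "trait_table"))
  x <- table[table$phase == "stress" & table$trait %in% c("g_wv", "Psi_pd"), ]
  wide <- merge(
    stats::setNames(x[x$trait == "g_wv", c("seedling_id", "family", "value")],
                    c("seedling_id", "family", "g_wv")),
    x[x$trait == "Psi_pd", c("seedling_id", "value")],
    by = "seedling_id")
  names(wide)[names(wide) == "value"] <- "psi"
  wide <- wide[is.finite(wide$g_wv) & is.finite(wide$psi), ]
  if (nrow(wide) == 0L) stop("no paired g_wv / Psi_pd stress-phase records")
  if (any(wide$g_wv <= 0)) {
    stop("g_wv must be strictly positive before the log transform")
  }

  fam_levels <- sort_family_codes(unique(wide$family))
  wide$family <- factor(wide$family, levels = fam_levels)
  counts <- table(wide$family)
  if (any(counts < 2L)) {
    stop("singular fit: family(ies) with fewer than 2 observations: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  spread <- tapply(wide$psi, wide$family, function(p) stats::var(p) > 0)
  if (any(!spread)) {
    stop("singular fit: degenerate Psi_pd spread in family(ies): ",
         paste(names(spread)[!spread], collapse = ", "))
  }

  wide$negln_gwv <- -log(wide$g_wv)
  fit <- if (nf_levels(wide$family) > 1L) {
    stats::lm(negln_gwv ~ psi * family, data = wide)
  } else {
    stats::lm(negln_gwv ~ psi, data = wide)
  }
  beta_hat <- stats::coef(fit)
  V <- stats::vcov(fit)
  df_res <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - level) / 2, df_res)

  nf <- nf_levels(wide$family)
  comp <- data.frame(family = fam_levels, alpha = NA_real_, alpha_se = NA_real_,
                     alpha_lo = NA_real_, alpha_hi = NA_real_, beta = NA_real_,
                     beta_se = NA_real_, beta_lo = NA_real_, beta_hi = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(nf)) {
    ca <- numeric(length(beta_hat)); names(ca) <- names(beta_hat)
    cb <- ca
    ca["(Intercept)"] <- 1
    cb["psi"] <- 1
    if (k > 1L && nf > 1L) {
      ca[paste0("family", fam_levels[k])] <- 1
      cb[paste0("psi:family", fam_levels[k])] <- 1
    }
    est_a <- sum(ca * beta_hat); se_a <- sqrt(drop(t(ca) %*% V %*% ca))
    est_b <- sum(cb * beta_hat); se_b <- sqrt(drop(t(cb) %*% V %*% cb))
    comp[k, c("alpha", "alpha_se", "alpha_lo", "alpha_hi")] <-
      c(est_a, se_a, est_a - tcrit * se_a, est_a + tcrit * se_a)
    comp[k, c("beta", "beta_se", "beta_lo", "beta_hi")] <-
      c(est_b, se_b, est_b - tcrit * se_b, est_b + tcrit * se_b)
  }
  comp$alpha_letters <- letter_groups(comp$alpha, comp$alpha_lo, comp$alpha_hi)
  comp$beta_letters <- letter_groups(comp$beta, comp$beta_lo, comp$beta_hi)

  structure(list(fit = fit, coefficients = comp, level = level,
                 df_residual = df_res, n = nrow(wide), data = wide),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Log-linear stomatal fit: %d observations, %d families, residual df %d\n",
              x$n, nrow(x$coefficients), x$df_residual))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Predict stomatal conductance from a fitted log-linear model
#'
#' Inverts the model: `g_wv = exp(-(alpha(f) + beta(f) * Psi_pd))`.
#'
#' @param fit A `loglinear_fit`.
#' @param family Family code(s).
#' @param psi Predawn water potential(s), MPa.
#' @return Predicted `g_wv` (mol m-2 s-1).
#' @export
predict_gwv <- function(fit, family, psi) {
  stopifnot(inherits(fit, "loglinear_fit"))
  co <- fit$coefficients
  i <- match(as.character(family), co$family)
  if (anyNA(i)) stop("unknown family: ", family[which(is.na(i))[1L]])
  exp(-(co$alpha[i] + co$beta[i] * psi))
}

#' Sequential (Type I) ANOVA of the log-linear stomatal fit
#'
#' Sums of squares are attributed in the fixed entry order `Psi_pd`,
#' `Family`, `Psi_pd x Family`, with F tests against the residual mean
#' square.
#'
#' @param fit A `loglinear_fit`.
#' @return A data frame with rows `Psi_pd`, `Family`, `Psi_pd x Family`,
#'   `Residuals` and columns `df`, `sum_sq`, `mean_sq`, `F`, `p`.
#' @export
sequential_anova <- function(fit) {
  stopifnot(inherits(fit, "loglinear_fit"))
  a <- stats::anova(fit$fit)
  term_map <- c(psi = "Psi_pd", family = "Family",
                `psi:family` = "Psi_pd x Family", Residuals = "Residuals")
  out <- data.frame(
    term = unname(term_map[rownames(a)]),
    df = a$Df,
    sum_sq = a$`Sum Sq`,
    mean_sq = a$`Mean Sq`,
    F = a$`F value`,
    p = a$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Compact letter display from confidence-interval overlap
#'
#' Families whose confidence intervals overlap share at least one letter;
#' non-overlapping families share none. Letters index the maximal groups of
#' mutually-overlapping intervals (the maximal cliques of the interval
#' overlap graph), ordered by the sorted point estimates.
#'
#' @param estimates Numeric point estimates, one per group.
#' @param lower,upper Interval bounds (`lower <= upper` required).
#' @return Character vector of letter codes, aligned with `estimates`
#'   (named if `estimates` is).
#' @export
#' @examples
#' letter_groups(c(1.5, 2, 3.5), c(1, 1.5, 3), c(2, 2.5, 4))
letter_groups <- function(estimates, lower, upper) {
  n <- length(estimates)
  stopifnot(length(lower) == n, length(upper) == n)
  if (any(lower > upper)) stop("malformed interval: lower > upper")
  if (n == 0L) return(character(0))

  # maximal cliques of an interval graph: every clique is the set of
  # intervals covering some point, and each maximal clique is realized at
  # the left endpoint of one of its members
  cliques <- unique(lapply(seq_len(n), function(k) {
    which(lower <= lower[k] & upper >= lower[k])
  }))
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j) {
      i != j && all(cliques[[i]] %in% cliques[[j]])
    }, logical(1L)))
  }, logical(1L))
  cliques <- cliques[keep]
  # order groups by the smallest estimate they contain
  ord <- order(vapply(cliques, function(s) min(estimates[s]), numeric(1L)),
               vapply(cliques, function(s) min(s), numeric(1L)))
  cliques <- cliques[ord]
  out <- rep("", n)
  for (g in seq_along(cliques)) {
    lab <- make_letter(g)
    out[cliques[[g]]] <- paste0(out[cliques[[g]]], lab)
  }
  names(out) <- names(estimates)
  out
}

nf_levels <- function(f) length(levels(f))

make_letter <- function(i) {
  # a..z, then aa, ab, ... for pathological numbers of groups
  if (i <= 26L) letters[i] else paste0(make_letter((i - 1L) %/% 26L),
                                       letters[((i - 1L) %% 26L) + 1L])
}
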