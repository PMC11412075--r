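# Relative distance plasticity index (RDPI): phenotypic plasticity (PP,
# end-of-stress) and post-drought recovery (RE, post-rewatering) per trait
# and family, plus a permutation test for among-family differences.

# Orient values so all are >= 0: all-nonpositive vectors (isotope ratios,
# water potential) are negated; mixed-sign input makes the index undefined.
normalize_sign <- function(values) {
  has_pos <- any(values > 0)
  has_neg <- any(values < 0)
  if (has_pos && has_neg) {
    stop("mixed-sign trait values: relative-distance index undefined")
  }
  if (has_neg) -values else values
}

#' Relative distance index between two treatment samples
#'
#' For samples `x` (e.g. well-watered) and `x'` (water-stressed) of the same
#' trait, the index is the mean over all cross-treatment observation pairs of
#' the relative distance `r = |x' - x| / (x' + x)`, computed after sign
#' normalization (all-negative traits are negated; mixed signs are an
#' error). It ranges from 0 (identical distributions: no plasticity for PP,
#' complete recovery for RE) to 1 (maximal divergence: maximum plasticity
#' for PP, absence of recovery for RE). Pairs with a zero denominator (both
#' values zero) are dropped and counted.
#'
#' @param values_ww,values_ws Numeric vectors of observations, one per
#'   treatment (at least one finite value each, same sign class).
#' @param boot_se Number of bootstrap resamples of the pair distances used
#'   for a standard error (0 = skip, the default).
#' @param seed Optional seed for the bootstrap.
#' @return A list of class `rdpi` with elements `value` (the index),
#'   `n_pairs`, `n_dropped`, `pairs` (data frame `x_ww`, `x_ws`, `r`) and
#'   `se` (bootstrap SE or `NA`).
#' @export
#' @examples
#' relative_distance_index(c(1, 2), c(3, 4))$value  # 0.408333...
relative_distance_index <- function(values_ww, values_ws, boot_se = 0L,
                                    seed = NULL) {
  if (length(values_ww) < 1L || length(values_ws) < 1L) {
    stop("need at least one observation per treatment")
  }
  if (any(!is.finite(values_ww)) || any(!is.finite(values_ws))) {
    stop("non-finite trait values")
  }
  all_values <- normalize_sign(c(values_ww, values_ws))
  ww <- all_values[seq_along(values_ww)]
  ws <- all_values[-seq_along(values_ww)]

  d <- abs(outer(ws, ww, "-"))
  s <- outer(ws, ww, "+")
  valid <- s > 0
  n_dropped <- sum(!valid)
  if (!any(valid)) {
    stop("all pairs have zero denominator: index undefined")
  }
  r <- d[valid] / s[valid]
  idx <- list(value = mean(r),
              n_pairs = sum(valid),
              n_dropped = n_dropped,
              pairs = data.frame(
                x_ww = rep(ww, each = length(ws))[as.vector(valid)],
                x_ws = rep(ws, times = length(ww))[as.vector(valid)],
                r = as.vector(d / ifelse(valid, s, NA))[as.vector(valid)]),
              se = NA_real_)
  if (boot_se > 0L) {
    boot <- function() {
      stats::var(vapply(seq_len(boot_se), function(i) {
        mean(r[sample.int(length(r), replace = TRUE)])
      }, numeric(1L)))
    }
    v <- if (is.null(seed)) boot() else withr::with_seed(as.integer(seed), boot())
    idx$se <- sqrt(v)
  }
  class(idx) <- "rdpi"
  idx
}

#' @export
print.rdpi <- function(x, ...) {
  cat(sprintf("Relative distance index: %.4f (%d pairs, %d dropped)\n",
              x$value, x$n_pairs, x$n_dropped))
  invisible(x)
}

kind_phase <- c(PP = "stress", RE = "recovery")

#' Per-family plasticity (PP) or recovery (RE) indices
#'
#' Computes the relative-distance index between the two watering treatments
#' for every (family, trait) combination observed in the phase implied by
#' `kind`: PP uses end-of-stress measurements, RE post-recovery
#' measurements. Pairs are pooled across blocks within each family. A
#' family missing one treatment entirely for a trait yields a missing cell
#' with a warning.
#'
#' @param table A `trait_table`.
#' @param kind `"PP"` or `"RE"`.
#' @param boot_se,seed Passed to [relative_distance_index()].
#' @return A data frame of class `index_results`: `family`, `trait`, `kind`,
#'   `value`, `n_pairs`, `n_dropped`, `se`.
#' @export
indices_per_family <- function(table, kind = c("PP", "RE"), boot_se = 0L,
                               seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "trait_table"))
  phase <- kind_phase[[kind]]
  x <- table[table$phase == phase, , drop = FALSE]
  if (nrow(x) == 0L) stop("no ", phase, "-phase observations for kind ", kind)

  families <- sort_family_codes(unique(x$family))
  traits <- intersect(trait_vocabulary()$trait, unique(x$trait))
  out <- expand.grid(family = families, trait = traits,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$kind <- kind
  out$value <- NA_real_
  out$n_pairs <- 0L
  out$n_dropped <- 0L
  out$se <- NA_real_
  n_missing <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- x$family == out$family[i] & x$trait == out$trait[i]
    ww <- x$value[sel & x$treatment == "WW"]
    ws <- x$value[sel & x$treatment == "WS"]
    if (length(ww) == 0L || length(ws) == 0L) {
      n_missing <- n_missing + 1L
      next
    }
    r <- relative_distance_index(ww, ws, boot_se = boot_se, seed = seed)
    out$value[i] <- r$value
    out$n_pairs[i] <- r$n_pairs
    out$n_dropped[i] <- r$n_dropped
    out$se[i] <- r$se
  }
  if (n_missing > 0L) {
    warning(n_missing, " (family, trait) cell(s) missing a treatment; ",
            "index set to NA")
  }
  class(out) <- c("index_results", "data.frame")
  out
}

# family codes sort numerically when they all look numeric
sort_family_codes <- function(f) {
  num <- suppressWarnings(as.numeric(f))
  if (!anyNA(num)) f[order(num)] else sort(f)
}

#' Pivot index results to a families x indices matrix
#'
#' @param ... One or more `index_results` data frames (typically the PP and
#'   the RE set).
#' @return A numeric matrix, rows = families, columns labelled
#'   `"PP-<trait>"` / `"RE-<trait>"`.
#' @export
index_matrix <- function(...) {
  res <- do.call(rbind, lapply(list(...), as.data.frame))
  res$column <- paste0(res$kind, "-", res$trait)
  families <- sort_family_codes(unique(res$family))
  cols <- unique(res$column)
  m <- matrix(NA_real_, length(families), length(cols),
              dimnames = list(families, cols))
  m[cbind(match(res$family, families), match(res$column, cols))] <- res$value
  m
}

#' Permutation test for among-family differences in PP or RE
#'
#' The observed statistic is an F ratio (between-family mean square over
#' within-family mean square) computed on the per-pair relative distances
#' `r`, grouped by family. The null distribution is built by permuting
#' family labels across seedlings within each watering treatment
#' (treatment-stratified seedling-level permutation) and recomputing the
#' pairs per permutation;
#' `p = (1 + #\{perm stat >= observed\}) / (1 + n_perm)`.
#'
#' @param table A `trait_table`.
#' @param trait A single trait name.
#' @param kind `"PP"` or `"RE"`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return An object of class `htest` with `statistic` (F), `p.value`,
#'   `parameter` (n_perm) and the per-family index values in `estimate`.
#' @export
family_difference_test <- function(table, trait, kind = c("PP", "RE"),
                                   n_perm = 1000L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "trait_table"), length(trait) == 1L)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  x <- table[table$phase == kind_phase[[kind]] & table$trait == trait, ,
             drop = FALSE]
  if (nrow(x) == 0L) stop("no observations for trait ", trait)
  fam_all <- sort_family_codes(unique(x$family))
  if (length(fam_all) < 2L) stop("need at least 2 families")

  v <- normalize_sign(x$value)
  ww_i <- x$treatment == "WW"
  ws_i <- x$treatment == "WS"
  ww <- v[ww_i]; fam_ww <- factor(x$family[ww_i], levels = fam_all)
  wsv <- v[ws_i]; fam_ws <- factor(x$family[ws_i], levels = fam_all)
  if (length(ww) == 0L || length(wsv) == 0L) {
    stop("trait ", trait, " lacks one treatment in phase ", kind_phase[[kind]])
  }

  # precompute the full cross-treatment relative-distance matrix once; a
  # permutation only relabels which (row, col) submatrix belongs to which
  # family, so each permutation reduces to submatrix sums
  S <- outer(ww, wsv, "+")
  R <- abs(outer(ww, wsv, "-"))
  V <- S > 0                         # zero-denominator pairs are dropped
  R[V] <- R[V] / S[V]
  R[!V] <- 0

  nfam <- length(fam_all)
  iw_obs <- as.integer(fam_ww)
  is_obs <- as.integer(fam_ws)

  stat_from_labels <- function(iw, is) {
    n_f <- s_f <- q_f <- numeric(nfam)
    for (k in seq_len(nfam)) {
      sub <- R[iw == k, is == k]
      vs <- V[iw == k, is == k]
      n_f[k] <- sum(vs)
      if (n_f[k] < 2) return(NA_real_)
      s_f[k] <- sum(sub)
      q_f[k] <- sum(sub * sub)
    }
    m_f <- s_f / n_f
    N <- sum(n_f)
    m <- sum(s_f) / N
    ssb <- sum(n_f * (m_f - m)^2)
    ssw <- sum(q_f - n_f * m_f^2)
    (ssb / (nfam - 1)) / (ssw / (N - nfam))
  }

  obs <- stat_from_labels(iw_obs, is_obs)
  if (is.na(obs)) stop("fewer than 2 valid pairs in some family")

  perm_stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(b) {
      stat_from_labels(iw_obs[sample.int(length(iw_obs))],
                       is_obs[sample.int(length(is_obs))])
    }, numeric(1L))
  })
  perm_stats <- perm_stats[!is.na(perm_stats)]
  p <- (1 + sum(perm_stats >= obs)) / (1 + length(perm_stats))

  fam_values <- vapply(fam_all, function(f) {
    relative_distance_index(ww[fam_ww == f], wsv[fam_ws == f])$value
  }, numeric(1L))

  structure(list(
    statistic = c(F = obs),
    p.value = p,
    parameter = c(n_perm = length(perm_stats)),
    estimate = fam_values,
    method = paste0("Permutation test for among-family differences in ",
                    kind, " (pair-distance F ratio)"),
    data.name = paste0(trait, " (", kind, ")")
  ), class = "htest")
}
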