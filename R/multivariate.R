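# Hierarchical clustering of family index profiles with bootstrap support,
# PCA of the family feature matrix, and the FDR-corrected correlation matrix.

#' Hierarchical clustering of families with bootstrap support
#'
#' Families are clustered on their index profiles (Euclidean distance on
#' the unscaled rows — PP/RE indices already live on \[0, 1\] — with average
#' linkage). Support for each internal node of the point-estimate
#' dendrogram is the plain bootstrap probability: the fraction of `B`
#' column-resampled (with replacement) dendrograms that contain a node with
#' the identical leaf set. (This is a deliberate simplification of
#' multiscale-bootstrap approximately-unbiased p-values.)
#'
#' @param index_matrix Numeric matrix, rows = families, columns = indices
#'   (no missing cells).
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed for the resampling.
#' @param method Linkage method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return An object of class `cluster_tree`: `$hclust`, `$support` (one
#'   value in \[0, 1\] per internal node, in merge order), `$clades` (leaf
#'   label sets per node), `$B`.
#' @export
cluster_families <- function(index_matrix, B = 1000L, seed = 1L,
                             method = "average") {
  m <- as.matrix(index_matrix)
  if (nrow(m) < 2L) stop("need at least 2 families")
  if (ncol(m) < 2L) stop("need at least 2 index columns")
  if (anyNA(m)) stop("missing cells in index matrix")
  if (B < 1L) stop("B must be at least 1")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))

  hc <- stats::hclust(stats::dist(m), method = method)
  clades <- clade_sets(hc)
  keys <- vapply(clades, function(s) paste(sort(s), collapse = "\r"),
                 character(1L))

  hits <- integer(length(keys))
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      cols <- sample.int(ncol(m), replace = TRUE)
      hb <- stats::hclust(stats::dist(m[, cols, drop = FALSE]),
                          method = method)
      kb <- vapply(clade_sets(hb),
                   function(s) paste(sort(s), collapse = "\r"), character(1L))
      hits <- hits + (keys %in% kb)
    }
  })
  structure(list(hclust = hc, support = hits / B, clades = clades, B = B),
            class = "cluster_tree")
}

# leaf label sets for every internal node, in merge order
clade_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    sets[[k]] <- c(if (kids[1L] < 0) hc$labels[-kids[1L]] else sets[[kids[1L]]],
                   if (kids[2L] < 0) hc$labels[-kids[2L]] else sets[[kids[2L]]])
  }
  sets
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("Family dendrogram (%s linkage), %d leaves, B = %d bootstrap resamples\n",
              x$hclust$method, length(x$hclust$labels), x$B))
  for (k in seq_along(x$clades)) {
    cat(sprintf("  node %2d (h = %.3f, support %.3f): {%s}\n",
                k, x$hclust$height[k], x$support[k],
                paste(x$clades[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' Export a cluster tree to Newick
#'
#' @param tree A `cluster_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Build the family feature matrix for ordination and correlation
#'
#' Rows are families; columns are the PP/RE indices, the per-family mean of
#' each trait within each watering treatment (stress-phase traits as
#' `<trait>-ww` / `<trait>-ws`, recovery-phase gas exchange as
#' `<trait>_recov-ww` / `<trait>_recov-ws`), and the per-family slope
#' `beta` of the log-linear stomatal model when a fit is supplied.
#'
#' @param index_matrix Matrix from [index_matrix()] (or `NULL` to omit).
#' @param table A `trait_table` (or `NULL` to omit trait means).
#' @param fit Optional `loglinear_fit` contributing the `beta` column.
#' @return Numeric matrix, rows = families.
#' @export
family_feature_matrix <- function(index_matrix = NULL, table = NULL,
                                  fit = NULL) {
  blocks <- list()
  if (!is.null(index_matrix)) blocks$indices <- as.matrix(index_matrix)
  if (!is.null(table)) {
    stopifnot(inherits(table, "trait_table"))
    fam <- sort_family_codes(unique(table$family))
    mean_block <- function(phase, suffix) {
      x <- table[table$phase == phase, ]
      traits <- intersect(trait_vocabulary()$trait, unique(x$trait))
      cols <- lapply(traits, function(tr) {
        vapply(c("WW", "WS"), function(tt) {
          v <- x$value[x$trait == tr & x$treatment == tt]
          f <- x$family[x$trait == tr & x$treatment == tt]
          out <- vapply(fam, function(ff) mean(v[f == ff]), numeric(1L))
          out
        }, numeric(length(fam)))
      })
      m <- do.call(cbind, cols)
      colnames(m) <- unlist(lapply(traits, function(tr)
        paste0(tr, suffix, "-", c("ww", "ws"))))
      rownames(m) <- fam
      m
    }
    if (any(table$phase == "stress")) {
      blocks$stress <- mean_block("stress", "")
    }
    if (any(table$phase == "recovery")) {
      blocks$recov <- mean_block("recovery", "_recov")
    }
  }
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "loglinear_fit"))
    beta <- matrix(fit$coefficients$beta, ncol = 1,
                   dimnames = list(fit$coefficients$family, "beta"))
    blocks$beta <- beta
  }
  if (length(blocks) == 0L) stop("no feature blocks supplied")
  fam <- rownames(blocks[[1L]])
  out <- do.call(cbind, lapply(blocks, function(b) b[fam, , drop = FALSE]))
  out
}

#' Principal components analysis of the family feature matrix
#'
#' Columns are standardized to zero mean and unit variance, so the PCA is
#' an eigendecomposition of the correlation matrix. Components with
#' eigenvalue > 1 are retained (Kaiser rule). Component signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param features Complete numeric matrix (families x variables).
#' @return A list of class `pca_result`: `eigenvalues`, `variance_fraction`
#'   (sums to 1 over all components), `retained` (indices with eigenvalue
#'   > 1), `loadings`, `scores`, `center`, `scale`.
#' @export
pca_families <- function(features) {
  m <- as.matrix(features)
  if (anyNA(m)) stop("feature matrix has missing cells")
  if (ncol(m) < 2L) stop("need at least 2 feature columns")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  flip <- apply(p$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  rot <- sweep(p$rotation, 2L, flip, `*`)
  sco <- sweep(p$x, 2L, flip, `*`)
  structure(list(eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 retained = which(ev > 1),
                 loadings = rot,
                 scores = sco,
                 center = p$center,
                 scale = p$scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$retained)
  cat(sprintf("PCA: %d component(s) with eigenvalue > 1, explaining %.2f%% of total variance\n",
              k, 100 * sum(x$variance_fraction[x$retained])))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted q-values (monotone, `q >= p`, capped at 1).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / (m - seq_len(m) + 1L)))
  q[order(ord)]
}

#' Pairwise Pearson correlations with FDR correction
#'
#' Computes Pearson r for every unique column pair, a two-sided p-value via
#' the t transform, and Benjamini-Hochberg q-values across all unique
#' pairs. Pairs involving a constant column get `NA` (flagged, not
#' computed).
#'
#' @param features Numeric matrix (>= 4 rows).
#' @param alpha Significance level applied to the q-values (default 0.05).
#' @return A list of class `correlation_result`: `r`, `p`, `q` (symmetric
#'   matrices; diagonal r = 1, p/q = NA), `significant` (logical matrix,
#'   `q <= alpha` off-diagonal), `n`, `alpha`.
#' @export
correlation_matrix <- function(features, alpha = 0.05) {
  m <- as.matrix(features)
  n <- nrow(m)
  if (n < 4L) stop("need at least 4 rows for correlation inference")
  pn <- ncol(m)
  sds <- apply(m, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)

  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_

  up <- upper.tri(p)
  pv <- p[up]
  qv <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  qv[ok] <- bh_adjust(pv[ok])
  q <- matrix(NA_real_, pn, pn, dimnames = dimnames(p))
  q[up] <- qv
  q[lower.tri(q)] <- t(q)[lower.tri(q)]

  sig <- !is.na(q) & q <= alpha
  structure(list(r = r, p = p, q = q, significant = sig, n = n,
                 alpha = alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  k <- sum(x$significant[upper.tri(x$significant)])
  cat(sprintf("Correlation matrix: %d variables, %d significant pair(s) at FDR q <= %g\n",
              ncol(x$r), k, x$alpha))
  invisible(x)
}
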