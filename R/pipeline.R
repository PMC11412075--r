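# End-to-end pipeline: simulate (or load) -> derive -> indices + permutation
# tests -> stomatal model -> recovery ANOVA -> clustering / PCA / correlation,
# with a deterministic run manifest.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @return A configuration list (see [run_pipeline()]).
#' @export
default_config <- function(out_dir = "plastrec_run", seed = 1L) {
  list(
    out_dir = out_dir,
    input = NULL,                 # path to an existing trait-table CSV
    seed = as.integer(seed),
    design = list(n_families = 16L, replicates = 5L, blocks = 2L,
                  stress_cycles = 11L),
    n_perm = 1000L,
    B = 1000L,
    alpha = 0.05,
    anova_traits = c("A_area", "A_mass", "g_wv", "iWUE", "Phi_PSII"),
    stages = list(simulate = TRUE, indices = TRUE, stomatal = TRUE,
                  anova = TRUE, multivariate = TRUE)
  )
}

#' Read a pipeline configuration from JSON
#'
#' Fields missing from the file fall back to [default_config()] values.
#'
#' @param path JSON configuration file.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (k in names(user)) {
    if (k %in% c("design", "stages") && is.list(cfg[[k]])) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

log_msg <- function(stage, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

write_matrix_csv <- function(m, path, rowname_col = "family") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE)
  names(df)[1L] <- rowname_col
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate/load -> indices ->
#' stomatal -> anova -> multivariate), writing stage outputs beneath
#' `config$out_dir` (`tables/`, `indices/`, `models/`, `multivariate/`) and
#' a `manifest.json` recording configuration, derived per-stage seeds,
#' package version and MD5 digests of every output file. The manifest holds
#' no wall-clock information, so two runs with the same configuration and
#' seed produce byte-identical output trees. Timestamped progress logging
#' goes to standard error.
#'
#' @param config A configuration list ([default_config()]), or the path to
#'   a JSON file readable by [read_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)
  if (is.null(cfg$input) && !isTRUE(cfg$stages$simulate)) {
    stop("config error: no input table and simulation stage disabled")
  }
  seeds <- list(simulate = cfg$seed,
                indices = cfg$seed + 1001L,
                multivariate = cfg$seed + 2002L)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("tables", "indices", "models", "multivariate")) {
    dir.create(file.path(cfg$out_dir, d), showWarnings = FALSE)
  }
  outputs <- character(0)
  keep <- function(path) { outputs <<- c(outputs, path); path }

  # --- input table --------------------------------------------------------
  tab <- run_stage("input", {
    if (!is.null(cfg$input)) {
      log_msg("input", "reading trait table from ", cfg$input)
      derive_traits(read_trait_table(cfg$input))
    } else {
      log_msg("simulate", "simulating design with seed ", seeds$simulate)
      des <- do.call(experiment_design,
                     c(cfg$design, list(seed = seeds$simulate)))
      simulate_experiment(des)
    }
  })
  keep(write_trait_table(tab, file.path(cfg$out_dir, "tables", "table.csv")))

  results <- list(table = tab)

  # --- indices + permutation tests ---------------------------------------
  if (isTRUE(cfg$stages$indices)) {
    run_stage("indices", {
      log_msg("indices", "computing PP and RE indices")
      pp <- indices_per_family(tab, "PP")
      re <- indices_per_family(tab, "RE")
      im <- index_matrix(pp, re)
      keep(write_table_csv(rbind(pp, re),
                           file.path(cfg$out_dir, "indices", "indices.csv")))
      keep(write_matrix_csv(im, file.path(cfg$out_dir, "indices",
                                          "index_matrix.csv")))
      tests <- do.call(rbind, lapply(seq_len(nrow(unique(rbind(pp, re)[c("kind", "trait")]))), function(i) {
        ktr <- unique(rbind(pp, re)[c("kind", "trait")])[i, ]
        ht <- family_difference_test(tab, ktr$trait, ktr$kind,
                                     n_perm = cfg$n_perm,
                                     seed = seeds$indices + i)
        data.frame(kind = ktr$kind, trait = ktr$trait,
                   F = unname(ht$statistic), p = ht$p.value,
                   n_perm = unname(ht$parameter))
      }))
      keep(write_table_csv(tests,
                           file.path(cfg$out_dir, "indices", "tests.csv")))
      results$index_matrix <- im
    })
  }

  # --- stomatal model -----------------------------------------------------
  if (isTRUE(cfg$stages$stomatal)) {
    run_stage("stomatal", {
      log_msg("stomatal", "fitting log-linear stomatal model")
      fit <- fit_loglinear(tab)
      keep(write_table_csv(fit$coefficients,
                           file.path(cfg$out_dir, "models",
                                     "stomatal_coefficients.csv")))
      keep(write_table_csv(sequential_anova(fit),
                           file.path(cfg$out_dir, "models",
                                     "stomatal_anova.csv")))
      results$stomatal_fit <- fit
    })
  }

  # --- recovery ANOVA -----------------------------------------------------
  if (isTRUE(cfg$stages$anova)) {
    run_stage("anova", {
      log_msg("anova", "two-way ANOVA of recovery gas exchange")
      traits <- intersect(cfg$anova_traits,
                          unique(tab$trait[tab$phase == "recovery"]))
      rows <- do.call(rbind, lapply(traits, function(tr) {
        a <- two_way_anova(tab, tr, "recovery")
        cbind(trait = tr, a$table,
              shapiro_p = a$assumptions$shapiro_p,
              levene_p = a$assumptions$levene_p)
      }))
      keep(write_table_csv(rows, file.path(cfg$out_dir, "models",
                                           "anova_recovery.csv")))
    })
  }

  # --- multivariate -------------------------------------------------------
  if (isTRUE(cfg$stages$multivariate)) {
    run_stage("multivariate", {
      if (is.null(results$index_matrix)) {
        stop("multivariate stage requires the indices stage")
      }
      log_msg("multivariate", "clustering, PCA and correlations (B = ",
              cfg$B, ")")
      im <- results$index_matrix
      ok <- !apply(is.na(im), 1L, any)
      tree <- cluster_families(im[ok, , drop = FALSE], B = cfg$B,
                               seed = seeds$multivariate)
      keep(write_cluster_newick(tree, file.path(cfg$out_dir, "multivariate",
                                                "dendrogram.nwk")))
      supp <- data.frame(node = seq_along(tree$support),
                         height = tree$hclust$height,
                         support = tree$support,
                         leaves = vapply(tree$clades, paste,
                                         character(1L), collapse = ";"))
      keep(write_table_csv(supp, file.path(cfg$out_dir, "multivariate",
                                           "cluster_support.csv")))

      feats <- family_feature_matrix(im, tab, results$stomatal_fit)
      feats <- feats[, apply(feats, 2L, function(v) stats::sd(v) > 0 && !anyNA(v)),
                     drop = FALSE]
      pca <- pca_families(feats)
      keep(write_table_csv(
        data.frame(component = seq_along(pca$eigenvalues),
                   eigenvalue = pca$eigenvalues,
                   variance_fraction = pca$variance_fraction,
                   retained = seq_along(pca$eigenvalues) %in% pca$retained),
        file.path(cfg$out_dir, "multivariate", "pca_eigenvalues.csv")))
      keep(write_matrix_csv(pca$loadings,
                            file.path(cfg$out_dir, "multivariate",
                                      "pca_loadings.csv"),
                            rowname_col = "variable"))
      keep(write_matrix_csv(pca$scores,
                            file.path(cfg$out_dir, "multivariate",
                                      "pca_scores.csv")))
      cm <- correlation_matrix(feats, alpha = cfg$alpha)
      keep(write_matrix_csv(cm$r, file.path(cfg$out_dir, "multivariate",
                                            "correlation_r.csv"),
                            rowname_col = "variable"))
      keep(write_matrix_csv(cm$q, file.path(cfg$out_dir, "multivariate",
                                            "correlation_q.csv"),
                            rowname_col = "variable"))
    })
  }

  manifest <- list(
    package = "plastrec",
    version = as.character(utils::packageVersion("plastrec")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    seeds = seeds,
    outputs = lapply(stats::setNames(sort(outputs),
                                     sub(paste0("^", cfg$out_dir, "/?"), "",
                                         sort(outputs))),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("done", "wrote ", length(outputs) + 1L, " file(s) to ", cfg$out_dir)
  invisible(manifest)
}
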