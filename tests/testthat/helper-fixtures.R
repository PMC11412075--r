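# Shared fixtures: all fixtures are built in code at test time.

# minimal hand-built observation set (one family, both treatments)
tiny_table <- function() {
  trait_table(data.frame(
    seedling_id = c("a1", "a2", "b1", "b2"),
    family = "1",
    block = 1L,
    treatment = c("WW", "WW", "WS", "WS"),
    phase = "stress",
    trait = "A_area",
    value = c(10, 12, 4, 5)
  ))
}

# zero-noise profiles with no treatment effect, full recovery and a
# degenerate (shared) predawn-water-potential law: the generator then
# produces identical WW and WS distributions per family, so every PP and
# RE index is exactly zero
null_profiles <- function(design) {
  p <- default_profiles(design)
  p$traits$tau <- 0
  p$traits$sigma <- 0
  p$block[] <- 0
  p$stomatal$sigma <- 0
  p$recovery$rho <- 1
  p$recovery_sigma[] <- 0
  p$psi <- list(ww = list(mean = -0.4, sd = 0, max = -0.05),
                ws = list(min = -0.4, max = -0.4))
  p
}

# build a stress-phase trait table holding only g_wv / Psi_pd pairs drawn
# from the log-linear stomatal model with given per-family coefficients
make_stomatal_table <- function(alpha, beta, n_obs, sigma = 0,
                                psi_range = c(-3.3, -0.3), seed = NULL) {
  nf <- length(alpha)
  fam <- as.character(seq_len(nf))
  gen <- function() {
    rows <- lapply(seq_len(nf), function(i) {
      psi <- runif(n_obs, psi_range[1L], psi_range[2L])
      eps <- if (sigma > 0) rnorm(n_obs, 0, sigma) else 0
      gwv <- exp(-(alpha[i] + beta[i] * psi + eps))
      id <- sprintf("f%d_s%d", i, seq_len(n_obs))
      rbind(
        data.frame(seedling_id = id, family = fam[i], block = 1L,
                   treatment = "WS", phase = "stress", trait = "g_wv",
                   value = gwv),
        data.frame(seedling_id = id, family = fam[i], block = 1L,
                   treatment = "WS", phase = "stress", trait = "Psi_pd",
                   value = psi)
      )
    })
    trait_table(do.call(rbind, rows))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# one-trait table with explicit per-family WW/WS values
make_index_table <- function(values_ww, values_ws, trait = "A_area",
                             phase = "stress") {
  stopifnot(identical(names(values_ww), names(values_ws)))
  rows <- lapply(names(values_ww), function(f) {
    ww <- values_ww[[f]]; ws <- values_ws[[f]]
    data.frame(
      seedling_id = sprintf("%s_%s%d", f, rep(c("ww", "ws"),
                                              c(length(ww), length(ws))),
                            c(seq_along(ww), seq_along(ws))),
      family = f, block = 1L,
      treatment = rep(c("WW", "WS"), c(length(ww), length(ws))),
      phase = phase, trait = trait, value = c(ww, ws))
  })
  trait_table(do.call(rbind, rows))
}

# independent brute-force oracle for the relative distance index:
# explicit double loop over all cross-treatment pairs
rdpi_oracle <- function(ww, ws) {
  vals <- c(ww, ws)
  if (all(vals <= 0)) { ww <- -ww; ws <- -ws }
  tot <- 0; n <- 0
  for (a in ww) for (b in ws) {
    if (a + b > 0) { tot <- tot + abs(b - a) / (b + a); n <- n + 1 }
  }
  tot / n
}
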