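# Synthetic split-plot drought experiment generator.
#
# The generator emulates the statistical structure the downstream analyses
# assume: additive family, treatment and block effects with a family x
# treatment interaction on most traits; a family-specific log-linear
# stomatal dose-response g_wv = exp(-(alpha_f + beta_f * Psi_pd + eps));
# and family-specific fractional recovery of gas exchange after rewatering.

#' Describe a split-plot watering experiment
#'
#' @param n_families Number of maternal families (default 16).
#' @param replicates Seedlings per family x treatment x block cell (default 5).
#' @param blocks Number of blocks (default 2).
#' @param stress_cycles Number of weekly water-stress cycles (default 11;
#'   each cycle is 6 days of water deprivation plus rehydration on day 7).
#' @param families Optional character vector of family codes. The default for
#'   a 16-family design is the non-consecutive code set
#'   1,2,4,5,7,9,10,11,12,13,15,16,17,19,21,22; otherwise `1:n_families`.
#' @param seed Integer seed recorded with the design.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_families = 16L, replicates = 5L, blocks = 2L,
                              stress_cycles = 11L, families = NULL,
                              seed = 1L) {
  stopifnot(n_families >= 1L, replicates >= 1L, blocks >= 1L,
            stress_cycles >= 1L)
  if (is.null(families)) {
    families <- if (n_families == 16L) {
      c("1", "2", "4", "5", "7", "9", "10", "11",
        "12", "13", "15", "16", "17", "19", "21", "22")
    } else {
      as.character(seq_len(n_families))
    }
  }
  families <- as.character(families)
  stopifnot(length(families) == n_families, !anyDuplicated(families))
  structure(list(n_families = as.integer(n_families),
                 replicates = as.integer(replicates),
                 blocks = as.integer(blocks),
                 treatments = c("WW", "WS"),
                 stress_cycles = as.integer(stress_cycles),
                 families = families,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "Split-plot design: %d seedlings = %d reps x %d families x 2 treatments x %d blocks; %d stress cycles\n",
    n_seedlings(x), x$replicates, x$n_families, x$blocks, x$stress_cycles))
  invisible(x)
}

n_seedlings <- function(design) {
  design$replicates * design$n_families * 2L * design$blocks
}

# traits simulated directly from (mu, tau, sigma) profiles; g_wv and Psi_pd
# come from the stomatal model and the watering-dependent Psi_pd law, and
# A_mass / iWUE / PNUE are derived downstream.
direct_traits <- function() {
  c("A_area", "Phi_PSII", "SLA", "N_m", "C_m", "d13C", "d15N",
    "RGR_T1", "RGR_T2", "RGR_Tot")
}

# WW baselines, mean water-stress effects and residual sds, on each trait's
# natural scale (Table-style units; negative-valued isotope traits stay on
# their negative scale so downstream sign handling is exercised).
trait_baselines <- function() {
  data.frame(
    trait = direct_traits(),
    mu    = c(9.0, 0.55, 25.0, 2.2, 47.0, -28.5, -2.0, 0.012, 0.008, 0.010),
    tau   = c(-5.5, -0.25, -2.0, 0.15, 0.5, 1.5, 0.3, -0.006, -0.005, -0.0055),
    sigma = c(0.9, 0.04, 1.5, 0.12, 0.5, 0.4, 0.25, 0.0015, 0.0012, 0.0010),
    block = c(0.4, 0.01, 0.8, 0.05, 0.2, 0.1, 0.05, 5e-4, 4e-4, 4e-4),
    stringsAsFactors = FALSE
  )
}

#' Default family profiles for the synthetic generator
#'
#' Draws reproducible per-family parameters: trait baseline means `mu_f`,
#' water-stress effects `tau_f` (varying across families, i.e. a family x
#' treatment interaction), a shared additive block effect, residual sds,
#' stomatal intercepts `alpha_f` spread over \[0.63, 1.41\] and slopes
#' `beta_f` over \[-1.50, -0.77\], per-trait recovery fractions
#' `rho_f` in \[0, 1\] (1 = full recovery; lower for stomatal conductance
#' than for photosynthesis), and the predawn-water-potential sampling laws
#' per treatment (WW: Normal(-0.4, 0.1^2) truncated to <= -0.05 MPa;
#' WS: Uniform(-3.3, -0.8) MPa).
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed (default: the design's seed).
#' @return An object of class `family_profiles`.
#' @export
default_profiles <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "experiment_design"), design$n_families >= 1L)
  fam <- design$families
  nf <- length(fam)
  withr::with_seed(as.integer(seed), {
    base <- trait_baselines()
    traits <- do.call(rbind, lapply(seq_len(nrow(base)), function(k) {
      b <- base[k, ]
      data.frame(
        family = fam,
        trait = b$trait,
        mu = b$mu + stats::rnorm(nf, 0, 0.06 * abs(b$mu)),
        tau = b$tau * (1 + stats::rnorm(nf, 0, 0.25)),
        sigma = rep(b$sigma, nf),
        stringsAsFactors = FALSE
      )
    }))
    spread <- function(lo, hi) {
      if (nf == 1L) (lo + hi) / 2 else sample(seq(lo, hi, length.out = nf))
    }
    stomatal <- data.frame(family = fam,
                           alpha = spread(0.63, 1.41),
                           beta = spread(-1.50, -0.77),
                           sigma = rep(0.53, nf),
                           stringsAsFactors = FALSE)
    recovery <- rbind(
      data.frame(family = fam, trait = "A_area",
                 rho = stats::runif(nf, 0.70, 1.00)),
      data.frame(family = fam, trait = "Phi_PSII",
                 rho = stats::runif(nf, 0.75, 1.00)),
      data.frame(family = fam, trait = "g_wv",
                 rho = stats::runif(nf, 0.25, 0.60))
    )
    structure(list(
      families = fam,
      traits = traits,
      block = stats::setNames(base$block, base$trait),
      stomatal = stomatal,
      recovery = recovery,
      recovery_sigma = c(A_area = 0.7, Phi_PSII = 0.03, g_wv = 0.02),
      psi = list(ww = list(mean = -0.4, sd = 0.1, max = -0.05),
                 ws = list(min = -3.3, max = -0.8))
    ), class = "family_profiles")
  })
}

#' @export
print.family_profiles <- function(x, ...) {
  cat(sprintf("Family profiles for %d families; alpha in [%.2f, %.2f], beta in [%.2f, %.2f]\n",
              length(x$families), min(x$stomatal$alpha), max(x$stomatal$alpha),
              min(x$stomatal$beta), max(x$stomatal$beta)))
  invisible(x)
}

#' Write / read family profiles as JSON
#'
#' Profiles round-trip losslessly through a JSON configuration file so a
#' simulation can be re-run from its recorded profile set.
#'
#' @param profiles A `family_profiles` object.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `family_profiles` object (read).
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "family_profiles"))
  jsonlite::write_json(unclass(profiles), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$block <- unlist(x$block)
  x$recovery_sigma <- unlist(x$recovery_sigma)
  x$psi <- lapply(x$psi, as.list)
  structure(x, class = "family_profiles")
}

validate_profiles <- function(design, profiles) {
  stopifnot(inherits(profiles, "family_profiles"))
  missing_fam <- setdiff(design$families, profiles$families)
  if (length(missing_fam) > 0L) {
    stop("profiles do not cover family(ies): ",
         paste(missing_fam, collapse = ", "))
  }
  if (any(profiles$recovery$rho < 0 | profiles$recovery$rho > 1)) {
    stop("recovery fraction rho outside [0, 1]")
  }
  invisible(TRUE)
}

rtrunc_norm_upper <- function(n, mean, sd, upper) {
  if (sd == 0) return(rep(pmin(mean, upper), n))
  # inverse-cdf sampling of a Normal truncated from above
  p_up <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n) * p_up, mean, sd)
}

#' Simulate a trait table from a split-plot drought experiment
#'
#' Generates one stress-phase record per seedling for every trait in
#' [trait_vocabulary()] and one recovery-phase record per gas-exchange
#' trait, then appends derived traits via [derive_traits()].
#'
#' Stress phase: `Psi_pd` is drawn per treatment from the profile's sampling
#' laws; `g_wv = exp(-(alpha_f + beta_f * Psi_pd + eps))` with
#' `eps ~ Normal(0, sigma)` (log-normal multiplicative noise keeps `g_wv`
#' positive); all other traits are
#' `mu_f + tau_f * 1[WS] + b * 1[block 2] + Normal(0, sigma)`.
#' Recovery phase: well-watered seedlings get a fresh draw from their
#' well-watered distribution; water-stressed seedlings relax toward the
#' family's well-watered mean as
#' `WW mean + (1 - rho_f) * (stress value - WW mean) + noise`, so
#' `rho_f = 1` is complete recovery and `rho_f = 0` no recovery.
#'
#' @param design An [experiment_design()].
#' @param profiles A `family_profiles` set covering every design family
#'   (default [default_profiles()]).
#' @param seed Integer seed (default: the design's seed).
#' @return A validated `trait_table` with derived traits appended.
#' @export
#' @examples
#' des <- experiment_design(n_families = 4, replicates = 2)
#' tab <- simulate_experiment(des, seed = 42)
#' table(tab$phase)
simulate_experiment <- function(design, profiles = default_profiles(design),
                                seed = design$seed) {
  stopifnot(inherits(design, "experiment_design"))
  validate_profiles(design, profiles)

  layout <- expand.grid(rep = seq_len(design$replicates),
                        family = design$families,
                        treatment = design$treatments,
                        block = seq_len(design$blocks),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(layout)
  layout$seedling_id <- sprintf("S%04d", seq_len(n))
  ws <- layout$treatment == "WS"
  blk2 <- layout$block >= 2L  # shared additive effect for non-reference blocks

  sto <- profiles$stomatal[match(layout$family, profiles$stomatal$family), ]
  rows <- list()
  emit <- function(trait, phase, value, sel = rep(TRUE, n)) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seedling_id = layout$seedling_id[sel], family = layout$family[sel],
      block = layout$block[sel], treatment = layout$treatment[sel],
      phase = phase, trait = trait, value = value[sel],
      stringsAsFactors = FALSE)
  }

  withr::with_seed(as.integer(seed), {
    # --- stress phase -----------------------------------------------------
    psi <- numeric(n)
    psi[!ws] <- rtrunc_norm_upper(sum(!ws), profiles$psi$ww$mean,
                                  profiles$psi$ww$sd, profiles$psi$ww$max)
    psi[ws] <- stats::runif(sum(ws), profiles$psi$ws$min, profiles$psi$ws$max)
    emit("Psi_pd", "stress", psi)

    eps <- stats::rnorm(n, 0, sto$sigma)
    gwv_stress <- exp(-(sto$alpha + sto$beta * psi + eps))
    emit("g_wv", "stress", gwv_stress)

    voc <- trait_vocabulary()
    sign_class <- stats::setNames(voc$sign_class, voc$trait)
    clamp <- function(trait, v) {
      if (sign_class[[trait]] == "positive") pmax(v, 1e-6)
      else if (sign_class[[trait]] == "nonpositive") pmin(v, 0)
      else v
    }
    stress_value <- matrix(NA_real_, n, length(direct_traits()),
                           dimnames = list(NULL, direct_traits()))
    for (tr in direct_traits()) {
      p <- profiles$traits[profiles$traits$trait == tr, ]
      p <- p[match(layout$family, p$family), ]
      v <- p$mu + p$tau * ws + profiles$block[[tr]] * blk2 +
        stats::rnorm(n, 0, p$sigma)
      v <- clamp(tr, v)
      # basal area of surviving seedlings does not shrink: floor RGR just
      # above zero so cross-treatment pairs keep a common sign
      if (startsWith(tr, "RGR")) v <- pmax(v, 1e-4)
      stress_value[, tr] <- v
      emit(tr, "stress", v)
    }

    # --- recovery phase (measured gas-exchange traits) --------------------
    # family x block expected WW value at the stress phase
    for (tr in c("A_area", "Phi_PSII", "g_wv")) {
      if (tr == "g_wv") {
        ww_mean <- exp(-(sto$alpha + sto$beta * profiles$psi$ww$mean))
        stress_v <- gwv_stress
      } else {
        p <- profiles$traits[profiles$traits$trait == tr, ]
        p <- p[match(layout$family, p$family), ]
        ww_mean <- p$mu + profiles$block[[tr]] * blk2
        stress_v <- stress_value[, tr]
      }
      rho <- profiles$recovery[profiles$recovery$trait == tr, ]
      rho <- rho$rho[match(layout$family, rho$family)]
      sdr <- profiles$recovery_sigma[[tr]]
      v <- numeric(n)
      noise <- stats::rnorm(n, 0, sdr)
      # WW seedlings: fresh draw around their WW mean
      v[!ws] <- ww_mean[!ws] +
        if (tr == "g_wv") (exp(-stats::rnorm(sum(!ws), 0, sto$sigma[!ws])) - 1) * ww_mean[!ws]
        else stats::rnorm(sum(!ws), 0,
                          profiles$traits$sigma[profiles$traits$trait == tr][1L])
      v[ws] <- ww_mean[ws] + (1 - rho[ws]) * (stress_v[ws] - ww_mean[ws]) +
        noise[ws]
      v <- clamp(tr, v)
      emit(tr, "recovery", v)
    }
  })

  tab <- trait_table(do.call(rbind, rows), strict = TRUE)
  derive_traits(tab)
}
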