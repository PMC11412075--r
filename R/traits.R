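# Trait vocabulary, tidy trait table container, derived traits and RGR.

#' Trait vocabulary
#'
#' The controlled vocabulary of functional traits handled by the package,
#' with measurement units and sign class. Gas-exchange traits are the only
#' ones re-measured after the post-drought recovery period.
#'
#' Sign classes constrain valid observation values: `positive` traits must be
#' strictly greater than zero, `nonpositive` traits must be less than or equal
#' to zero, `any` traits are unconstrained (beyond finiteness).
#'
#' @return A data frame with columns `trait`, `units`, `sign_class`,
#'   `gas_exchange` (logical: measured again in the recovery phase).
#' @export
#' @examples
#' trait_vocabulary()
trait_vocabulary <- function() {
  data.frame(
    trait = c("A_area", "A_mass", "g_wv", "iWUE", "PNUE", "Phi_PSII",
              "SLA", "N_m", "C_m", "d13C", "d15N", "Psi_pd",
              "RGR_T1", "RGR_T2", "RGR_Tot"),
    units = c("umol m-2 s-1", "nmol g-1 s-1", "mol m-2 s-1", "umol mol-1",
              "umol gN-1 s-1", "dimensionless", "m2 kg-1", "%", "%",
              "permil", "permil", "MPa", "day-1", "day-1", "day-1"),
    sign_class = c("positive", "any", "positive", "any", "any", "any",
                   "positive", "any", "any", "nonpositive", "any",
                   "nonpositive", "any", "any", "any"),
    gas_exchange = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                     FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Gas-exchange traits eligible for recovery-phase records
#' @return Character vector of trait names.
#' @export
gas_exchange_traits <- function() {
  voc <- trait_vocabulary()
  voc$trait[voc$gas_exchange]
}

required_columns <- c("seedling_id", "family", "block", "treatment",
                      "phase", "trait", "value")

#' Construct and validate a trait table
#'
#' A trait table is a tidy long-format data frame with one row per
#' observation: columns `seedling_id`, `family`, `block`, `treatment`
#' (`WW` well-watered / `WS` water-stressed), `phase` (`stress` =
#' end-of-stress, `recovery` = post-rewatering), `trait` and `value`.
#'
#' Validation enforces: traits belong to [trait_vocabulary()]; values are
#' finite and respect each trait's sign class; `(seedling_id, phase, trait)`
#' is unique; recovery-phase rows exist only for gas-exchange traits. In
#' strict mode any violation is an error naming the offending rows; in
#' lenient mode offending rows are dropped with a message (schema problems
#' such as missing columns are always errors).
#'
#' @param x Data frame with the columns above.
#' @param strict Logical; `TRUE` (default) errors on invalid rows,
#'   `FALSE` drops them with a message.
#' @return The validated data frame with class `trait_table` and attribute
#'   `balanced` (logical: identical replicate counts in every
#'   family x treatment x block cell).
#' @export
trait_table <- function(x, strict = TRUE) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(required_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[required_columns]
  x$seedling_id <- as.character(x$seedling_id)
  x$family <- as.character(x$family)
  x$block <- as.integer(x$block)
  x$treatment <- as.character(x$treatment)
  x$phase <- as.character(x$phase)
  x$trait <- as.character(x$trait)
  if (!is.numeric(x$value)) {
    val <- suppressWarnings(as.numeric(x$value))
    bad <- is.na(val) & !is.na(x$value)
    if (any(bad) && strict) {
      stop("non-numeric value(s) in row(s): ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    x$value <- val
  }

  voc <- trait_vocabulary()
  sign_class <- stats::setNames(voc$sign_class, voc$trait)

  problems <- character(nrow(x))
  bad_trait <- !(x$trait %in% voc$trait)
  problems[bad_trait] <- "trait not in vocabulary"
  bad_levels <- !(x$treatment %in% c("WW", "WS")) |
    !(x$phase %in% c("stress", "recovery")) |
    is.na(x$block) | x$block < 1L
  problems[bad_levels & problems == ""] <- "invalid treatment/phase/block"
  bad_value <- !is.finite(x$value)
  problems[bad_value & problems == ""] <- "non-finite value"
  cls <- sign_class[x$trait]
  bad_sign <- (!is.na(cls) & cls == "positive" & is.finite(x$value) & x$value <= 0) |
    (!is.na(cls) & cls == "nonpositive" & is.finite(x$value) & x$value > 0)
  problems[bad_sign & problems == ""] <- "value violates trait sign class"
  bad_phase <- x$phase == "recovery" & !(x$trait %in% gas_exchange_traits())
  problems[bad_phase & problems == ""] <-
    "recovery-phase record for a non-gas-exchange trait"

  bad <- problems != ""
  if (any(bad)) {
    if (strict) {
      i <- which(bad)[1L]
      stop(sprintf("invalid observation in row %d (%s, trait %s): %s",
                   i, x$seedling_id[i], x$trait[i], problems[i]))
    }
    message(sum(bad), " invalid row(s) dropped from trait table")
    x <- x[!bad, , drop = FALSE]
  }

  key <- paste(x$seedling_id, x$phase, x$trait, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    if (strict) {
      stop("duplicated (seedling_id, phase, trait) for seedling ",
           x$seedling_id[which(dup)[1L]])
    }
    message(sum(dup), " duplicated row(s) dropped from trait table")
    x <- x[!dup, , drop = FALSE]
  }

  rownames(x) <- NULL
  class(x) <- c("trait_table", "data.frame")
  attr(x, "balanced") <- is_balanced(x)
  x
}

# replicate counts per family x treatment x block (distinct seedlings)
design_summary <- function(x) {
  seedlings <- unique(x[c("seedling_id", "family", "treatment", "block")])
  as.data.frame(table(family = seedlings$family,
                      treatment = seedlings$treatment,
                      block = seedlings$block),
                responseName = "n_seedlings")
}

is_balanced <- function(x) {
  ds <- design_summary(x)
  length(unique(ds$n_seedlings)) == 1L
}

#' @export
print.trait_table <- function(x, ...) {
  ds <- design_summary(x)
  cat(sprintf(paste0(
    "Trait table: %d observations, %d seedlings, %d families,\n",
    "  %d trait(s), phases: %s, %s design\n"),
    nrow(x), length(unique(x$seedling_id)), length(unique(x$family)),
    length(unique(x$trait)), paste(sort(unique(x$phase)), collapse = "/"),
    if (isTRUE(attr(x, "balanced"))) "balanced" else "UNBALANCED"))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Read a trait table from CSV
#'
#' Expects a UTF-8 CSV with header
#' `seedling_id,family,block,treatment,phase,trait,value` and `.` as the
#' decimal separator.
#'
#' @param path Path to the CSV file.
#' @param strict Passed to [trait_table()].
#' @return A validated `trait_table`.
#' @export
read_trait_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(value = "character"))
  missing_cols <- setdiff(required_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  val <- suppressWarnings(as.numeric(x$value))
  bad <- is.na(val) & !(is.na(x$value) | x$value == "" | x$value == "NA")
  if (any(bad)) {
    if (strict) {
      stop("parse error in ", path, ": non-numeric value in data row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    message(sum(bad), " non-numeric row(s) dropped while reading ", path)
    x <- x[!bad, , drop = FALSE]
    val <- val[!bad]
  }
  x$value <- val
  trait_table(x, strict = strict)
}

#' Write a trait table to CSV
#'
#' Values are serialized with 17 significant digits so that a
#' write/read round trip is lossless at double precision.
#'
#' @param x A `trait_table` (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  x <- as.data.frame(x)[required_columns]
  x$value <- formatC(x$value, digits = 17, format = "g")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Append derived gas-exchange traits
#'
#' Adds, wherever the parent traits are present for a seedling and phase and
#' the derived trait is not already recorded:
#' \itemize{
#'   \item `A_mass` (nmol g-1 s-1) = `A_area` (umol m-2 s-1) x `SLA` (m2 kg-1)
#'   \item `iWUE` (umol mol-1) = `A_area` / `g_wv`
#'   \item `PNUE` (umol gN-1 s-1) = `A_mass` / (10 x `N_m`), `N_m` in %
#' }
#' `SLA` and `N_m` are measured only at the end of stress; recovery-phase
#' `A_mass` therefore reuses the seedling's stress-phase `SLA` (leaf structure
#' is not re-measured), and `PNUE` is derived for the stress phase only.
#' Observations with `g_wv = 0` are skipped with a warning (iWUE undefined).
#' The operation is idempotent.
#'
#' @param table A `trait_table`.
#' @return The augmented `trait_table`.
#' @export
derive_traits <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  x <- as.data.frame(table)

  get_val <- function(trait, phase_wanted, ids, fallback_phase = NULL) {
    sel <- x$trait == trait & x$phase == phase_wanted
    v <- stats::setNames(x$value[sel], x$seedling_id[sel])[ids]
    if (!is.null(fallback_phase)) {
      miss <- is.na(v)
      if (any(miss)) {
        sel2 <- x$trait == trait & x$phase == fallback_phase
        v2 <- stats::setNames(x$value[sel2], x$seedling_id[sel2])[ids[miss]]
        v[miss] <- v2
      }
    }
    unname(v)
  }

  new_rows <- list()
  meta <- unique(x[c("seedling_id", "family", "block", "treatment")])

  add_derived <- function(trait, phase, ids, values) {
    ok <- !is.na(values)
    have <- x$seedling_id[x$trait == trait & x$phase == phase]
    ok <- ok & !(ids %in% have)
    if (!any(ok)) return(NULL)
    m <- meta[match(ids[ok], meta$seedling_id), ]
    data.frame(seedling_id = ids[ok], family = m$family, block = m$block,
               treatment = m$treatment, phase = phase, trait = trait,
               value = values[ok], stringsAsFactors = FALSE)
  }

  for (ph in intersect(c("stress", "recovery"), unique(x$phase))) {
    ids <- unique(x$seedling_id[x$phase == ph])
    a_area <- get_val("A_area", ph, ids)
    sla <- get_val("SLA", ph, ids,
                   fallback_phase = if (ph == "recovery") "stress")
    g_wv <- get_val("g_wv", ph, ids)

    a_mass <- a_area * sla
    new_rows[[length(new_rows) + 1L]] <- add_derived("A_mass", ph, ids, a_mass)

    iwue <- a_area / g_wv
    zero_g <- !is.na(g_wv) & g_wv == 0
    if (any(zero_g & !is.na(a_area))) {
      warning(sum(zero_g & !is.na(a_area)),
              " observation(s) with g_wv = 0 skipped (iWUE undefined)")
      iwue[zero_g] <- NA_real_
    }
    new_rows[[length(new_rows) + 1L]] <- add_derived("iWUE", ph, ids, iwue)

    if (ph == "stress") {
      # PNUE needs A_mass, which may itself be freshly derived
      a_mass_all <- get_val("A_mass", ph, ids)
      a_mass_all[is.na(a_mass_all)] <- a_mass[is.na(a_mass_all)]
      n_m <- get_val("N_m", ph, ids)
      pnue <- a_mass_all / (10 * n_m)
      new_rows[[length(new_rows) + 1L]] <- add_derived("PNUE", ph, ids, pnue)
    }
  }

  new_rows <- do.call(rbind, new_rows)
  if (is.null(new_rows) || nrow(new_rows) == 0L) return(table)
  trait_table(rbind(x, new_rows), strict = TRUE)
}

#' Relative growth rate of stem basal area
#'
#' RGR = (ln(basal area end) - ln(basal area start)) / days. With basal area
#' `pi * (d/2)^2` the constants cancel, giving `2 * (ln d_end - ln d_start)
#' / days`, in day-1.
#'
#' @param d_start,d_end Stem collar diameters (mm), strictly positive.
#' @param days Interval length in days, strictly positive.
#' @return RGR in day-1 (vectorized).
#' @export
#' @examples
#' compute_rgr(2.0, 2.2, 35)
compute_rgr <- function(d_start, d_end, days) {
  if (any(!is.finite(d_start)) || any(d_start <= 0) ||
      any(!is.finite(d_end)) || any(d_end <= 0)) {
    stop("diameters must be finite and strictly positive")
  }
  if (any(!is.finite(days)) || any(days <= 0)) {
    stop("days must be finite and strictly positive")
  }
  2 * (log(d_end) - log(d_start)) / days
}
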