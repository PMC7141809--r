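# Whole-cell bi-ionic selectivity analysis: normalization of voltage-clamp
# families, reversal-potential estimation by zero-crossing interpolation, and
# the bi-ionic permeability ratio
#   P_X / P_Y = ([Y+]ext / [X+]int) * exp(-Erev * F / (R * T)),
# with X the intracellular and Y the extracellular cation.

#' Describe a bi-ionic recording condition
#'
#' @param species_internal,species_external Cation names, e.g. "K", "Na".
#' @param conc_internal,conc_external Concentrations in mM (pipette / bath).
#' @param temperature Kelvin (default 298.15; RT/F is then ~25.7 mV).
#' @return A \code{bi_ionic_condition} list.
#' @export
bi_ionic_condition <- function(species_internal = "K",
                               species_external = "Na",
                               conc_internal = 150, conc_external = 150,
                               temperature = 298.15) {
  if (conc_internal <= 0 || conc_external <= 0) {
    abort("concentrations must be positive", class = "ionpore_parameter_error")
  }
  if (temperature < 250 || temperature > 330) {
    abort("temperature outside the physiological range 250-330 K",
          class = "ionpore_parameter_error")
  }
  structure(list(species_internal = species_internal,
                 species_external = species_external,
                 conc_internal = conc_internal,
                 conc_external = conc_external,
                 temperature = temperature),
            class = "bi_ionic_condition")
}

#' Build an I-V family
#'
#' @param records Data frame with columns \code{voltage} (mV),
#'   \code{current} (pA) and \code{replicate}.
#' @param condition A \code{\link{bi_ionic_condition}}.
#' @param construct Label for the channel construct (default "WT").
#' @return An \code{iv_family} tibble.
#' @export
iv_family <- function(records, condition = bi_ionic_condition(),
                      construct = "WT") {
  records <- as_tibble(records)
  stopifnot(all(c("voltage", "current", "replicate") %in% names(records)))
  if (length(unique(records$voltage)) < 2) {
    abort("an I-V family needs at least two distinct voltages",
          class = "ionpore_format_error")
  }
  if (any(abs(records$voltage) > 150)) {
    abort("voltages outside [-150, 150] mV", class = "ionpore_format_error")
  }
  structure(records,
            class = c("iv_family", class(records)),
            condition = condition, construct = construct,
            normalized = FALSE)
}

#' Read delimited I-V recordings
#'
#' Expects columns \code{voltage_mV}, \code{current_pA}, \code{replicate}
#' and optionally \code{construct} (comma- or tab-delimited, with header).
#'
#' @param path File path.
#' @param condition A \code{\link{bi_ionic_condition}} applied to every
#'   construct.
#' @return A named list of \code{iv_family} objects, one per construct.
#' @export
read_iv <- function(path, condition = bi_ionic_condition()) {
  if (!file.exists(path)) {
    abort(paste0("I-V file not found: ", path), class = "ionpore_io_error")
  }
  header <- readLines(path, n = 1)
  df <- if (grepl(",", header)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, sep = "", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  need <- c("voltage_mV", "current_pA", "replicate")
  if (!all(need %in% names(df))) {
    abort(paste0("I-V file must have columns ",
                 paste(need, collapse = ", ")),
          class = "ionpore_format_error")
  }
  if (!"construct" %in% names(df)) df$construct <- "WT"
  fams <- lapply(split(df, df$construct), function(d) {
    iv_family(tibble(voltage = d$voltage_mV, current = d$current_pA,
                     replicate = d$replicate),
              condition = condition, construct = d$construct[1])
  })
  fams
}

#' Normalize currents to the +100 mV current of each replicate
#'
#' Mirrors the standard presentation of whole-cell families: every current
#' of a replicate is divided by that replicate's current at +100 mV, so all
#' replicates read 1.0 there.
#'
#' @param family An \code{iv_family}.
#' @return The normalized family (\code{normalized} attribute set).
#' @export
normalize_iv <- function(family) {
  stopifnot(inherits(family, "iv_family"))
  out <- dplyr::group_modify(
    dplyr::group_by(as_tibble(family), .data$replicate),
    function(d, key) {
      ref <- d$current[abs(d$voltage - 100) < 1e-9]
      if (length(ref) == 0) {
        abort(paste0("replicate ", key$replicate,
                     " has no +100 mV record to normalize by"),
              class = "ionpore_normalization_error")
      }
      if (abs(ref[1]) < .Machine$double.eps) {
        abort(paste0("replicate ", key$replicate,
                     " has zero current at +100 mV"),
              class = "ionpore_degenerate_recording")
      }
      d$current <- d$current / ref[1]
      d
    })
  out <- dplyr::ungroup(out)[, names(family)]
  structure(as_tibble(out),
            class = class(family),
            condition = attr(family, "condition"),
            construct = attr(family, "construct"),
            normalized = TRUE)
}

# zero crossing of one replicate's I-V curve by linear interpolation
replicate_erev <- function(voltage, current, replicate_id) {
  o <- order(voltage)
  v <- voltage[o]; i <- current[o]
  if (any(i == 0)) return(v[which(i == 0)[1]])
  sgn <- sign(i)
  flips <- which(sgn[-1] != sgn[-length(sgn)])
  if (length(flips) == 0) {
    abort(paste0("replicate ", replicate_id,
                 ": current never changes sign in the recorded range"),
          class = "ionpore_out_of_range")
  }
  crossings <- vapply(flips, function(k) {
    v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
  }, numeric(1))
  if (length(flips) > 1) {
    abort(paste0("replicate ", replicate_id,
                 ": multiple zero crossings at ",
                 paste(sprintf("%.1f", crossings), collapse = ", "),
                 " mV"),
          class = "ionpore_ambiguous_crossing")
  }
  crossings[1]
}

#' Estimate the reversal potential of an I-V family
#'
#' Per replicate, the reversal potential is the zero crossing of the I-V
#' curve by linear interpolation between the bracketing voltage steps; the
#' family value is the replicate mean with its standard error. Normalization
#' does not affect the crossing, so raw and normalized families give the
#' same estimate.
#'
#' @param family An \code{iv_family}.
#' @return An \code{erev_fit} object; see \code{tidy()} for per-replicate
#'   crossings and \code{glance()} for the summary.
#' @export
estimate_erev <- function(family) {
  stopifnot(inherits(family, "iv_family"))
  reps <- split(as_tibble(family), family$replicate)
  per <- tibble(
    replicate = names(reps),
    erev = vapply(names(reps), function(r) {
      replicate_erev(reps[[r]]$voltage, reps[[r]]$current, r)
    }, numeric(1))
  )
  n <- nrow(per)
  structure(
    list(per_replicate = per,
         erev = mean(per$erev),
         erev_sem = if (n > 1) sd(per$erev) / sqrt(n) else 0,
         n_replicates = n,
         condition = attr(family, "condition"),
         construct = attr(family, "construct")),
    class = "erev_fit"
  )
}

#' @export
print.erev_fit <- function(x, ...) {
  cat(sprintf("<erev_fit %s: Erev = %.1f +/- %.1f mV (n = %d)>\n",
              x$construct, x$erev, x$erev_sem, x$n_replicates))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.erev_fit <- function(x, ...) x$per_replicate

#' @exportS3Method generics::glance
glance.erev_fit <- function(x, ...) {
  cond <- x$condition
  tibble(construct = x$construct,
         erev_mv = x$erev, erev_sem_mv = x$erev_sem,
         n_replicates = x$n_replicates,
         ratio = permeability_ratio(x$erev, cond))
}

#' Bi-ionic permeability ratio from a reversal potential
#'
#' Computes P_X/P_Y = ([Y+]ext/[X+]int) * exp(-Erev * F / (R * T)) for
#' intracellular cation X and extracellular cation Y. A reversal potential
#' of -55 mV under symmetric 150 mM at 298.15 K gives ~8.5 (i.e. ~9); -65 mV
#' gives ~12.6 (~13).
#'
#' @param erev_mv Reversal potential in mV (internally converted to volts).
#' @param condition A \code{\link{bi_ionic_condition}}.
#' @return The dimensionless permeability ratio.
#' @export
permeability_ratio <- function(erev_mv, condition = bi_ionic_condition()) {
  stopifnot(inherits(condition, "bi_ionic_condition"))
  rt_f <- .GAS_CONSTANT * condition$temperature / .FARADAY  # volts
  (condition$conc_external / condition$conc_internal) *
    exp(-(erev_mv / 1000) / rt_f)
}

#' Selectivity summary over constructs
#'
#' One row per I-V family: mean reversal potential with standard error, the
#' permeability ratio, and the replicate count. Families whose current never
#' reverses in the recorded range (e.g. non-transfected controls) are kept
#' and flagged \code{functional = FALSE} rather than dropped.
#'
#' @param families List of \code{iv_family} objects (optionally named; names
#'   override each family's construct attribute).
#' @return A tibble with columns \code{construct}, \code{erev_mv},
#'   \code{erev_sem_mv}, \code{ratio}, \code{n_replicates},
#'   \code{functional}.
#' @export
selectivity_table <- function(families) {
  if (length(families) == 0) {
    abort("no I-V families supplied", class = "ionpore_empty_input")
  }
  if (inherits(families, "iv_family")) families <- list(families)
  labels <- names(families)
  rows <- lapply(seq_along(families), function(k) {
    fam <- families[[k]]
    lab <- if (!is.null(labels) && nzchar(labels[k])) labels[k]
           else attr(fam, "construct")
    fit <- tryCatch(estimate_erev(fam),
                    ionpore_out_of_range = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(construct = lab, erev_mv = NA_real_,
                    erev_sem_mv = NA_real_, ratio = NA_real_,
                    n_replicates = length(unique(fam$replicate)),
                    functional = FALSE))
    }
    tibble(construct = lab, erev_mv = fit$erev,
           erev_sem_mv = fit$erev_sem,
           ratio = permeability_ratio(fit$erev, attr(fam, "condition")),
           n_replicates = fit$n_replicates, functional = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Plot an I-V family
#'
#' Mean current vs voltage with per-replicate traces.
#' @param object An \code{iv_family}.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.iv_family <- function(object, ...) {
  d <- as_tibble(object)
  m <- dplyr::summarise(dplyr::group_by(d, .data$voltage),
                        current = mean(.data$current), .groups = "drop")
  ylab <- if (isTRUE(attr(object, "normalized"))) "normalized current"
          else "current (pA)"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$voltage, y = .data$current)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                       alpha = 0.3) +
    ggplot2::geom_point(data = m, size = 2) +
    ggplot2::geom_line(data = m, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::labs(x = "voltage (mV)", y = ylab,
                  title = attr(object, "construct")) +
    ggplot2::theme_minimal()
}
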