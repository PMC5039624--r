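# Lipid partition-coefficient analysis for the liposome centrifugation assay.
#
# Model: mole-fraction partition equilibrium.  The ratio of membrane-bound to
# aqueous peptide is proportional to the accessible lipid concentration,
#   bound/free = Kp * [lipid] / [water],
# with [water] = 55.3 M the molar concentration of bulk water.  Kp is the
# dimensionless mole-fraction partition coefficient.

WATER_CONC_M <- 55.3

#' Bound/free peptide ratio under the mole-fraction partition model
#'
#' @param Kp Mole-fraction partition coefficient (>= 0, dimensionless).
#' @param lipid_conc Accessible lipid concentration, M (vectorised).
#' @param water_conc Molar water concentration, M (default 55.3).
#' @return `Kp * lipid_conc / water_conc`; linear in lipid concentration.
#' @export
#' @examples
#' bound_free_ratio(2.4e5, 1.3e-3)  # 5.642
bound_free_ratio <- function(Kp, lipid_conc, water_conc = WATER_CONC_M) {
  check_partition_args(Kp, lipid_conc, water_conc)
  Kp * lipid_conc / water_conc
}

#' Fraction of peptide remaining in the aqueous phase
#'
#' @inheritParams bound_free_ratio
#' @return `1 / (1 + Kp * lipid_conc / water_conc)`, in (0, 1].
#' @export
free_fraction <- function(Kp, lipid_conc, water_conc = WATER_CONC_M) {
  check_partition_args(Kp, lipid_conc, water_conc)
  1 / (1 + Kp * lipid_conc / water_conc)
}

check_partition_args <- function(Kp, lipid_conc, water_conc) {
  if (any(Kp < 0) || any(!is.finite(Kp)))
    stop_validation("Kp must be finite and >= 0")
  if (any(lipid_conc < 0) || any(!is.finite(lipid_conc)))
    stop_validation("lipid_conc must be finite and >= 0")
  if (length(water_conc) != 1 || !is.finite(water_conc) || water_conc <= 0)
    stop_validation("water_conc must be a single positive molarity")
}

#' Fit the mole-fraction partition coefficient
#'
#' Converts each centrifugation-assay measurement to a bound/free ratio
#' `(total - free) / free` and fits the linear-through-origin partition model
#' by ordinary least squares.  Because the model is linear in Kp the least-
#' squares solution is closed form and the fit is exactly deterministic.
#'
#' Free signals may be HPLC peak areas rather than concentrations: when a
#' zero-lipid control row is present, signals are converted to concentration
#' through that point (free = total at zero lipid); only ratios enter the
#' fit, so the signal units cancel.
#'
#' Measurements with `free_signal == 0` have an infinite bound/free ratio;
#' they are censored (excluded with a warning).  An all-censored input is an
#' error.
#'
#' @param measurements data.frame with columns `lipid_conc_M`, `free_signal`
#'   and `peptide_total_uM` (constant across rows).
#' @param water_conc Molar water concentration, M.
#' @param leaflet_fraction Fraction of total lipid accessible to the peptide
#'   (default 1 = total lipid; 0.5 would count only the outer leaflet).
#' @return A `partition_fit`: `Kp`, `water_conc`, `rss`, `se_Kp`, `n_used`,
#'   `censored` (row indices), `ratios` table.
#' @export
#' @examples
#' lip <- c(0.2, 0.5, 0.9, 1.3) * 1e-3
#' m <- data.frame(lipid_conc_M = lip,
#'                 free_signal = 10 * free_fraction(2.4e5, lip),
#'                 peptide_total_uM = 10)
#' fit_kp(m)
fit_kp <- function(measurements, water_conc = WATER_CONC_M,
                   leaflet_fraction = 1) {
  m <- as.data.frame(measurements)
  need <- c("lipid_conc_M", "free_signal", "peptide_total_uM")
  if (!all(need %in% names(m)))
    stop_validation("measurements need columns: ", paste(need, collapse = ", "))
  if (any(m$lipid_conc_M < 0) || any(m$free_signal < 0))
    stop_validation("negative lipid concentration or free signal")
  if (length(unique(m$peptide_total_uM)) != 1)
    stop_validation("peptide_total_uM must be constant across the assay")
  if (leaflet_fraction <= 0 || leaflet_fraction > 1)
    stop_validation("leaflet_fraction must be in (0, 1]")

  total <- m$peptide_total_uM[1]
  # area -> concentration through the zero-lipid control when present
  ctrl <- which(m$lipid_conc_M == 0)
  scale <- if (length(ctrl) > 0) total / mean(m$free_signal[ctrl]) else 1
  free <- m$free_signal * scale
  over <- free > total * (1 + 1e-9)
  if (any(over)) {
    warning(sprintf("%d measurement(s) with free > total clamped to total",
                    sum(over)), call. = FALSE)
    free[over] <- total
  }
  lipid <- m$lipid_conc_M * leaflet_fraction
  nz <- lipid > 0
  if (sum(nz) < 2 || length(unique(lipid[nz])) < 2)
    stop_validation("need >= 2 measurements at distinct nonzero lipid ",
                    "concentrations")
  censored <- which(nz & free == 0)
  if (length(censored) > 0)
    warning(sprintf("censored %d measurement(s) with zero free signal ",
                    length(censored)),
            "(bound/free ratio infinite)", call. = FALSE)
  use <- nz & free > 0
  if (!any(use))
    stop_data("all measurements censored; cannot fit Kp")
  ratio <- (total - free[use]) / free[use]
  x <- lipid[use] / water_conc
  Kp <- sum(x * ratio) / sum(x^2)       # OLS through the origin
  Kp <- max(Kp, 0)
  resid <- ratio - Kp * x
  rss <- sum(resid^2)
  n <- length(ratio)
  se_Kp <- if (n > 1) sqrt(rss / (n - 1) / sum(x^2)) else NA_real_
  structure(list(Kp = Kp, water_conc = water_conc, rss = rss, se_Kp = se_Kp,
                 n_used = n, censored = censored,
                 ratios = data.frame(lipid_conc_M = lipid[use],
                                     bound_free = ratio)),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("<partition_fit> Kp = %.4g (se %.3g), n = %d, RSS = %.4g\n",
              x$Kp, x$se_Kp, x$n_used, x$rss))
  if (length(x$censored))
    cat(sprintf("  censored rows: %s\n", paste(x$censored, collapse = ", ")))
  invisible(x)
}

#' Percent change of a fitted constant relative to a reference
#'
#' The wild-type-vs-mutant comparison statistic:
#' `100 * (1 - new_value / ref_value)`.  Positive output is a decrease,
#' negative an increase.  Values are kept at full precision; round only at
#' the reporting layer.
#'
#' @param ref_value Reference (e.g. wild-type) value, > 0.
#' @param new_value Comparison (e.g. mutant) value.
#' @return Percent change (vectorised over `new_value`).
#' @export
#' @examples
#' percent_change(2.4e5, 0.11e5)  # 95.42 -> reported as 95
percent_change <- function(ref_value, new_value) {
  if (any(ref_value <= 0) || any(!is.finite(ref_value)))
    stop_validation("ref_value must be finite and > 0")
  100 * (1 - new_value / ref_value)
}

#' Tabulate a panel of partition fits against a reference
#'
#' @param fits Named list of `partition_fit` objects (or bare Kp values);
#'   the first entry is the reference unless `ref` names another.
#' @param ref Name of the reference entry.
#' @param path Optional CSV output path.
#' @return data.frame: `variant`, `Kp`, `percent_change` (rounded to integer
#'   in the `percent_change_rounded` column only).
#' @export
compare_partition <- function(fits, ref = names(fits)[1], path = NULL) {
  kp <- vapply(fits, function(f) if (inherits(f, "partition_fit")) f$Kp else
    as.numeric(f), numeric(1))
  if (!ref %in% names(kp)) stop_validation("unknown reference: ", ref)
  pc <- percent_change(kp[[ref]], kp)
  out <- data.frame(variant = names(kp), Kp = unname(kp),
                    percent_change = unname(pc),
                    percent_change_rounded = round(unname(pc)),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Write a partition-fit report
#' @param fit A `partition_fit`.
#' @param path Output path; `.json` selects JSON, otherwise CSV.
#' @return The report list, invisibly.
#' @export
write_partition_fit <- function(fit, path) {
  rep <- list(Kp = fit$Kp, water_conc_M = fit$water_conc, rss = fit$rss,
              se_Kp = fit$se_Kp, n_used = fit$n_used)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(rep), path, row.names = FALSE)
  }
  invisible(rep)
}
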