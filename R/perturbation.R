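# Chemical-shift-perturbation mapping and exchange-broadening analysis.

#' Combined 1H/15N chemical-shift perturbation
#'
#' The combined shift change for one amide,
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}}
#' where `alpha` down-weights the wider 15N dispersion (default 0.15, the
#' conventional scaling for amide nitrogens).
#'
#' @param dH,dN Shift differences in ppm (1H and 15N); vectors recycle.
#' @param alpha 15N scaling factor, > 0.
#' @return Combined shift change, ppm (>= 0); NA propagates.
#' @export
#' @examples
#' combined_shift(0.03, 0.20)  # 0.042426
combined_shift <- function(dH, dN, alpha = 0.15) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stop_validation("alpha must be a single positive number")
  if (any(!is.finite(dH) & !is.na(dH)) || any(!is.finite(dN) & !is.na(dN)))
    stop_validation("non-finite shift difference")
  sqrt(dH^2 + (alpha * dN)^2)
}

#' Per-residue perturbation profile across a titration
#'
#' Computes, for every assignment in the series, the 1H and 15N shift changes
#' relative to the reference point, the combined shift change, and the raw
#' intensity ratio at each titration point.  Assignments missing at a point
#' (e.g. broadened beyond detection) are `NA` with the `missing` flag set.
#'
#' @param series A [match_series()] result.
#' @param alpha 15N scaling factor passed to [combined_shift()].
#' @return A data.frame of class `csp_profile`, one row per assignment x
#'   point: `assignment`, `residue`, `atom_group`, `point`, `titrant_conc`,
#'   `delta_H`, `delta_N`, `combined`, `intensity_ratio`, `missing`.
#' @export
csp_profile <- function(series, alpha = 0.15) {
  if (!inherits(series, "titration_series"))
    stop_validation("'series' must be a titration_series (see match_series)")
  ref <- series$reference
  if (is.null(ref) || nrow(ref) == 0)
    stop_validation("series has no reference point")
  ref_key <- assignment_key(ref)
  out <- list()
  for (i in seq_along(series$points)) {
    pt <- series$points[[i]]
    pt_key <- assignment_key(pt)
    idx <- match(ref_key, pt_key)
    dH <- pt$shift_H[idx] - ref$shift_H
    dN <- pt$shift_N[idx] - ref$shift_N
    iratio <- pt$intensity[idx] / ref$intensity
    out[[i]] <- data.frame(
      assignment = ref_key,
      residue = ref$residue,
      atom_group = ref$atom_group,
      point = i,
      titrant_conc = series$titrant_conc[i],
      delta_H = dH,
      delta_N = dN,
      combined = combined_shift(dH, dN, alpha),
      intensity_ratio = iratio,
      missing = is.na(idx),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "n_points") <- length(series$points)
  class(res) <- c("csp_profile", "data.frame")
  res
}

endpoint_rows <- function(profile) {
  profile[profile$point == attr(profile, "n_points"), , drop = FALSE]
}

#' Significance cutoff for endpoint chemical-shift perturbations
#'
#' Implements the standard-deviation significance rule: the cutoff is the
#' population standard deviation of all endpoint combined shift changes
#' (backbone amides only), and a residue is significant when its endpoint
#' combined shift strictly exceeds the cutoff.  The SD is computed once over
#' all non-missing values, with no iterative outlier trimming.
#'
#' Degenerate case: when all values are equal and positive the SD is 0 and
#' every residue is significant under the strict inequality; all-zero values
#' yield an empty significant set.
#'
#' @param x A `csp_profile` (endpoint values are extracted, sidechain NH
#'   peaks excluded from the SD pool), or a named numeric vector of endpoint
#'   combined shifts.
#' @return A `csp_result`: list with `endpoint` (named numeric), `cutoff`,
#'   `significant` (character vector), `broadened_out` (assignments present
#'   in the reference, absent at the endpoint).
#' @export
significance_cutoff <- function(x) {
  broadened <- character()
  if (inherits(x, "csp_profile")) {
    ep <- endpoint_rows(x)
    ep <- ep[ep$atom_group == "bb", , drop = FALSE]
    broadened <- ep$assignment[ep$missing]
    vals <- stats::setNames(ep$combined, ep$assignment)
  } else {
    vals <- x
    if (is.null(names(vals))) names(vals) <- paste0("r", seq_along(vals))
  }
  obs <- vals[!is.na(vals)]
  if (length(obs) < 3)
    stop_validation("need at least 3 non-missing endpoint values to define ",
                    "an SD cutoff (got ", length(obs), ")")
  mu <- mean(obs)
  cutoff <- sqrt(mean((obs - mu)^2))  # population SD (ddof 0)
  structure(list(endpoint = vals,
                 cutoff = cutoff,
                 significant = names(obs)[obs > cutoff],
                 broadened_out = broadened),
            class = "csp_result")
}

#' @export
print.csp_result <- function(x, ...) {
  cat(sprintf("<csp_result> cutoff (1 SD) = %.4f ppm\n", x$cutoff))
  cat(sprintf("  significant (%d): %s\n", length(x$significant),
              paste(x$significant, collapse = ", ")))
  if (length(x$broadened_out))
    cat(sprintf("  broadened out (%d): %s\n", length(x$broadened_out),
                paste(x$broadened_out, collapse = ", ")))
  invisible(x)
}

#' Quantify exchange broadening across a titration
#'
#' Peak intensities at each titration point are first rescaled so that the
#' median intensity ratio over a user-supplied set of unaffected reference
#' residues equals 1 -- correcting for dilution and receiver-gain differences
#' between spectra.  The extent of broadening at the endpoint is then
#' \deqn{B = 100\,(1 - I/I_{ref}),} clipped to \[0, 100\].  Peaks present in
#' the reference but lost at the endpoint get B = 100.
#'
#' Severity tiers: `severe` = lost peak or B >= `severe_threshold`;
#' `significant` = B > 50\% of the mean broadening over all residues with a
#' B value; `moderate` = B in (25\%, 50\%\] of the mean; `none` otherwise.
#'
#' @param series A `titration_series`.
#' @param reference_set Assignments assumed unaffected by binding, used for
#'   intensity normalisation; must be present at the endpoint.
#' @param severe_threshold B at or above which a retained peak counts as
#'   severely broadened (default 90).
#' @return A `broadening_result`: data.frame `table`
#'   (`assignment`, `residue`, `atom_group`, `B`, `severity`, `lost`),
#'   plus `mean_broadening` and the per-point `scale` factors applied.
#' @export
broadening_profile <- function(series, reference_set,
                               severe_threshold = 90) {
  if (!inherits(series, "titration_series"))
    stop_validation("'series' must be a titration_series")
  if (length(reference_set) == 0)
    stop_validation("reference_set must be non-empty")
  ref <- series$reference
  ref_key <- assignment_key(ref)
  miss_ref <- setdiff(reference_set, ref_key)
  if (length(miss_ref) > 0)
    stop_validation("reference_set residues absent from the reference list: ",
                    paste(miss_ref, collapse = ", "))
  n_pt <- length(series$points)
  scales <- numeric(n_pt)
  for (i in seq_len(n_pt)) {
    pt <- series$points[[i]]
    idx <- match(reference_set, assignment_key(pt))
    ratios <- pt$intensity[idx] / ref$intensity[match(reference_set, ref_key)]
    ratios <- ratios[is.finite(ratios)]
    if (length(ratios) == 0)
      stop_data("all normalisation reference residues lost at point ", i)
    scales[i] <- 1 / stats::median(ratios)
  }
  # endpoint broadening over peaks that carry intensity in the reference
  ep <- series$points[[n_pt]]
  ep_key <- assignment_key(ep)
  has_int <- !is.na(ref$intensity)
  keep <- which(has_int)
  idx <- match(ref_key[keep], ep_key)
  raw <- ep$intensity[idx] / ref$intensity[keep]
  scaled <- raw * scales[n_pt]
  lost <- is.na(idx)
  B <- 100 * (1 - scaled)
  B[lost] <- 100
  B <- pmin(pmax(B, 0), 100)
  meanB <- mean(B)
  severity <- rep("none", length(B))
  severity[B > 0.25 * meanB] <- "moderate"
  severity[B > 0.50 * meanB] <- "significant"
  severity[lost | B >= severe_threshold] <- "severe"
  tab <- data.frame(assignment = ref_key[keep],
                    residue = ref$residue[keep],
                    atom_group = ref$atom_group[keep],
                    B = B, severity = severity, lost = lost,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, mean_broadening = meanB, scale = scales,
                 severe_threshold = severe_threshold),
            class = "broadening_result")
}

#' @export
print.broadening_result <- function(x, ...) {
  cat(sprintf("<broadening_result> mean broadening %.1f%%\n", x$mean_broadening))
  for (s in c("severe", "significant", "moderate")) {
    r <- x$table$assignment[x$table$severity == s]
    if (length(r)) cat(sprintf("  %-11s: %s\n", s, paste(r, collapse = ", ")))
  }
  invisible(x)
}

#' Shift-trajectory colinearity between two titrations
#'
#' For each residue shared between two series, computes the cosine of the
#' angle between the endpoint shift vectors in (delta_H, alpha * delta_N)
#' space.  A cosine near 1 means the peak moves along the same trajectory in
#' both titrations -- the signature of a shared underlying equilibrium (e.g.
#' micelle binding enhanced, not redirected, by a second partner).
#'
#' Residues whose endpoint vector magnitude falls below `noise_floor` in
#' either series are flagged indeterminate (`NA` cosine): direction is
#' meaningless within noise.
#'
#' @param series_A,series_B Two `titration_series` sharing residues.
#' @param alpha 15N scaling factor.
#' @param noise_floor Minimum combined shift magnitude, ppm, for a defined
#'   direction (default 0.005).
#' @return data.frame: `assignment`, `cosine`, `mag_A`, `mag_B`,
#'   `indeterminate`.
#' @export
trajectory_colinearity <- function(series_A, series_B, alpha = 0.15,
                                   noise_floor = 0.005) {
  pa <- endpoint_rows(csp_profile(series_A, alpha))
  pb <- endpoint_rows(csp_profile(series_B, alpha))
  shared <- intersect(pa$assignment, pb$assignment)
  if (length(shared) == 0)
    stop_validation("series share no assignments")
  ia <- match(shared, pa$assignment); ib <- match(shared, pb$assignment)
  va <- cbind(pa$delta_H[ia], alpha * pa$delta_N[ia])
  vb <- cbind(pb$delta_H[ib], alpha * pb$delta_N[ib])
  mag_a <- sqrt(rowSums(va^2)); mag_b <- sqrt(rowSums(vb^2))
  cosine <- rowSums(va * vb) / (mag_a * mag_b)
  indet <- is.na(cosine) | mag_a < noise_floor | mag_b < noise_floor
  cosine[indet] <- NA_real_
  data.frame(assignment = shared, cosine = cosine,
             mag_A = mag_a, mag_B = mag_b, indeterminate = indet,
             stringsAsFactors = FALSE)
}

#' Write the per-residue perturbation/broadening summary table
#'
#' @param profile A `csp_profile`.
#' @param csp A `csp_result` from [significance_cutoff()].
#' @param broadening Optional `broadening_result`.
#' @param path Output CSV path; `NULL` returns the data.frame only.
#' @return The summary data.frame, invisibly if written.
#' @export
write_csp_table <- function(profile, csp, broadening = NULL, path = NULL) {
  ep <- endpoint_rows(profile)
  out <- data.frame(residue = ep$assignment,
                    endpoint_ddH = ep$delta_H,
                    endpoint_ddN = ep$delta_N,
                    combined = ep$combined,
                    significant = ep$assignment %in% csp$significant,
                    stringsAsFactors = FALSE)
  if (!is.null(broadening)) {
    idx <- match(out$residue, broadening$table$assignment)
    out$B_percent <- broadening$table$B[idx]
    out$severity <- broadening$table$severity[idx]
  } else {
    out$B_percent <- NA_real_
    out$severity <- NA_character_
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
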