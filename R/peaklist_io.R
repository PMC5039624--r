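# Peak-list reading, validation, matching and writing.
#
# A peak list is a data.frame with one row per assigned amide NH cross-peak:
#   residue    - residue identifier, one-letter code + WT sequence number
#                (e.g. "R24"); the non-native N-terminal Ser is residue 0
#   atom_group - "bb" (backbone NH) or "sc" (sidechain NH, e.g. Trp indole)
#   shift_H    - 1H chemical shift, ppm
#   shift_N    - 15N chemical shift, ppm
#   intensity  - peak height, arbitrary units (NA = not measured)
# plus a "condition" attribute describing the titration point.

#' Construct a peak list
#'
#' Builds and validates a `peak_list` object, the container for one titration
#' point of an HSQC series.
#'
#' @param residue Character vector of residue identifiers, e.g. `"R24"`.
#' @param shift_H,shift_N Chemical shifts in ppm (1H and 15N dimensions).
#' @param intensity Peak heights (arbitrary units); `NA` for shift-only lists.
#' @param atom_group `"bb"` for backbone NH, `"sc"` for sidechain NH.
#' @param condition List describing the sample: `labelled_uM` (concentration
#'   of the observed species, uM), `titrant` (identity), `titrant_conc`
#'   (uM or \% w/v), `temperature_C`.
#' @return A `peak_list` data.frame.
#' @export
#' @examples
#' peak_list(residue = c("R24", "W25"), shift_H = c(8.45, 10.1),
#'           shift_N = c(121.3, 129.5), intensity = c(1e6, 8e5),
#'           atom_group = c("bb", "sc"))
peak_list <- function(residue, shift_H, shift_N, intensity = NA_real_,
                      atom_group = "bb",
                      condition = list(labelled_uM = NA_real_,
                                       titrant = NA_character_,
                                       titrant_conc = 0,
                                       temperature_C = NA_real_)) {
  n <- length(residue)
  x <- data.frame(residue = as.character(residue),
                  atom_group = rep_len(as.character(atom_group), n),
                  shift_H = as.numeric(shift_H),
                  shift_N = as.numeric(shift_N),
                  intensity = rep_len(as.numeric(intensity), n),
                  stringsAsFactors = FALSE)
  attr(x, "condition") <- condition
  class(x) <- c("peak_list", "data.frame")
  validate_peaklist(x)
}

#' @export
print.peak_list <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("<peak_list> %d peaks", nrow(x)))
  if (!is.null(cond) && !is.na(cond$titrant_conc))
    cat(sprintf(" | titrant %s at %s", cond$titrant %||% "?",
                format(cond$titrant_conc)))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

# Assignment key used for matching across titration points: backbone peaks
# are keyed by residue alone, sidechain NH peaks get a "-sc" suffix.
assignment_key <- function(x) {
  ifelse(x$atom_group == "sc", paste0(x$residue, "-sc"), x$residue)
}

validate_peaklist <- function(x) {
  key <- assignment_key(x)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0)
    stop_validation("duplicate assignments in peak list: ",
                    paste(dup, collapse = ", "))
  bad_H <- x$shift_H < -2 | x$shift_H > 15
  bad_N <- x$shift_N < 90 | x$shift_N > 140
  if (any(bad_H, na.rm = TRUE))
    stop_validation("1H shifts outside [-2, 15] ppm for: ",
                    paste(key[which(bad_H)], collapse = ", "))
  if (any(bad_N, na.rm = TRUE))
    stop_validation("15N shifts outside [90, 140] ppm for: ",
                    paste(key[which(bad_N)], collapse = ", "))
  if (any(!is.na(x$intensity) & x$intensity < 0))
    stop_validation("negative intensities for: ",
                    paste(key[which(x$intensity < 0)], collapse = ", "))
  cond <- attr(x, "condition")
  if (!is.null(cond$titrant_conc) && !is.na(cond$titrant_conc) &&
      cond$titrant_conc < 0)
    stop_validation("titrant concentration must be >= 0")
  x
}

# Parse a Sparky-style assignment token, e.g. "R24N-H" or "W25NE1-HE1".
# Returns list(residue, atom_group) or NULL if the token does not match the
# grammar <res_letters><number><N-atom>-<H-atom>.
parse_assignment <- function(token) {
  m <- regmatches(token,
                  regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z0-9]*)-([A-Za-z0-9]*)$",
                          token))[[1]]
  if (length(m) == 0) return(NULL)
  res_code <- m[2]; num <- m[3]; natom <- toupper(m[4]); hatom <- toupper(m[5])
  # one- or three-letter residue codes are accepted; stored as given + number
  sc <- natom %in% c("NE1", "ND1", "NE2", "ND2", "NH1", "NH2", "NZ", "SC") ||
    hatom == "SC"
  if (natom == "" && hatom %in% c("H", "HN", "")) sc <- FALSE
  list(residue = paste0(res_code, num),
       atom_group = if (sc) "sc" else "bb")
}

#' Parse an assigned peak list
#'
#' Reads a per-titration-point peak list from text in one of two dialects:
#'
#' * `"sparky"`: whitespace-separated columns
#'   `Assignment  w1(15N)  w2(1H)  Height`, the usual Sparky `.list` export.
#'   Assignments follow the grammar `<res><number><Natom>-<Hatom>`; an `NE1`
#'   nitrogen (or an explicit `sc` tag) marks a sidechain NH such as the Trp
#'   indole.  The `Height` column is optional (shift-only lists).
#' * `"csv"`: header-mandatory CSV with columns
#'   `residue,atom_group,shift_H_ppm,shift_N_ppm,intensity`.
#'
#' Rows whose assignment cannot be parsed are collected in the `skipped`
#' attribute and reported via a warning -- never silently dropped.
#'
#' @param text Raw file content (single string or character vector of lines),
#'   or a file path to read.
#' @param dialect `"sparky"` or `"csv"`.
#' @param condition Sample condition list, see [peak_list()].
#' @return A [peak_list()]; attribute `skipped` holds unparseable lines.
#' @export
#' @examples
#' parse_peaklist("Assignment w1 w2 Height\nR24N-H 121.30 8.45 1.0e6",
#'                dialect = "sparky")
parse_peaklist <- function(text, dialect = c("sparky", "csv"),
                           condition = list(labelled_uM = NA_real_,
                                            titrant = NA_character_,
                                            titrant_conc = 0,
                                            temperature_C = NA_real_)) {
  dialect <- match.arg(dialect)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0)
    stop_format("empty peak list (", dialect, " dialect)")
  if (dialect == "sparky") parse_sparky(lines, condition)
  else parse_csv_peaklist(lines, condition)
}

parse_sparky <- function(lines, condition) {
  # optional header starting with "Assignment"
  if (grepl("^\\s*Assignment\\b", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (length(lines) == 0) stop_format("Sparky list contains a header but no data rows")
  rows <- list(); skipped <- character()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 3) { skipped <- c(skipped, ln); next }
    asn <- parse_assignment(f[1])
    w1 <- suppressWarnings(as.numeric(f[2]))  # w1 = 15N by convention
    w2 <- suppressWarnings(as.numeric(f[3]))  # w2 = 1H
    ht <- if (length(f) >= 4) suppressWarnings(as.numeric(f[4])) else NA_real_
    if (is.null(asn) || is.na(w1) || is.na(w2)) { skipped <- c(skipped, ln); next }
    rows[[length(rows) + 1L]] <- data.frame(
      residue = asn$residue, atom_group = asn$atom_group,
      shift_H = w2, shift_N = w1, intensity = ht, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    stop_format("no parseable rows in Sparky list; first line: ", lines[1])
  out <- do.call(rbind, rows)
  if (length(skipped) > 0)
    warning(sprintf("%d unparseable row(s) skipped: %s", length(skipped),
                    paste(utils::head(skipped, 3), collapse = " | ")),
            call. = FALSE)
  pl <- peak_list(out$residue, out$shift_H, out$shift_N, out$intensity,
                  out$atom_group, condition)
  attr(pl, "skipped") <- skipped
  pl
}

csv_cols <- c("residue", "atom_group", "shift_H_ppm", "shift_N_ppm", "intensity")

parse_csv_peaklist <- function(lines, condition) {
  header <- strsplit(trimws(lines[1]), ",")[[1]]
  if (!identical(trimws(header), csv_cols))
    stop_format("malformed CSV header at line 1: expected '",
                paste(csv_cols, collapse = ","), "', got '", lines[1], "'")
  if (length(lines) < 2) stop_format("CSV peak list has a header but no data rows")
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  peak_list(df$residue, df$shift_H_ppm, df$shift_N_ppm,
            df$intensity, df$atom_group, condition)
}

#' Write a peak list
#'
#' Serialises a [peak_list()] in either supported dialect.  Numbers are
#' printed with full precision so that parse -> write -> parse round-trips
#' to an identical list.
#'
#' @param x A `peak_list`.
#' @param path Output file; if `NULL` the text is returned invisibly.
#' @inheritParams parse_peaklist
#' @return The file content, invisibly.
#' @export
write_peaklist <- function(x, path = NULL, dialect = c("sparky", "csv")) {
  dialect <- match.arg(dialect)
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.15g", v))
  if (dialect == "sparky") {
    asn <- ifelse(x$atom_group == "sc",
                  paste0(x$residue, "NE1-HE1"),
                  paste0(x$residue, "N-H"))
    body <- sprintf("%s %s %s %s", asn, num(x$shift_N), num(x$shift_H),
                    num(x$intensity))
    txt <- c("Assignment w1 w2 Height", body)
  } else {
    body <- sprintf("%s,%s,%s,%s,%s", x$residue, x$atom_group,
                    num(x$shift_H), num(x$shift_N), num(x$intensity))
    txt <- c(paste(csv_cols, collapse = ","), body)
  }
  txt <- paste0(paste(txt, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Assemble a titration series from matched peak lists
#'
#' Combines a reference (titrant = 0) peak list with ordered titration points
#' into a `titration_series`.  Peaks are matched strictly by assignment label
#' -- never by nearest chemical shift.  Assignments present in the reference
#' but absent at a point are recorded as missing with reason
#' `"broadened_out_candidate"`; assignments appearing only at later points
#' are recorded as `"absent_in_reference"`.
#'
#' @param reference `peak_list` at zero titrant.
#' @param points List of `peak_list`s, ordered by strictly ascending titrant
#'   concentration (taken from each list's condition).
#' @param labelled_total Concentration of the observed (labelled) species,
#'   uM, constant across points; defaults to the reference condition.
#' @return A `titration_series`: list with elements `reference`, `points`,
#'   `titrant_conc`, `labelled_total`, and a `missing` data.frame
#'   (`assignment`, `point`, `reason`).
#' @export
match_series <- function(reference, points, labelled_total = NULL) {
  stopifnot(inherits(reference, "peak_list"))
  if (!is.list(points) || length(points) == 0)
    stop_validation("'points' must be a non-empty list of peak lists")
  ref_key <- assignment_key(reference)
  conc <- vapply(points, function(p) {
    cc <- attr(p, "condition")$titrant_conc
    if (is.null(cc) || is.na(cc)) NA_real_ else as.numeric(cc)
  }, numeric(1))
  if (anyNA(conc))
    stop_validation("every titration point needs a titrant concentration")
  if (any(diff(conc) <= 0))
    stop_validation("titration points must be strictly ordered by ascending ",
                    "titrant concentration (got: ",
                    paste(conc, collapse = ", "), ")")
  if (is.null(labelled_total))
    labelled_total <- attr(reference, "condition")$labelled_uM
  for (p in points) {
    lt <- attr(p, "condition")$labelled_uM
    if (!is.null(lt) && !is.na(lt) && !is.na(labelled_total) &&
        !isTRUE(all.equal(lt, labelled_total)))
      stop_validation("labelled-species concentration differs between points (",
                      lt, " vs ", labelled_total, " uM)")
  }
  missing <- data.frame(assignment = character(), point = integer(),
                        reason = character(), stringsAsFactors = FALSE)
  for (i in seq_along(points)) {
    key_i <- assignment_key(points[[i]])
    if (length(intersect(key_i, ref_key)) == 0)
      stop_validation("point ", i, " shares no assignments with the reference")
    gone <- setdiff(ref_key, key_i)
    new <- setdiff(key_i, ref_key)
    if (length(gone) > 0)
      missing <- rbind(missing, data.frame(
        assignment = gone, point = i, reason = "broadened_out_candidate",
        stringsAsFactors = FALSE))
    if (length(new) > 0)
      missing <- rbind(missing, data.frame(
        assignment = new, point = 0L, reason = "absent_in_reference",
        stringsAsFactors = FALSE))
  }
  structure(list(reference = reference, points = points,
                 titrant_conc = conc, labelled_total = labelled_total,
                 missing = missing),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d points, titrant conc: %s\n",
              length(x$points), paste(x$titrant_conc, collapse = ", ")))
  cat(sprintf("  reference: %d peaks; labelled total: %s uM; %d missing entries\n",
              nrow(x$reference), format(x$labelled_total), nrow(x$missing)))
  invisible(x)
}

#' All assignments occurring anywhere in a series
#' @param series A `titration_series`.
#' @return Character vector of assignment keys (union over all points).
#' @export
series_assignments <- function(series) {
  keys <- assignment_key(series$reference)
  for (p in series$points) keys <- union(keys, assignment_key(p))
  keys
}
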