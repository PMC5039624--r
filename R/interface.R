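# Interface-restraint derivation: active/passive residue selection, CNS-style
# ambiguous interaction restraint (AIR) emission, and restraint accounting.

#' Select active and passive interface residues from evidence
#'
#' Translates perturbation, broadening and mutagenesis evidence into the
#' active/passive residue sets used to build ambiguous interaction restraints
#' for data-driven docking:
#'
#' * **active**: severely broadened OR mutagenesis-confirmed residues that
#'   are surface exposed -- direct evidence of contact;
#' * **passive**: surface-exposed residues with supporting evidence
#'   (moderate/significant broadening or a significant CSP) not already
#'   active.
#'
#' Surface exposure is an input flag (computed externally by any
#' accessibility method); a residue flagged mutagenesis-confirmed but buried
#' is contradictory evidence and is excluded with a warning.
#'
#' @param evidence data.frame with columns `residue`, `partner` (segment
#'   id, e.g. `"A"`/`"B"`), `severity` (`"severe"`, `"significant"`,
#'   `"moderate"`, `"none"`), `csp_significant` (logical),
#'   `mutagenesis_hit` (logical), `surface_exposed` (logical).
#' @return An `interface_spec`: named list of partners, each with `active`
#'   and `passive` character vectors; `excluded` records contradictory rows.
#' @export
select_active_passive <- function(evidence) {
  need <- c("residue", "partner", "severity", "csp_significant",
            "mutagenesis_hit", "surface_exposed")
  if (!all(need %in% names(evidence)))
    stop_validation("evidence needs columns: ", paste(need, collapse = ", "))
  partners <- unique(evidence$partner)
  if (length(partners) < 2)
    stop_validation("evidence must cover both binding partners")
  contradictory <- evidence$mutagenesis_hit & !evidence$surface_exposed
  if (any(contradictory))
    warning("mutagenesis-confirmed but buried residue(s) excluded: ",
            paste(evidence$residue[contradictory], collapse = ", "),
            call. = FALSE)
  ev <- evidence[!contradictory, , drop = FALSE]
  spec <- lapply(partners, function(p) {
    e <- ev[ev$partner == p, , drop = FALSE]
    active <- e$residue[(e$severity == "severe" | e$mutagenesis_hit) &
                          e$surface_exposed]
    passive <- e$residue[(e$severity %in% c("significant", "moderate") |
                            e$csp_significant) &
                           e$surface_exposed & !(e$residue %in% active)]
    list(active = unique(active), passive = unique(passive))
  })
  names(spec) <- partners
  structure(list(partners = spec,
                 excluded = evidence$residue[contradictory]),
            class = "interface_spec")
}

#' @export
print.interface_spec <- function(x, ...) {
  cat("<interface_spec>\n")
  for (p in names(x$partners)) {
    cat(sprintf("  partner %s: active {%s}; passive {%s}\n", p,
                paste(x$partners[[p]]$active, collapse = ", "),
                paste(x$partners[[p]]$passive, collapse = ", ")))
  }
  if (length(x$excluded))
    cat("  excluded (buried mutagenesis hits):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

residue_number <- function(residue) {
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", residue)))
  if (anyNA(n)) stop_validation("residue identifiers must carry a number: ",
                                paste(residue[is.na(n)], collapse = ", "))
  n
}

#' Emit ambiguous interaction restraints in CNS dialect
#'
#' Writes one ambiguous `assign` statement per active residue of each
#' partner, restraining it against the union of the other partner's active
#' and passive residues:
#' ```
#' assign (segid A and resid 24) ((segid B and resid 45) or ...) 2.0 2.0 0.0
#' ```
#' The distance triple is `target minus plus`: an effective upper bound of
#' `target + plus` (default 2.0 A) on the ambiguous distance, with
#' `target - minus >= 0`.  Statement count is exactly
#' `|active(A)| + |active(B)|`.  Output round-trips byte-identically through
#' [parse_air_tbl()].
#'
#' @param spec An `interface_spec`; at least one partner must have both
#'   active residues and a non-empty opposing selection.
#' @param distance,minus,plus AIR distance parameters, Angstrom.
#' @param path Optional output file.
#' @return Character vector of `assign` lines (one statement per line).
#' @export
emit_air_tbl <- function(spec, distance = 2.0, minus = 2.0, plus = 0.0,
                         path = NULL) {
  if (!inherits(spec, "interface_spec"))
    stop_validation("spec must be an interface_spec")
  if (distance < 0 || minus < 0 || plus < 0 || distance - minus < 0)
    stop_validation("require non-negative bounds with target - minus >= 0")
  partners <- names(spec$partners)
  if (length(partners) != 2)
    stop_validation("AIR emission needs exactly two partners")
  total_active <- sum(vapply(spec$partners,
                             function(p) length(p$active), integer(1)))
  if (total_active == 0)
    stop_data("no active residues in either partner; nothing to emit")
  fmt <- function(x) formatC(x, format = "f", digits = 1)
  lines <- character()
  for (i in 1:2) {
    a <- partners[i]; b <- partners[3 - i]
    opposing <- c(spec$partners[[b]]$active, spec$partners[[b]]$passive)
    for (res in spec$partners[[a]]$active) {
      if (length(opposing) == 0)
        stop_data("active residue ", res, " of partner ", a,
                  " has an empty opposing selection")
      sel <- paste(sprintf("(segid %s and resid %d)", b,
                           residue_number(opposing)),
                   collapse = " or ")
      lines <- c(lines, sprintf(
        "assign (segid %s and resid %d) (%s) %s %s %s",
        a, residue_number(res), sel,
        fmt(distance), fmt(minus), fmt(plus)))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  lines
}

#' Parse a CNS-style AIR table
#'
#' Round-trip reader for [emit_air_tbl()] output: each `assign` line becomes
#' one record with the active selection, the opposing residue list, and the
#' `target/minus/plus` distance triple (effective upper bound
#' `target + plus`).
#'
#' @param text Lines, a single string, or a file path.
#' @return data.frame: `segid_i`, `resid_i`, `segid_j`, `resid_j`
#'   (comma-joined), `target`, `minus`, `plus`.
#' @export
parse_air_tbl <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "!")]
  pat <- paste0("^assign \\(segid (\\S+) and resid ([0-9]+)\\) \\((.+)\\) ",
                "([0-9.]+) ([0-9.]+) ([0-9.]+)$")
  out <- lapply(lines, function(ln) {
    m <- regmatches(ln, regexec(pat, ln))[[1]]
    if (length(m) == 0) stop_format("unparseable assign statement: ", ln)
    terms <- regmatches(m[4],
                        gregexpr("segid (\\S+) and resid ([0-9]+)", m[4]))[[1]]
    segs <- sub("segid (\\S+) and resid ([0-9]+)", "\\1", terms)
    ress <- sub("segid (\\S+) and resid ([0-9]+)", "\\2", terms)
    if (length(unique(segs)) != 1)
      stop_format("mixed segids in opposing selection: ", ln)
    data.frame(segid_i = m[2], resid_i = as.integer(m[3]),
               segid_j = segs[1], resid_j = paste(ress, collapse = ","),
               target = as.numeric(m[5]), minus = as.numeric(m[6]),
               plus = as.numeric(m[7]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Rebuild an emit-style line from one parsed record (used for round-trip
# checking).
air_record_to_line <- function(rec) {
  fmt <- function(x) formatC(x, format = "f", digits = 1)
  resj <- as.integer(strsplit(rec$resid_j, ",")[[1]])
  sel <- paste(sprintf("(segid %s and resid %d)", rec$segid_j, resj),
               collapse = " or ")
  sprintf("assign (segid %s and resid %d) (%s) %s %s %s",
          rec$segid_i, rec$resid_i, sel,
          fmt(rec$target), fmt(rec$minus), fmt(rec$plus))
}

#' Classify a distance restraint by sequence range
#'
#' Standard NOE bookkeeping bins, mutually exclusive:
#' intraresidue (i = j), sequential (|i-j| = 1), medium range
#' (2 <= |i-j| <= 4), long range (|i-j| >= 5).  Symmetric in its arguments.
#'
#' @param residue_i,residue_j Positive residue sequence positions
#'   (vectorised).
#' @return Character vector in
#'   `c("intraresidue", "sequential", "medium", "long")`.
#' @export
classify_restraint_range <- function(residue_i, residue_j) {
  if (any(residue_i < 1) || any(residue_j < 1))
    stop_validation("residue indices must be positive")
  d <- abs(residue_i - residue_j)
  ifelse(d == 0, "intraresidue",
         ifelse(d == 1, "sequential",
                ifelse(d <= 4, "medium", "long")))
}

#' Count restraints per sequence-range category
#'
#' @param records data.frame with columns `residue_i`, `residue_j`, or a
#'   named numeric vector of pre-binned counts (names from
#'   [classify_restraint_range()] categories).
#' @return Named list: `intraresidue`, `sequential`, `medium`, `long`,
#'   `total` (the categories partition the input, so total = sum).
#' @export
#' @examples
#' restraint_stats(c(intraresidue = 193, sequential = 206,
#'                   medium = 116, long = 179))$total  # 694
restraint_stats <- function(records) {
  cats <- c("intraresidue", "sequential", "medium", "long")
  if (is.numeric(records) && !is.null(names(records))) {
    unknown <- setdiff(names(records), cats)
    if (length(unknown) > 0)
      stop_validation("unknown categories: ", paste(unknown, collapse = ", "))
    counts <- stats::setNames(rep(0, 4), cats)
    counts[names(records)] <- records
  } else if (is.data.frame(records)) {
    if (nrow(records) == 0) {
      counts <- stats::setNames(rep(0, 4), cats)
    } else {
      cls <- classify_restraint_range(records$residue_i, records$residue_j)
      counts <- vapply(cats, function(cc) sum(cls == cc), numeric(1))
    }
  } else {
    stop_validation("records must be a data.frame or named count vector")
  }
  as.list(c(counts, total = sum(counts)))
}
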