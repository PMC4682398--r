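## Readers and writers for the per-residue output formats of the external
## predictors whose tracks feed featurization: PSI-BLAST ASCII PSSMs,
## PSIPRED .ss2 secondary structure, IUPred disorder tendencies, FlexPred
## flexibility calls and WESA solvent accessibility. Each reader validates
## the residue column against the expected sequence when one is supplied.

check_profile_sequence <- function(residues, sequence, what, path) {
  if (is.null(sequence)) return(invisible(NULL))
  expected <- strsplit(sequence, "")[[1]]
  if (length(residues) != length(expected)) {
    rlang::abort(paste0(
      what, " profile length ", length(residues),
      " does not match sequence length ", length(expected),
      if (!is.null(path)) paste0(" (", path, ")") else ""
    ))
  }
  mism <- which(residues != expected & residues != UNKNOWN &
                  expected != UNKNOWN)
  if (length(mism) > 0) {
    rlang::abort(paste0(
      what, " residue mismatch at row ", mism[1], ": profile has ",
      residues[mism[1]], ", sequence has ", expected[mism[1]],
      if (!is.null(path)) paste0(" (", path, ")") else ""
    ))
  }
  invisible(NULL)
}

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the `-out_ascii_pssm` layout (two header lines, one row per
#' residue with rank, residue, 20 log-odds columns, 20 weighted-percentage
#' columns and two information columns, then a footer). Only the first 20
#' numeric columns (the log-odds scores) are retained.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional protein sequence string; when given, the residue
#'   column must match it.
#' @return A tibble with columns `position`, `residue` and one numeric
#'   column per amino acid (alphabet order A R N D C Q E G H I L K M F P S T
#'   W Y V).
#' @export
parse_pssm_ascii <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^\\s*\\d+\\s+[A-Z]\\s+-?\\d", lines, value = TRUE)
  if (length(rows) == 0) {
    rlang::abort(paste0("no PSSM rows found in ", path))
  }
  parsed <- lapply(rows, function(l) strsplit(trimws(l), "\\s+")[[1]])
  nfield <- lengths(parsed)
  if (any(nfield < 22)) {
    rlang::abort(paste0(
      "malformed PSSM row in ", path, ": ",
      rows[which(nfield < 22)[1]]
    ))
  }
  pos <- as.integer(vapply(parsed, `[`, character(1), 1))
  res <- vapply(parsed, `[`, character(1), 2)
  scores <- t(vapply(parsed, function(f) as.numeric(f[3:22]), numeric(20)))
  if (anyNA(scores)) {
    rlang::abort(paste0("non-numeric PSSM score in ", path))
  }
  check_profile_sequence(res, sequence, "PSSM", path)
  colnames(scores) <- AA_LETTERS
  dplyr::bind_cols(
    tibble::tibble(position = pos, residue = res),
    tibble::as_tibble(scores)
  )
}

#' @rdname parse_pssm_ascii
#' @param profile A PSSM profile tibble (as returned by
#'   [parse_pssm_ascii()]).
#' @export
write_pssm_ascii <- function(profile, path) {
  header <- c(
    "",
    paste(
      "Last position-specific scoring matrix computed, weighted observed",
      "percentages rounded down, information per position, and relative",
      "weight of gapless real matches to pseudocounts"
    ),
    paste0("           ",
           paste(sprintf("%3s", c(AA_LETTERS, AA_LETTERS)), collapse = " "))
  )
  mat <- as.matrix(profile[, AA_LETTERS])
  body <- vapply(seq_len(nrow(profile)), function(i) {
    paste0(
      sprintf("%5d %s ", profile$position[i], profile$residue[i]),
      paste(sprintf("%3d", as.integer(mat[i, ])), collapse = " "), " ",
      paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
      sprintf("  %4.2f %8.2f", 0, 0)
    )
  }, character(1))
  footer <- c("", "                      K         Lambda",
              "Standard Ungapped    0.1000     0.3000")
  writeLines(c(header, body, footer), path)
  invisible(path)
}

# L x 20 numeric matrix (alphabet columns) from a PSSM profile tibble
pssm_matrix <- function(profile) {
  m <- as.matrix(profile[order(profile$position), AA_LETTERS])
  rownames(m) <- NULL
  m
}

#' Parse a PSIPRED vertical (.ss2) secondary structure file
#'
#' @param path Path to the `.ss2` file.
#' @param sequence Optional sequence string for validation.
#' @return A tibble with columns `position`, `residue`, `state` (one of
#'   `C`/`H`/`E`) and the three state probabilities `p_coil`, `p_helix`,
#'   `p_strand`.
#' @export
parse_ss2 <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^\\s*\\d+\\s+[A-Z]\\s+[CHE]\\s", lines, value = TRUE)
  if (length(rows) == 0) rlang::abort(paste0("no .ss2 rows found in ", path))
  parsed <- lapply(rows, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(lengths(parsed) < 6)) {
    rlang::abort(paste0("malformed .ss2 row in ", path))
  }
  out <- tibble::tibble(
    position = as.integer(vapply(parsed, `[`, character(1), 1)),
    residue = vapply(parsed, `[`, character(1), 2),
    state = vapply(parsed, `[`, character(1), 3),
    p_coil = as.numeric(vapply(parsed, `[`, character(1), 4)),
    p_helix = as.numeric(vapply(parsed, `[`, character(1), 5)),
    p_strand = as.numeric(vapply(parsed, `[`, character(1), 6))
  )
  check_profile_sequence(out$residue, sequence, "secondary structure", path)
  out
}

#' @rdname parse_ss2
#' @param profile An SS profile tibble (as returned by [parse_ss2()]).
#' @export
write_ss2 <- function(profile, path) {
  header <- c("# PSIPRED VFORMAT (PSIPRED V3.3)", "")
  body <- sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                  profile$position, profile$residue, profile$state,
                  profile$p_coil, profile$p_helix, profile$p_strand)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse an IUPred per-residue disorder tendency table
#'
#' Lines starting with `#` are comments; data rows are
#' `position residue tendency` with tendencies in \[0, 1\].
#'
#' @param path Path to the IUPred output.
#' @param sequence Optional sequence string for validation.
#' @return A tibble with columns `position`, `residue`, `tendency`.
#' @export
parse_iupred <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  rows <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(rows) == 0) {
    rlang::abort(paste0("no disorder rows found in ", path))
  }
  parsed <- lapply(rows, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(lengths(parsed) < 3)) {
    rlang::abort(paste0("malformed disorder row in ", path))
  }
  out <- tibble::tibble(
    position = as.integer(vapply(parsed, `[`, character(1), 1)),
    residue = vapply(parsed, `[`, character(1), 2),
    tendency = as.numeric(vapply(parsed, `[`, character(1), 3))
  )
  if (anyNA(out$tendency) || any(out$tendency < 0 | out$tendency > 1)) {
    rlang::abort(paste0("disorder tendency outside [0, 1] in ", path))
  }
  check_profile_sequence(out$residue, sequence, "disorder", path)
  out
}

#' @rdname parse_iupred
#' @param profile A disorder profile tibble.
#' @export
write_iupred <- function(profile, path) {
  header <- c("# IUPred-style disorder tendency",
              "# POS RES TENDENCY")
  body <- sprintf("%5d %s %6.4f", profile$position, profile$residue,
                  profile$tendency)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse a FlexPred per-residue flexibility table
#'
#' Data rows are `position residue call confidence`, where `call` is `F`
#' (flexible) or `R` (rigid) and `confidence` is a non-negative prediction
#' confidence.
#'
#' @param path Path to the FlexPred-style table.
#' @param sequence Optional sequence string for validation.
#' @return A tibble with columns `position`, `residue`, `call`,
#'   `confidence`.
#' @export
parse_flexpred <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  rows <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(rows) == 0) {
    rlang::abort(paste0("no flexibility rows found in ", path))
  }
  parsed <- lapply(rows, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(lengths(parsed) < 4)) {
    rlang::abort(paste0("malformed flexibility row in ", path))
  }
  out <- tibble::tibble(
    position = as.integer(vapply(parsed, `[`, character(1), 1)),
    residue = vapply(parsed, `[`, character(1), 2),
    call = vapply(parsed, `[`, character(1), 3),
    confidence = as.numeric(vapply(parsed, `[`, character(1), 4))
  )
  bad <- setdiff(unique(out$call), c("F", "R"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown flexibility call '", bad[1], "' in ", path))
  }
  if (anyNA(out$confidence) || any(out$confidence < 0)) {
    rlang::abort(paste0("negative flexibility confidence in ", path))
  }
  check_profile_sequence(out$residue, sequence, "flexibility", path)
  out
}

#' @rdname parse_flexpred
#' @param profile A flexibility profile tibble.
#' @export
write_flexpred <- function(profile, path) {
  header <- "# POS RES CALL CONFIDENCE"
  body <- sprintf("%5d %s %s %6.3f", profile$position, profile$residue,
                  profile$call, profile$confidence)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse a WESA per-residue binary solvent accessibility table
#'
#' Data rows are `position residue exposed` with `exposed` in `{0, 1}`
#' (1 = solvent exposed, 0 = buried).
#'
#' @param path Path to the WESA-style table.
#' @param sequence Optional sequence string for validation.
#' @return A tibble with columns `position`, `residue`, `exposed`.
#' @export
parse_wesa <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  rows <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(rows) == 0) {
    rlang::abort(paste0("no accessibility rows found in ", path))
  }
  parsed <- lapply(rows, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(lengths(parsed) < 3)) {
    rlang::abort(paste0("malformed accessibility row in ", path))
  }
  out <- tibble::tibble(
    position = as.integer(vapply(parsed, `[`, character(1), 1)),
    residue = vapply(parsed, `[`, character(1), 2),
    exposed = as.integer(vapply(parsed, `[`, character(1), 3))
  )
  if (anyNA(out$exposed) || !all(out$exposed %in% c(0L, 1L))) {
    rlang::abort(paste0("accessibility calls must be 0/1 in ", path))
  }
  check_profile_sequence(out$residue, sequence, "accessibility", path)
  out
}

#' @rdname parse_wesa
#' @param profile An accessibility profile tibble.
#' @export
write_wesa <- function(profile, path) {
  header <- "# POS RES EXPOSED"
  body <- sprintf("%5d %s %d", profile$position, profile$residue,
                  profile$exposed)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read all external-predictor profiles for a sequence set from a directory
#'
#' Expects per-protein files named `<id>.pssm`, `<id>.ss2`, `<id>.iupred`,
#' `<id>.flexpred` and `<id>.wesa` (any subset of tracks may be present).
#'
#' @param dir Directory holding profile files.
#' @param sequences Sequence tibble; profiles are validated against it.
#' @return A named list with elements `pssm`, `ss`, `disorder`,
#'   `flexibility`, `accessibility`; each is a named list (by protein id) of
#'   per-protein profile tibbles, or `NULL` when no file of that track
#'   exists.
#' @export
read_profile_dir <- function(dir, sequences) {
  track <- function(ext, parser) {
    files <- file.path(dir, paste0(sequences$id, ".", ext))
    present <- file.exists(files)
    if (!any(present)) return(NULL)
    out <- purrr::map2(files[present], sequences$sequence[present], parser)
    stats::setNames(out, sequences$id[present])
  }
  list(
    pssm = track("pssm", parse_pssm_ascii),
    ss = track("ss2", parse_ss2),
    disorder = track("iupred", parse_iupred),
    flexibility = track("flexpred", parse_flexpred),
    accessibility = track("wesa", parse_wesa)
  )
}
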