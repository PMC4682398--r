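#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and returns sequences as a tibble.
#' Sequences are upper-cased and translation stops (`*`) are stripped. The
#' first whitespace-delimited token of each header is used as the id.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `id`, `sequence`, `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1", "MKS", ">P2", "RKAK"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("FASTA file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    rlang::abort(paste0("empty FASTA file: ", path))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    rlang::abort(paste0(
      "malformed FASTA (line ", first, "): expected '>' header, got: ",
      substr(lines[first], 1, 40)
    ))
  }
  empty_headers <- nonblank[trimws(lines[nonblank]) == ">"]
  if (length(empty_headers) > 0) {
    rlang::abort(paste0(
      "malformed FASTA (line ", empty_headers[1], "): empty header"
    ))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- stringr::str_extract(names(set), "^\\S+")
  seqs <- unname(toupper(gsub("\\*", "", as.character(set))))
  if (anyDuplicated(ids)) {
    rlang::abort(paste0(
      "duplicate sequence id in ", path, ": ",
      ids[duplicated(ids)][1]
    ))
  }
  if (any(!nzchar(seqs))) {
    rlang::abort(paste0("zero-length sequence for id ", ids[!nzchar(seqs)][1]))
  }
  tibble::tibble(id = ids, sequence = seqs, length = nchar(seqs))
}

#' Write sequences to FASTA
#'
#' @param sequences Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences$sequence)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a site annotation table
#'
#' Site annotations are a headered TSV with columns `protein_id`, `position`
#' (1-based residue index of a lysine) and `label`
#' (`"positive"`/`"negative"`).
#'
#' @param path Path to the TSV.
#' @param sequences Optional sequence tibble (from [read_fasta()]); when
#'   given, annotations are validated against it (position in range and a K
#'   at the annotated position).
#' @return A tibble with columns `protein_id`, `position`, `label`.
#' @export
read_site_annotations <- function(path, sequences = NULL) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    label = readr::col_character()
  ))
  validate_annotations(ann, sequences)
  ann
}

#' @rdname read_site_annotations
#' @param annotations Annotation tibble to write.
#' @export
write_site_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

validate_annotations <- function(annotations, sequences = NULL) {
  bad <- setdiff(unique(annotations$label), c("positive", "negative"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown annotation label: ", bad[1]))
  }
  if (!is.null(sequences)) {
    idx <- match(annotations$protein_id, sequences$id)
    if (anyNA(idx)) {
      rlang::abort(paste0(
        "annotation refers to unknown protein: ",
        annotations$protein_id[is.na(idx)][1]
      ))
    }
    len <- sequences$length[idx]
    out <- annotations$position < 1 | annotations$position > len
    if (any(out)) {
      rlang::abort(paste0(
        "annotation position out of range for ",
        annotations$protein_id[out][1]
      ))
    }
    res <- substr(sequences$sequence[idx], annotations$position,
                  annotations$position)
    if (any(res != "K")) {
      i <- which(res != "K")[1]
      rlang::abort(paste0(
        "annotated residue is not lysine: ", annotations$protein_id[i],
        " position ", annotations$position[i], " is ", res[i]
      ))
    }
  }
  invisible(annotations)
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment identity between two amino-acid
#' sequences, scored with match = 1, mismatch = 0, gap = -1 (linear), via
#' [Biostrings::pairwiseAlignment()]. Identity is the number of identical
#' aligned columns divided by the total number of alignment columns
#' (gap columns included).
#'
#' @param a,b Amino-acid sequence strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  letters_all <- c(AA_LETTERS, UNKNOWN)
  sub <- matrix(0, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == pb & pa != GAP) / length(pa)
}

#' Greedy identity clustering of protein sequences
#'
#' A redundancy filter with the same exclusion property as CD-HIT at low
#' thresholds: sequences are sorted longest-first, each sequence joins the
#' first existing representative whose global-alignment identity with it
#' exceeds `identity_threshold`, otherwise it founds a new cluster. Only
#' cluster representatives are returned, so no two retained sequences share
#' an identity above the threshold.
#'
#' @param sequences Tibble with columns `id`, `sequence` (e.g. from
#'   [read_fasta()]).
#' @param identity_threshold Identity fraction in (0, 1\]; default 0.4.
#' @return The rows of `sequences` that are cluster representatives, with an
#'   added `cluster` column, plus a `"members"` attribute mapping each input
#'   id to its representative id.
#' @export
greedy_identity_cluster <- function(sequences, identity_threshold = 0.4) {
  stopifnot(nrow(sequences) >= 1)
  if (identity_threshold <= 0 || identity_threshold > 1) {
    rlang::abort("identity_threshold must be in (0, 1]")
  }
  ord <- order(-nchar(sequences$sequence))
  sorted <- sequences[ord, , drop = FALSE]
  rep_idx <- integer(0)
  assign <- integer(nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    hit <- 0L
    for (j in seq_along(rep_idx)) {
      idy <- pairwise_identity(sorted$sequence[i],
                               sorted$sequence[rep_idx[j]])
      if (idy > identity_threshold) {
        hit <- j
        break
      }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- length(rep_idx)
    } else {
      assign[i] <- hit
    }
  }
  out <- sorted[rep_idx, , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  attr(out, "members") <- stats::setNames(out$id[assign], sorted$id)
  out
}

#' Extract a lysine-centred sequence window
#'
#' Returns the 2n+1 residue window around a central lysine; positions beyond
#' the sequence ends hold the gap sentinel `'-'`.
#'
#' @param sequence Amino-acid sequence string.
#' @param position 1-based index of the central residue (must be `K`).
#' @param n Flank length; the window spans offsets -n..+n.
#' @return Character string of length 2n+1.
#' @export
#' @examples
#' site_window("KAS", 1, 2) # "--KAS"
site_window <- function(sequence, position, n) {
  L <- nchar(sequence)
  if (position < 1 || position > L) {
    rlang::abort("window position out of sequence range")
  }
  if (substr(sequence, position, position) != "K") {
    rlang::abort(
      paste0("central residue at position ", position, " is not lysine"),
      class = "neddly_center_not_lysine"
    )
  }
  offs <- (position - n):(position + n)
  chars <- rep(GAP, length(offs))
  inside <- offs >= 1 & offs <= L
  chars[inside] <- strsplit(substr(sequence, max(1, position - n),
                                   min(L, position + n)), "")[[1]]
  paste(chars, collapse = "")
}

#' Enumerate labeled lysine windows for a sequence set
#'
#' Emits one window per lysine in every sequence. A window is labeled
#' positive iff annotated positive; every other lysine is assumed
#' non-modified and labeled negative.
#'
#' @param sequences Tibble with `id`, `sequence`.
#' @param annotations Tibble with `protein_id`, `position`, `label`; may
#'   cover only a subset of lysines. An annotation at a non-lysine position
#'   is an error.
#' @param n Flank length.
#' @return A tibble with columns `protein_id`, `center`, `label`, `window`
#'   (2n+1-character string), `n`.
#' @export
enumerate_lysine_windows <- function(sequences, annotations = NULL, n = 10) {
  if (!is.null(annotations)) validate_annotations(annotations, sequences)
  rows <- purrr::pmap(
    list(sequences$id, sequences$sequence),
    function(id, seq) {
      ks <- stringr::str_locate_all(seq, "K")[[1]][, 1]
      if (length(ks) == 0) return(NULL)
      tibble::tibble(
        protein_id = id,
        center = as.integer(ks),
        window = vapply(ks, function(p) site_window(seq, p, n), character(1))
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      protein_id = character(), center = integer(),
      label = character(), window = character(), n = integer()
    ))
  }
  pos_key <- character(0)
  if (!is.null(annotations)) {
    pos <- dplyr::filter(annotations, .data$label == "positive")
    pos_key <- paste(pos$protein_id, pos$position)
  }
  out$label <- ifelse(paste(out$protein_id, out$center) %in% pos_key,
                      "positive", "negative")
  out$n <- as.integer(n)
  dplyr::select(out, "protein_id", "center", "label", "window", "n")
}

round_half_up <- function(x) floor(x + 0.5)

#' Partition labeled windows into train / validation / test sets
#'
#' Per class, windows are shuffled with `seed` and divided first into train
#' and holdout sets (default ratio 2:1), then the holdout set into
#' validation and independent test sets (default ratio 1:2). Share sizes use
#' round-half-up on the train and validation fractions, with the remainder
#' going to the later set; applied to 51 positives and 1031 negatives this
#' yields the canonical 34/687 train, 6/115 validation, 11/229 test sizes.
#'
#' @param windows Tibble with a `label` column (from
#'   [enumerate_lysine_windows()]).
#' @param train_fraction Fraction of each class assigned to training.
#' @param validation_fraction Fraction of the holdout assigned to validation.
#' @param seed Integer seed controlling the shuffle.
#' @return `windows` with an added `split` column
#'   (`"train"`/`"validation"`/`"test"`).
#' @export
split_dataset <- function(windows, train_fraction = 2 / 3,
                          validation_fraction = 1 / 3, seed = 1L) {
  stopifnot(nrow(windows) > 0)
  windows$split <- NA_character_
  for (lab in unique(windows$label)) {
    idx <- which(windows$label == lab)
    N <- length(idx)
    if (N < 3) {
      rlang::warn(paste0(
        "class '", lab, "' has fewer than 3 members; split is degenerate"
      ))
    }
    perm <- with_local_seed(seed + match(lab, c("positive", "negative"),
                                         nomatch = 0L),
                            sample.int(N))
    n_train <- round_half_up(N * train_fraction)
    H <- N - n_train
    n_val <- round_half_up(H * validation_fraction)
    assign <- rep("test", N)
    assign[seq_len(n_train)] <- "train"
    if (n_val > 0) assign[n_train + seq_len(n_val)] <- "validation"
    windows$split[idx[perm]] <- assign
  }
  windows
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
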