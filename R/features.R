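## Window featurization. Every feature family operates on a lysine-centred
## 2n+1 window (a character string with '-' marking out-of-sequence
## positions) and returns a named numeric vector; assemble_features()
## concatenates the families in a fixed, documented order.

window_chars <- function(window) strsplit(window, "")[[1]]

window_flank <- function(window) {
  len <- nchar(window)
  if (len %% 2 != 1) rlang::abort("window length must be odd (2n+1)")
  (len - 1L) %/% 2L
}

#' Positional one-hot encoding of a sequence window
#'
#' Each window position is represented by a 20-dimensional indicator over
#' the standard amino acids; gap positions (and unknown residues) are
#' all-zero.
#'
#' @param window A 2n+1 window string (see [site_window()]).
#' @return Named numeric vector of 20*(2n+1) binary features, named
#'   `aa_identity[p][R]` for offset `p` in -n..+n and residue `R`.
#' @export
#' @examples
#' v <- encode_positional_identity("MKS")
#' v[v == 1]
encode_positional_identity <- function(window) {
  n <- window_flank(window)
  chars <- window_chars(window)
  offs <- offset_label(-n:n)
  out <- matrix(0, length(chars), 20)
  hit <- match(chars, AA_LETTERS)
  ok <- !is.na(hit)
  out[cbind(which(ok), hit[ok])] <- 1
  names_out <- paste0("aa_identity[", rep(offs, each = 20), "][",
                      rep(AA_LETTERS, length(chars)), "]")
  stats::setNames(as.vector(t(out)), names_out)
}

#' Positional reduced-alphabet encoding of a sequence window
#'
#' As [encode_positional_identity()] but over the 11 biochemical groups of
#' `grouping`; gap positions are all-zero.
#'
#' @inheritParams encode_positional_identity
#' @param grouping Residue grouping, as [default_grouping()].
#' @return Named numeric vector of `length(grouping)`*(2n+1) binary
#'   features, named `aa_group[p][G]`.
#' @export
encode_positional_groups <- function(window, grouping = default_grouping()) {
  validate_grouping(grouping)
  n <- window_flank(window)
  chars <- window_chars(window)
  offs <- offset_label(-n:n)
  lookup <- grouping_lookup(grouping)
  glabs <- names(grouping)
  out <- matrix(0, length(chars), length(glabs))
  hit <- match(lookup[chars], glabs)
  ok <- !is.na(hit)
  out[cbind(which(ok), hit[ok])] <- 1
  names_out <- paste0("aa_group[", rep(offs, each = length(glabs)), "][",
                      rep(glabs, length(chars)), "]")
  stats::setNames(as.vector(t(out)), names_out)
}

#' Amino-acid and group occurrence counts within a window
#'
#' Counts are taken over the non-gap window symbols; grouped counts include
#' unknown residues through the catch-all group.
#'
#' @inheritParams encode_positional_groups
#' @return Named numeric vector of 20 + `length(grouping)` count features,
#'   named `aa_count[R]` and `group_count[G]`.
#' @export
composition_counts <- function(window, grouping = default_grouping()) {
  validate_grouping(grouping)
  chars <- window_chars(window)
  chars <- chars[chars != GAP]
  aa <- vapply(AA_LETTERS, function(a) sum(chars == a), numeric(1))
  lookup <- grouping_lookup(grouping)
  gl <- lookup[chars]
  grp <- vapply(names(grouping), function(g) sum(gl == g, na.rm = TRUE),
                numeric(1))
  c(
    stats::setNames(aa, paste0("aa_count[", AA_LETTERS, "]")),
    stats::setNames(grp, paste0("group_count[", names(grouping), "]"))
  )
}

#' Window-to-protein occurrence ratio features
#'
#' For each amino acid (and group), the ratio of its frequency within the
#' window (count over non-gap window length) to its frequency in the whole
#' parent protein; 0 when the residue is absent from the protein.
#'
#' @inheritParams encode_positional_groups
#' @param sequence The parent protein sequence string.
#' @return Named numeric vector of 20 + `length(grouping)` features, named
#'   `aa_ratio[R]` and `group_ratio[G]`.
#' @export
composition_ratio <- function(window, sequence,
                              grouping = default_grouping()) {
  validate_grouping(grouping)
  chars <- window_chars(window)
  chars <- chars[chars != GAP]
  prot <- window_chars(sequence)
  wlen <- length(chars)
  L <- length(prot)
  lookup <- grouping_lookup(grouping)
  ratio_of <- function(cw, cp) {
    ifelse(cp > 0, (cw / wlen) / (cp / L), 0)
  }
  aa <- vapply(AA_LETTERS, function(a) {
    ratio_of(sum(chars == a), sum(prot == a))
  }, numeric(1))
  glc <- lookup[chars]
  glp <- lookup[prot]
  grp <- vapply(names(grouping), function(g) {
    ratio_of(sum(glc == g, na.rm = TRUE), sum(glp == g, na.rm = TRUE))
  }, numeric(1))
  c(
    stats::setNames(aa, paste0("aa_ratio[", AA_LETTERS, "]")),
    stats::setNames(grp, paste0("group_ratio[", names(grouping), "]"))
  )
}

#' Evolutionary conservation (PSSM) window features
#'
#' Each window position contributes the 20 position-specific log-odds
#' scores of the corresponding sequence row; gap positions contribute 20
#' zeros.
#'
#' @param profile A PSSM profile tibble (from [parse_pssm_ascii()]) or an
#'   L x 20 numeric matrix with alphabet-ordered columns.
#' @param center 1-based sequence position of the central lysine.
#' @param n Flank length.
#' @return Named numeric vector of 20*(2n+1) features, named `pssm[p][R]`.
#' @export
pssm_window_features <- function(profile, center, n) {
  m <- if (is.matrix(profile)) profile else pssm_matrix(profile)
  L <- nrow(m)
  offs <- -n:n
  rows <- center + offs
  out <- matrix(0, length(offs), 20)
  inside <- rows >= 1 & rows <= L
  out[inside, ] <- m[rows[inside], , drop = FALSE]
  names_out <- paste0("pssm[", rep(offset_label(offs), each = 20), "][",
                      rep(AA_LETTERS, length(offs)), "]")
  stats::setNames(as.vector(t(out)), names_out)
}

# per-residue element bookkeeping for the SS-terminus rule
ss_elements <- function(states) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(starts = rep(starts, r$lengths), ends = rep(ends, r$lengths),
       lengths = rep(r$lengths, r$lengths))
}

#' Secondary-structure features of the central lysine
#'
#' One-hot state of the central residue (helix/strand/coil) plus a binary
#' flag marking whether the residue lies in the termini of its secondary
#' structure element. A residue is in the element termini when its offset
#' from either element end is below `ceiling(0.15 * element_length)`.
#'
#' @param profile An SS profile tibble (from [parse_ss2()]) or a character
#'   vector of per-residue states (`C`/`H`/`E`).
#' @param center 1-based sequence position of the central lysine.
#' @return Named numeric vector `ss_H`, `ss_E`, `ss_C`, `ss_terminus`.
#' @export
ss_features <- function(profile, center) {
  states <- if (is.character(profile)) profile else {
    profile$state[order(profile$position)]
  }
  if (center < 1 || center > length(states)) {
    rlang::abort("center outside secondary structure profile")
  }
  st <- states[center]
  el <- ss_elements(states)
  len <- el$lengths[center]
  off <- min(center - el$starts[center], el$ends[center] - center)
  c(
    ss_H = as.numeric(st == "H"),
    ss_E = as.numeric(st == "E"),
    ss_C = as.numeric(st == "C"),
    ss_terminus = as.numeric(off < ceiling(0.15 * len))
  )
}

#' Binary solvent accessibility of the central lysine
#'
#' @param profile An accessibility profile tibble (from [parse_wesa()]) or
#'   an integer vector of per-residue 0/1 calls.
#' @param center 1-based sequence position of the central lysine.
#' @return Named numeric vector `accessibility` (1 = exposed).
#' @export
solvent_accessibility_feature <- function(profile, center) {
  calls <- if (is.numeric(profile)) profile else {
    profile$exposed[order(profile$position)]
  }
  if (center < 1 || center > length(calls) || is.na(calls[center])) {
    rlang::abort("no accessibility call for the central residue")
  }
  c(accessibility = as.numeric(calls[center]))
}

#' Window flexibility features
#'
#' `window_flexible` is 1 when flexible residues outnumber rigid ones among
#' the non-gap window positions (ties count as rigid). `conf_rat` is the
#' binary confidence-ratio feature: 1 when the summed prediction confidence
#' of flexible residues is at least that of rigid residues. A zero rigid
#' confidence sum yields 1 whenever any flexible residue is present.
#'
#' @param profile A flexibility profile tibble (from [parse_flexpred()]).
#' @param center 1-based sequence position of the central lysine.
#' @param n Flank length.
#' @return Named numeric vector `window_flexible`, `conf_rat`.
#' @export
flexibility_features <- function(profile, center, n) {
  ord <- order(profile$position)
  calls <- profile$call[ord]
  conf <- profile$confidence[ord]
  L <- length(calls)
  rows <- (center - n):(center + n)
  rows <- rows[rows >= 1 & rows <= L]
  if (length(rows) == 0) rlang::abort("window has no residues in profile")
  flex <- calls[rows] == "F"
  sum_f <- sum(conf[rows][flex])
  sum_r <- sum(conf[rows][!flex])
  conf_rat <- if (sum_r == 0) {
    as.numeric(any(flex))
  } else {
    as.numeric(sum_f / sum_r >= 1)
  }
  c(
    window_flexible = as.numeric(sum(flex) > sum(!flex)),
    conf_rat = conf_rat
  )
}

#' Window disorder features
#'
#' Mean per-residue disorder tendency over the non-gap window positions and
#' the binary disorder call (1 when the mean is >= 0.5).
#'
#' @param profile A disorder profile tibble (from [parse_iupred()]).
#' @param center 1-based sequence position of the central lysine.
#' @param n Flank length.
#' @return Named numeric vector `disorder_mean`, `disorder_binary`.
#' @export
disorder_features <- function(profile, center, n) {
  tend <- profile$tendency[order(profile$position)]
  L <- length(tend)
  rows <- (center - n):(center + n)
  rows <- rows[rows >= 1 & rows <= L]
  if (length(rows) == 0) rlang::abort("window has no residues in profile")
  m <- mean(tend[rows])
  c(disorder_mean = m, disorder_binary = as.numeric(m >= 0.5))
}

sub_window_chars <- function(window) {
  n <- window_flank(window)
  chars <- window_chars(window)
  list(
    pre = chars[seq_len(n)],
    center = chars[n + 1L],
    post = chars[n + 1L + seq_len(n)]
  )
}

#' Window hydropathy features
#'
#' Mean Hopp-Woods hydrophilicity of the whole window and of the pre- and
#' post-lysine sub-windows, over non-gap residues (unknown residues score
#' 0); an all-gap sub-window contributes 0.
#'
#' @inheritParams encode_positional_identity
#' @param scale Named per-residue hydropathy values, as
#'   [hopp_woods_scale()].
#' @return Named numeric vector `hydropathy_window`, `hydropathy_pre`,
#'   `hydropathy_post`.
#' @export
hydropathy_features <- function(window, scale = hopp_woods_scale()) {
  sw <- sub_window_chars(window)
  mean_of <- function(chars) {
    chars <- chars[chars != GAP]
    if (length(chars) == 0) return(0)
    vals <- scale[chars]
    vals[is.na(vals)] <- 0
    mean(vals)
  }
  c(
    hydropathy_window = mean_of(c(sw$pre, sw$center, sw$post)),
    hydropathy_pre = mean_of(sw$pre),
    hydropathy_post = mean_of(sw$post)
  )
}

#' Sub-window volume features
#'
#' Summed residue volumes of the pre- and post-lysine sub-windows (gaps and
#' unknown residues contribute 0) and their difference.
#'
#' @inheritParams encode_positional_identity
#' @param volumes Named per-residue volumes, as [kharakoz_volumes()].
#' @return Named numeric vector `volume_pre`, `volume_post`, `volume_diff`
#'   (pre minus post).
#' @export
volume_features <- function(window, volumes = kharakoz_volumes()) {
  sw <- sub_window_chars(window)
  sum_of <- function(chars) {
    vals <- volumes[chars[chars != GAP]]
    sum(vals, na.rm = TRUE)
  }
  pre <- sum_of(sw$pre)
  post <- sum_of(sw$post)
  c(volume_pre = pre, volume_post = post, volume_diff = pre - post)
}

#' Protein-termini features of the central lysine
#'
#' `termini_flag` is 1 when the central lysine lies within the first or last
#' `ceiling(0.10 * L)` residues of the protein. `termini_signed` encodes the
#' protein length with a sign distinguishing the two states: -L at the
#' termini, +L otherwise.
#'
#' @param length Protein length L in residues.
#' @param center 1-based sequence position of the central lysine.
#' @return Named numeric vector `termini_flag`, `termini_signed`.
#' @export
termini_features <- function(length, center) {
  length <- unname(length)
  edge <- ceiling(0.10 * length)
  flag <- center <= edge || center >= length - edge + 1
  c(
    termini_flag = as.numeric(flag),
    termini_signed = if (flag) -length else +length
  )
}

#' Canonical feature name vector
#'
#' The fixed, documented order of the full feature vector for flank length
#' `n`: positional one-hot (20 per position), positional groups, amino-acid
#' and group counts, amino-acid and group ratios, PSSM scores (20 per
#' position), secondary structure (4), solvent accessibility (1),
#' flexibility (2), disorder (2), hydropathy (3), volumes (3), termini (2).
#' For n = 10 this is 1150 features.
#'
#' @param n Flank length.
#' @param grouping Residue grouping.
#' @return Character vector of feature names.
#' @export
feature_names <- function(n = 10, grouping = default_grouping()) {
  offs <- offset_label(-n:n)
  glabs <- names(grouping)
  c(
    paste0("aa_identity[", rep(offs, each = 20), "][",
           rep(AA_LETTERS, length(offs)), "]"),
    paste0("aa_group[", rep(offs, each = length(glabs)), "][",
           rep(glabs, length(offs)), "]"),
    paste0("aa_count[", AA_LETTERS, "]"),
    paste0("group_count[", glabs, "]"),
    paste0("aa_ratio[", AA_LETTERS, "]"),
    paste0("group_ratio[", glabs, "]"),
    paste0("pssm[", rep(offs, each = 20), "][",
           rep(AA_LETTERS, length(offs)), "]"),
    c("ss_H", "ss_E", "ss_C", "ss_terminus"),
    "accessibility",
    c("window_flexible", "conf_rat"),
    c("disorder_mean", "disorder_binary"),
    c("hydropathy_window", "hydropathy_pre", "hydropathy_post"),
    c("volume_pre", "volume_post", "volume_diff"),
    c("termini_flag", "termini_signed")
  )
}

#' Assemble the full feature matrix for a set of labeled windows
#'
#' Computes every feature family for each window and returns the windows
#' tibble with one numeric column per feature, in the fixed order of
#' [feature_names()]. Profile-derived families (PSSM, secondary structure,
#' accessibility, flexibility, disorder) are zero-filled with a warning for
#' proteins whose profile track is absent (set `missing_profiles =
#' "error"` to hard-fail instead).
#'
#' @param windows Window tibble from [enumerate_lysine_windows()] (columns
#'   `protein_id`, `center`, `window`, plus any metadata such as `label` and
#'   `split`, which are carried through).
#' @param sequences Sequence tibble covering all window proteins.
#' @param profiles Profile list as returned by [read_profile_dir()] (or
#'   built in memory); any track may be `NULL`.
#' @param grouping Residue grouping.
#' @param hydropathy,volumes Per-residue scales.
#' @param missing_profiles `"zero"` (default) or `"error"`.
#' @return A tibble: the metadata columns of `windows` followed by the
#'   feature columns.
#' @export
assemble_features <- function(windows, sequences, profiles = NULL,
                              grouping = default_grouping(),
                              hydropathy = hopp_woods_scale(),
                              volumes = kharakoz_volumes(),
                              missing_profiles = c("zero", "error")) {
  missing_profiles <- match.arg(missing_profiles)
  validate_grouping(grouping)
  stopifnot(nrow(windows) > 0)
  n <- window_flank(windows$window[1])
  if (is.null(profiles)) profiles <- list()
  seq_idx <- match(windows$protein_id, sequences$id)
  if (anyNA(seq_idx)) {
    rlang::abort(paste0(
      "window protein absent from sequences: ",
      windows$protein_id[is.na(seq_idx)][1]
    ))
  }

  fnames <- feature_names(n, grouping)
  zeros <- function(names) stats::setNames(rep(0, length(names)), names)
  missing_seen <- character(0)
  get_track <- function(track, pid) {
    tr <- profiles[[track]]
    if (!is.null(tr) && !is.null(tr[[pid]])) return(tr[[pid]])
    if (missing_profiles == "error") {
      rlang::abort(paste0("missing ", track, " profile for ", pid))
    }
    missing_seen <<- union(missing_seen, paste0(track, ":", pid))
    NULL
  }
  # pre-convert PSSM tibbles to matrices once per protein
  pssm_mats <- if (!is.null(profiles$pssm)) {
    lapply(profiles$pssm, pssm_matrix)
  } else {
    NULL
  }

  feats <- matrix(0, nrow(windows), length(fnames),
                  dimnames = list(NULL, fnames))
  for (i in seq_len(nrow(windows))) {
    w <- windows$window[i]
    pid <- windows$protein_id[i]
    center <- windows$center[i]
    seqstr <- sequences$sequence[seq_idx[i]]
    L <- nchar(seqstr)

    pm <- if (!is.null(pssm_mats) && !is.null(pssm_mats[[pid]])) {
      pssm_mats[[pid]]
    } else {
      get_track("pssm", pid)
    }
    ss <- get_track("ss", pid)
    dis <- get_track("disorder", pid)
    flex <- get_track("flexibility", pid)
    acc <- get_track("accessibility", pid)

    v <- c(
      encode_positional_identity(w),
      encode_positional_groups(w, grouping),
      composition_counts(w, grouping),
      composition_ratio(w, seqstr, grouping),
      if (!is.null(pm)) pssm_window_features(pm, center, n) else {
        zeros(paste0("pssm[", rep(offset_label(-n:n), each = 20), "][",
                     rep(AA_LETTERS, 2 * n + 1), "]"))
      },
      if (!is.null(ss)) ss_features(ss, center) else {
        zeros(c("ss_H", "ss_E", "ss_C", "ss_terminus"))
      },
      if (!is.null(acc)) solvent_accessibility_feature(acc, center) else {
        zeros("accessibility")
      },
      if (!is.null(flex)) flexibility_features(flex, center, n) else {
        zeros(c("window_flexible", "conf_rat"))
      },
      if (!is.null(dis)) disorder_features(dis, center, n) else {
        zeros(c("disorder_mean", "disorder_binary"))
      },
      hydropathy_features(w, hydropathy),
      volume_features(w, volumes),
      termini_features(L, center)
    )
    feats[i, ] <- v[fnames]
  }
  if (length(missing_seen) > 0) {
    tracks <- unique(sub(":.*", "", missing_seen))
    rlang::warn(paste0(
      "zero-filled features for missing profile track(s): ",
      paste(tracks, collapse = ", ")
    ))
  }
  if (any(!is.finite(feats))) rlang::abort("non-finite feature value")
  dplyr::bind_cols(windows, tibble::as_tibble(feats))
}

#' Feature column names of an assembled feature tibble
#'
#' @param features Tibble from [assemble_features()].
#' @return Character vector of feature column names (metadata columns
#'   excluded).
#' @export
feature_columns <- function(features) {
  meta <- c("protein_id", "center", "label", "window", "n", "split")
  setdiff(names(features), meta)
}

#' Write / read a feature matrix as TSV with a sidecar name manifest
#'
#' The TSV holds metadata columns followed by feature columns; the sidecar
#' JSON (same path with `.names.json` appended) records the feature column
#' names in order.
#'
#' @param features Tibble from [assemble_features()].
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); the feature tibble (reader).
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path)
  jsonlite::write_json(feature_columns(features),
                       paste0(path, ".names.json"))
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    label = readr::col_character(),
    window = readr::col_character(),
    split = readr::col_character(),
    n = readr::col_integer(),
    .default = readr::col_double()
  ))
  attr(df, "spec") <- NULL
  manifest <- paste0(path, ".names.json")
  if (file.exists(manifest)) {
    expected <- unlist(jsonlite::read_json(manifest))
    if (!identical(feature_columns(df), expected)) {
      rlang::abort("feature matrix columns do not match the name manifest")
    }
  }
  df
}
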