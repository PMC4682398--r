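## Canonical 20-letter amino-acid alphabet; 'X' marks an unknown residue and
## '-' is the out-of-sequence gap sentinel used in windows.
AA_LETTERS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)
GAP <- "-"
UNKNOWN <- "X"

#' Hopp & Woods hydrophilicity scale
#'
#' Per-residue hydrophilicity values (positive = hydrophilic) used for the
#' window-average hydropathy features. Unknown residues ('X') score 0.
#'
#' @return A named numeric vector over the 20 standard amino acids.
#' @references Hopp TP, Woods KR (1981) PNAS 78:3824-3828.
#' @export
#' @examples
#' hopp_woods_scale()[["K"]]
hopp_woods_scale <- function() {
  c(
    A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
    Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8,
    L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
    S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5
  )
}

#' Kharakoz amino-acid residue volumes
#'
#' Partial molar volumes of amino-acid residues in aqueous solution
#' (cm^3/mol), used for the pre-/post-lysine sub-window volume features.
#' Unknown residues ('X') and gaps contribute 0.
#'
#' @return A named numeric vector over the 20 standard amino acids.
#' @references Kharakoz DP (1997) Biochemistry 36:10276-10285.
#' @export
kharakoz_volumes <- function() {
  c(
    A = 60.4, R = 127.3, N = 78.0, D = 70.6, C = 73.4,
    Q = 93.6, E = 85.9, G = 43.2, H = 98.8, I = 107.7,
    L = 107.8, K = 108.5, M = 105.3, F = 121.5, P = 82.8,
    S = 60.6, T = 76.8, W = 143.9, Y = 123.6, V = 90.8
  )
}

#' Reduced-alphabet grouping of amino acids
#'
#' An 11-group partition of the 20 amino acids by shared biochemical
#' properties (aliphatic, aromatic, basic, acidic, amide, hydroxyl, and the
#' single-member groups A, G, C, P plus a catch-all), in the spirit of the
#' Sezerman grouping used for reduced-alphabet window encodings. The grouping
#' is a plain named list so an alternative table can be substituted anywhere
#' a `grouping` argument is accepted.
#'
#' @return A named list mapping group label to a character vector of
#'   single-letter residue codes. Every standard amino acid appears in
#'   exactly one group; 'X' falls in the catch-all group `other`.
#' @export
#' @examples
#' default_grouping()$IVLM
default_grouping <- function() {
  list(
    IVLM = c("I", "V", "L", "M"),
    FYW = c("F", "Y", "W"),
    RKH = c("R", "K", "H"),
    DE = c("D", "E"),
    QN = c("Q", "N"),
    ST = c("S", "T"),
    A = "A",
    G = "G",
    C = "C",
    P = "P",
    other = "X"
  )
}

# residue -> group label lookup (named character vector)
grouping_lookup <- function(grouping = default_grouping()) {
  labs <- rep(names(grouping), lengths(grouping))
  stats::setNames(labs, unlist(grouping, use.names = FALSE))
}

validate_grouping <- function(grouping) {
  members <- unlist(grouping, use.names = FALSE)
  missing <- setdiff(AA_LETTERS, members)
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "grouping must cover all 20 standard amino acids; missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(members)) {
    rlang::abort("grouping maps some residue to more than one group")
  }
  invisible(grouping)
}

# "+1", "-1", "0" labels for window offsets
offset_label <- function(p) {
  ifelse(p > 0, paste0("+", p), as.character(p))
}
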