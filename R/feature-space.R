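# Residue feature embedding: raw per-residue features -> the d = 30 feature map
# consumed by the network. Column layout (fixed):
#   1-20  PSSM, squashed by y = 1/(1 + 2^-x)
#   21    RSA (retained as given)
#   22-24 secondary-structure propensities helix/strand/coil (as given)
#   25-26 phi/psi dihedrals, divided by 360
#   27-28 conservation scores RE, JSD (as given)
#   29    residue type index / 21
#   30    position i/L (1-based)

#' Amino-acid alphabet and residue-type index table
#'
#' The 20 standard one-letter residue codes in alphabetical order receive
#' indices 0--19; the dummy (padding) residue `"X"` receives index 20. The
#' residue-type feature is `index / 21`, so it lies in `[0, 1)`.
#'
#' @return Named integer vector of length 21 mapping residue letters to
#'   indices 0--20.
#' @export
#' @examples
#' aa_alphabet()[["A"]]  # 0
#' aa_alphabet()[["X"]]  # 20 (dummy)
aa_alphabet <- function() {
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  stats::setNames(0:20, c(letters20, "X"))
}

#' @rdname aa_alphabet
#' @export
dummy_residue <- function() "X"

#' Number of feature-space dimensions
#' @return The integer 30.
#' @export
feature_dim <- function() 30L

#' Names of the 30 feature-map columns, in their fixed order
#' @return Character vector of length 30.
#' @export
feature_columns <- function() {
  c(paste0("pssm_", 1:20), "rsa", "ss_h", "ss_e", "ss_c",
    "phi", "psi", "cs_re", "cs_jsd", "rt", "pe")
}

#' Squash raw PSSM log-odds scores into (0, 1)
#'
#' Applies `y = 1 / (1 + 2^-x)` elementwise. The map is strictly increasing
#' and its range is the open interval (0, 1).
#'
#' @param scores Numeric vector or matrix of raw PSSM log-odds.
#' @return Object of the same shape with values in (0, 1).
#' @export
#' @examples
#' normalize_pssm(0)  # 0.5
#' normalize_pssm(1)  # 2/3
normalize_pssm <- function(scores) {
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop("normalize_pssm: scores must be finite numeric values")
  }
  1 / (1 + 2^(-scores))
}

#' Normalize a dihedral angle
#'
#' Divides the angle (degrees) by 360. Negative angles pass through as-is by
#' default (giving negative features); set `wrap = TRUE` to first wrap into
#' `[0, 360)`.
#'
#' @param angle Numeric vector of angles in degrees.
#' @param wrap Wrap angles into `[0, 360)` before dividing? Default `FALSE`.
#' @return `angle / 360` (after optional wrapping).
#' @export
normalize_dihedral <- function(angle, wrap = FALSE) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("normalize_dihedral: angle must be finite numeric")
  }
  if (wrap) angle <- angle %% 360
  angle / 360
}

#' Encode a residue letter as a scalar in [0, 1)
#'
#' Residue types (20 standard + dummy) are numbered 0--20 and divided by 21.
#'
#' @param token Character vector of one-letter residue codes.
#' @param lenient Map unknown letters to the dummy residue instead of
#'   raising an error? Default `FALSE`.
#' @return Numeric vector of `index / 21` values.
#' @export
encode_residue_type <- function(token, lenient = FALSE) {
  tab <- aa_alphabet()
  token <- toupper(token)
  idx <- tab[token]
  if (anyNA(idx)) {
    if (lenient) {
      idx[is.na(idx)] <- tab[[dummy_residue()]]
    } else {
      bad <- unique(token[is.na(idx)])
      stop("encode_residue_type: unknown residue token(s): ",
           paste(bad, collapse = ", "))
    }
  }
  unname(idx) / length(tab)
}

#' Position embeddings for a sequence of length L
#'
#' The i-th residue (1-based) receives `i / L`, so values lie in (0, 1] and
#' the last residue is exactly 1.
#'
#' @param L Sequence length, a positive integer.
#' @return Numeric vector `(1:L) / L`.
#' @export
position_embeddings <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L < 1) {
    stop("position_embeddings: L must be a positive integer")
  }
  L <- as.integer(L)
  seq_len(L) / L
}

#' Conservation scores of a residue column against a background
#'
#' Relative entropy `RE(p||q) = sum p log2(p/q)` and Jensen-Shannon
#' divergence `JSD = RE(p||m)/2 + RE(q||m)/2` with `m = (p+q)/2`. Base-2
#' logarithms, so `JSD <= 1`. This is a convenience for building feature
#' tables; precomputed scores are accepted verbatim by
#' [assemble_feature_map()].
#'
#' @param p,q Probability vectors of equal length (nonnegative, sum 1
#'   within `tol`).
#' @param tol Tolerance on the sum-to-one check.
#' @return Named numeric vector `c(re = ..., jsd = ...)`.
#' @export
conservation_scores <- function(p, q, tol = 1e-6) {
  check_prob <- function(v, nm) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) ||
        abs(sum(v) - 1) > tol) {
      stop("conservation_scores: ", nm, " is not a probability vector")
    }
  }
  check_prob(p, "p"); check_prob(q, "q")
  if (length(p) != length(q)) {
    stop("conservation_scores: p and q must have equal length")
  }
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  m <- (p + q) / 2
  c(re = kl(p, q), jsd = kl(p, m) / 2 + kl(q, m) / 2)
}

#' Assemble the m x 30 feature map for one protein
#'
#' Applies each per-feature normalization: PSSM via [normalize_pssm()],
#' dihedrals via [normalize_dihedral()], residue type via
#' [encode_residue_type()], positions via [position_embeddings()]; RSA,
#' secondary-structure propensities and conservation scores pass through
#' unchanged.
#'
#' @param features Data frame with one row per residue and columns
#'   `pssm_1..pssm_20, rsa, ss_h, ss_e, ss_c, phi, psi, cs_re, cs_jsd`
#'   holding raw (pre-normalization) values.
#' @param residues Character vector of one-letter residue codes, one per row
#'   of `features`.
#' @param wrap_dihedrals Passed to [normalize_dihedral()].
#' @return Numeric matrix `m x 30` with columns [feature_columns()].
#' @export
assemble_feature_map <- function(features, residues, wrap_dihedrals = FALSE) {
  m <- nrow(features)
  if (length(residues) != m) {
    stop("assemble_feature_map: features (", m, " rows) and residues (",
         length(residues), ") disagree in length")
  }
  if (m == 0L) stop("assemble_feature_map: empty protein")
  raw_cols <- c(paste0("pssm_", 1:20), "rsa", "ss_h", "ss_e", "ss_c",
                "phi", "psi", "cs_re", "cs_jsd")
  missing_cols <- setdiff(raw_cols, names(features))
  if (length(missing_cols)) {
    stop("assemble_feature_map: missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ss <- as.matrix(features[, c("ss_h", "ss_e", "ss_c")])
  if (any(ss < 0 | ss > 1)) {
    stop("assemble_feature_map: secondary-structure propensities must lie in [0, 1]")
  }
  out <- cbind(
    normalize_pssm(as.matrix(features[, paste0("pssm_", 1:20)])),
    features$rsa,
    ss,
    normalize_dihedral(features$phi, wrap = wrap_dihedrals),
    normalize_dihedral(features$psi, wrap = wrap_dihedrals),
    features$cs_re,
    features$cs_jsd,
    encode_residue_type(residues),
    position_embeddings(m)
  )
  dimnames(out) <- list(NULL, feature_columns())
  out
}

# Embedded feature row used for dummy (padding) positions: all raw features
# zero (PSSM 0 squashes to 0.5), residue type = dummy, position feature 0.
dummy_feature_row <- function() {
  row <- c(rep(0.5, 20), rep(0, 8),
           aa_alphabet()[[dummy_residue()]] / 21, 0)
  names(row) <- feature_columns()
  row
}

#' Embed a protein record into the network feature space
#'
#' @param protein A list with elements `id`, `sequence` (string), `features`
#'   (raw feature data frame) and optionally `labels`.
#' @param ... Passed to [assemble_feature_map()].
#' @return The protein's `m x 30` feature matrix.
#' @export
embed_protein <- function(protein, ...) {
  residues <- strsplit(protein$sequence, "")[[1]]
  assemble_feature_map(protein$features, residues, ...)
}
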