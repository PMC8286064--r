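#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment under BLOSUM62 (default) with affine
#' gap costs: a gap of length L costs `gap_open + L * gap_extend`
#' (defaults 11 and 1). End gaps are penalized (true global alignment).
#'
#' @param a,b Amino-acid strings (the 20-letter alphabet plus `X`).
#' @param config Configuration list (keys `align.matrix`, `align.gap_open`,
#'   `align.gap_extend`).
#' @return List with `score`, `a_aligned`, `b_aligned` (gap character `-`).
#' @export
pairwise_align <- function(a, b, config = irp_config()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  check_residues(a)
  check_residues(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = config$`align.matrix`,
    gapOpening = config$`align.gap_open`,
    gapExtension = config$`align.gap_extend`,
    type = "global")
  list(score = Biostrings::score(aln),
       a_aligned = as.character(Biostrings::alignedPattern(aln)),
       b_aligned = as.character(Biostrings::alignedSubject(aln)))
}

alignment_columns <- function(a_aligned, b_aligned) {
  ra <- strsplit(a_aligned, "")[[1]]
  rb <- strsplit(b_aligned, "")[[1]]
  if (length(ra) != length(rb)) stop("aligned strings differ in length")
  keep <- ra != "-" & rb != "-" & ra != "X" & rb != "X"
  list(a = ra[keep], b = rb[keep])
}

#' Fraction of identical residues over aligned (non-gap) columns
#'
#' @param a_aligned,b_aligned Gapped strings of equal length.
#' @return Identity in `[0, 1]`.
#' @export
alignment_identity <- function(a_aligned, b_aligned) {
  cols <- alignment_columns(a_aligned, b_aligned)
  if (!length(cols$a)) stop("no aligned columns")
  mean(cols$a == cols$b)
}

#' Evolutionary distance from a pairwise alignment
#'
#' `p` is the mismatch fraction over aligned non-gap columns (columns
#' containing `X` are excluded from scoring); `poisson` is the Poisson
#' correction `-ln(1 - p)`, capped at `dist.cap` (default 5) as `p`
#' approaches 1.
#'
#' @param a_aligned,b_aligned Gapped strings of equal length.
#' @param correction `"p"` or `"poisson"`.
#' @param config Configuration list.
#' @return Non-negative distance.
#' @export
seq_distance <- function(a_aligned, b_aligned,
                         correction = c("poisson", "p"),
                         config = irp_config()) {
  correction <- match.arg(correction)
  cols <- alignment_columns(a_aligned, b_aligned)
  if (!length(cols$a)) stop("no aligned columns")
  p <- mean(cols$a != cols$b)
  if (correction == "p") return(p)
  cap <- config$`dist.cap`
  if (p >= 1 - exp(-cap)) cap else -log(1 - p)
}

#' Pairwise distance matrix over a set of sequences
#'
#' @param seqs Named character vector of sequences.
#' @param correction Distance correction, see [seq_distance()].
#' @param config Configuration list.
#' @return Symmetric matrix with zero diagonal, dimnames = sequence names.
#' @export
distance_matrix <- function(seqs, correction = "poisson",
                            config = irp_config()) {
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- pairwise_align(seqs[[i]], seqs[[j]], config)
      d[i, j] <- d[j, i] <- seq_distance(aln$a_aligned, aln$b_aligned,
                                         correction, config)
    }
  }
  d
}
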