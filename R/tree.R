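#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining: at each step the pair minimizing the
#' Q-criterion is joined, branch lengths follow the standard formulas, and
#' the matrix is reduced with the Studier-Keppler update. Negative branch
#' lengths are clamped to zero. Ties in the Q-criterion are broken towards
#' the lexicographically smallest label pair (each internal node is
#' represented by the smallest leaf label beneath it), which makes the
#' output deterministic.
#'
#' @param d Symmetric numeric matrix with zero diagonal and dimnames giving
#'   the leaf labels; at least 3 leaves.
#' @return Unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must carry labels")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")

  labels <- rownames(d)
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  # each active node: its newick fragment and its representative (smallest
  # leaf label, used for deterministic tie-breaking)
  frags <- labels
  reps <- labels

  fmt <- function(x) format(max(x, 0), digits = 15, scientific = FALSE,
                            trim = TRUE)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(reps[ij[1]], reps[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    new_frag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt(vi), frags[j], fmt(vj))
    new_rep <- min(reps[i], reps[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    labs <- c(rownames(d)[keep], new_rep)
    dimnames(d2) <- list(labs, labs)
    d <- d2
    frags <- c(frags[keep], new_frag)
    reps <- c(reps[keep], new_rep)
  }
  # final unrooted trifurcation
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frags[1], fmt(va), frags[2], fmt(vb), frags[3], fmt(vc))
  ape::read.tree(text = newick)
}

#' Sequence-similarity tree over annotated precursors
#'
#' Builds the distance matrix from pairwise global alignments of the
#' selected region and runs neighbor joining. These are similarity
#' illustrations, not phylogenies: the comparison region defaults to the
#' concatenated B+A core domains, whose cysteine scaffold keeps the
#' alignment meaningful across families, while C/D/E extensions (conserved
#' only between close relatives) are excluded.
#'
#' @param records List of sequence records.
#' @param region `"core"` (concatenated B and A domains) or `"mature"`
#'   (everything after the signal peptide).
#' @param config Configuration list.
#' @return List with `tree` (a `phylo`), `distances` (the matrix) and
#'   `excluded` (ids skipped for want of a cysteine framework).
#' @export
family_tree <- function(records, region = NULL, config = irp_config()) {
  if (is.null(region)) region <- config$`tree.region`
  region <- match.arg(region, c("core", "mature"))
  seqs <- character()
  excluded <- character()
  for (rec in records) {
    fw <- find_core_framework(rec$residues, config)
    if (is.null(fw)) {
      warning("record '", rec$id, "' lacks a cysteine framework; excluded")
      excluded <- c(excluded, rec$id)
      next
    }
    part <- tryCatch({
      signal_pos <- predict_signal_cleavage(rec$residues, config = config)
      sites <- find_cleavage_sites(rec$residues, signal_pos, fw, config)
      ann <- segment_domains(rec$residues, signal_pos, fw, sites, config)
      if (region == "core") {
        bi <- ann$intervals$B
        ai <- ann$intervals$A
        paste0(substr(rec$residues, bi[1] + 1L, bi[2]),
               substr(rec$residues, ai[1] + 1L, ai[2]))
      } else {
        substr(rec$residues, signal_pos + 1L, nchar(rec$residues))
      }
    }, error = function(e) NULL)
    if (is.null(part)) {
      warning("record '", rec$id, "' could not be segmented; excluded")
      excluded <- c(excluded, rec$id)
      next
    }
    seqs[rec$id] <- part
  }
  if (length(seqs) < 3L) stop("need at least 3 annotatable records for a tree")
  d <- distance_matrix(seqs, config$`dist.correction`, config)
  list(tree = neighbor_joining(d), distances = d, excluded = excluded)
}
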