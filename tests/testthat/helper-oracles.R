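# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: exhaustive enumeration and literal bookkeeping, no
# shared code with the package internals.

blosum62_matrix <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# Exhaustive global affine-gap alignment score: enumerates every monotone
# alignment path (match / gap-in-b / gap-in-a), charging a gap of length L
# as open + L * extend. No memoization - feasible only for short sequences.
oracle_align_score <- function(a, b, open = 11, ext = 1,
                               sub = blosum62_matrix) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[ra[i], rb[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= n) {
      best <- max(best, -(ext + if (prev == "A") 0 else open) +
                    rec(i + 1L, j, "A"))
    }
    if (j <= m) {
      best <- max(best, -(ext + if (prev == "B") 0 else open) +
                    rec(i, j + 1L, "B"))
    }
    best
  }
  rec(1L, 1L, "S")
}

# Exhaustive six-cysteine framework search: tries every sextet of cysteine
# positions satisfying the spacing constraints, scores modal spacings, and
# applies the same tie-break order as the contract (score, then most
# C-terminal A motif, then downstream positions).
oracle_framework <- function(seq, config = irp_config()) {
  res <- strsplit(seq, "")[[1]]
  cys <- which(res == "C") - 1L
  if (length(cys) < 6L || nchar(seq) < 40L) return(NULL)
  combos <- utils::combn(cys, 6L)
  best <- NULL; best_key <- NULL
  for (k in seq_len(ncol(combos))) {
    s <- sort(combos[, k])
    cb1 <- s[1]; cb2 <- s[2]; ca1 <- s[3]; ca2 <- s[4]; ca3 <- s[5]; ca4 <- s[6]
    if (ca2 != ca1 + 1L) next
    if (ca3 - ca2 - 1L < config$`framework.a_gap_min` ||
        ca3 - ca2 - 1L > config$`framework.a_gap_max`) next
    if (ca4 - ca3 - 1L < config$`framework.b_gap_min` ||
        ca4 - ca3 - 1L > config$`framework.b_gap_max`) next
    if (cb2 - cb1 < config$`framework.bpair_min` ||
        cb2 - cb1 > config$`framework.bpair_max`) next
    if (ca1 - cb2 < config$`framework.c_span_min` ||
        ca1 - cb2 > config$`framework.c_span_max`) next
    score <- (ca3 - ca2 - 1L == config$`framework.a_gap_modal`) +
      (ca4 - ca3 - 1L == config$`framework.b_gap_modal`) +
      (cb2 - cb1 == config$`framework.bpair_modal`)
    key <- c(score, ca1, ca4, cb2, cb1)
    if (is.null(best_key) || oracle_key_gt(key, best_key)) {
      best_key <- key
      best <- s
    }
  }
  best
}

oracle_key_gt <- function(a, b) {
  for (q in seq_along(a)) {
    if (a[q] > b[q]) return(TRUE)
    if (a[q] < b[q]) return(FALSE)
  }
  FALSE
}

# Literal codon walker: steps nucleotide by nucleotide through the
# concatenated CDS, recording the codon fill level at each exon boundary.
oracle_phases <- function(exon_lens) {
  fill <- 0L
  out <- integer()
  for (k in seq_along(exon_lens)) {
    for (nt in seq_len(exon_lens[k])) fill <- (fill + 1L) %% 3L
    if (k < length(exon_lens)) out <- c(out, fill)
  }
  out
}

# random exon-length partition of a CDS of n_codons codons (plus stop)
random_partition <- function(n_nt, k) {
  cuts <- sort(sample(seq_len(n_nt - 1L), k - 1L))
  diff(c(0L, cuts, n_nt))
}

family_set <- c("IGF", "GSS", "octinsulin", "dilp7", "multinsulin")

# genomic mirror of a gene model (same transcript on the opposite strand)
flip_gene_model <- function(gene, genome_len = 100000L) {
  ex <- gene$cds_exons
  flipped <- cbind(genome_len - ex[, 2], genome_len - ex[, 1])
  irpannot:::new_gene_model(gene$gene_id, gene$seq_region,
                            if (gene$strand == "+") "-" else "+", flipped)
}
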