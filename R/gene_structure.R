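#' Compute intron phases from a gene model
#'
#' For the intron between coding exons i and i+1, `cds_offset` is the number
#' of coding nucleotides upstream of the intron and the phase is
#' `cds_offset mod 3` (phase 0: between codons; 1: after the first
#' nucleotide; 2: after the second).
#'
#' @param gene A `gene_model` with a complete CDS (length divisible by 3).
#' @return Data frame with columns `index`, `cds_offset`, `phase`, `aa_pos`
#'   (`cds_offset %/% 3`) and `domain_tag` (`NA` until mapped); zero rows
#'   for a single-exon gene.
#' @export
compute_intron_phases <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  if (!gene$complete) {
    stop("incomplete CDS (length ", gene$cds_length, " not divisible by 3)")
  }
  k <- nrow(gene$cds_exons)
  if (k < 2L) {
    return(data.frame(index = integer(), cds_offset = integer(),
                      phase = integer(), aa_pos = integer(),
                      domain_tag = character(), stringsAsFactors = FALSE))
  }
  lens <- gene$cds_exons[, 2] - gene$cds_exons[, 1]
  offsets <- cumsum(lens)[-k]
  data.frame(index = seq_len(k - 1L),
             cds_offset = as.integer(offsets),
             phase = as.integer(offsets %% 3L),
             aa_pos = as.integer(offsets %/% 3L),
             domain_tag = NA_character_,
             stringsAsFactors = FALSE)
}

#' Map introns onto precursor domains
#'
#' Fills the `domain_tag` of each intron record with the domain containing
#' its amino-acid position (an intron interrupting a codon maps to that
#' codon's residue). The protein annotation must correspond to the gene's
#' CDS: `CDS/3 - 1` (with stop codon) or `CDS/3` (without) must equal the
#' protein length.
#'
#' @param introns Data frame from [compute_intron_phases()].
#' @param annotation A `domain_annotation` for the encoded precursor.
#' @param gene The `gene_model` (for the CDS-length consistency check).
#' @param protein_length Length of the annotated protein.
#' @return The intron data frame with `domain_tag` filled.
#' @export
map_introns_to_domains <- function(introns, annotation, gene, protein_length) {
  n_aa <- gene$cds_length %/% 3L
  if (!(protein_length %in% c(n_aa, n_aa - 1L))) {
    stop("CDS encodes ", n_aa, " residues (incl. any stop) but protein has ",
         protein_length, " residues")
  }
  if (nrow(introns) == 0L) return(introns)
  introns$domain_tag <- vapply(introns$aa_pos, function(aa) {
    tag <- domain_of_position(annotation, min(aa, protein_length - 1L))
    if (is.na(tag)) "none" else tag
  }, "")
  introns
}

#' Family gene-structure signature from intron phases
#'
#' The diagnostic rules: every irp gene carries a phase-1 intron in its
#' conceptual C domain (required for any call); a phase-2 intron on top of
#' it indicates a dilp7 ortholog; a phase-2 intron plus a second phase-1
#' intron indicates a multinsulin; a phase-0 intron in the last quarter of
#' the CDS indicates IGF; only the C-domain phase-1 intron is compatible
#' with both GSS and octinsulin, which share their gene structure.
#'
#' @param introns Domain-mapped intron data frame (from
#'   [map_introns_to_domains()]).
#' @param cds_length Total CDS length in nucleotides.
#' @param config Configuration list (key `genes.igf_tail_frac`).
#' @return List with `token` in `{IGF, GSS_or_octinsulin, dilp7,
#'   multinsulin, unknown}` and `matched_rules`.
#' @export
gene_signature <- function(introns, cds_length, config = irp_config()) {
  unknown <- list(token = "unknown", matched_rules = character())
  if (nrow(introns) == 0L) return(unknown)
  if (anyNA(introns$domain_tag)) {
    stop("introns must be domain-mapped before computing a signature")
  }
  p1_in_c <- any(introns$phase == 1L & introns$domain_tag == "C")
  if (!p1_in_c) return(unknown)
  rules <- "phase1-in-C"
  has_p2 <- any(introns$phase == 2L)
  extra_p1 <- sum(introns$phase == 1L) >= 2L
  tail_start <- (1 - config$`genes.igf_tail_frac`) * cds_length
  p0_late <- any(introns$phase == 0L & introns$cds_offset >= tail_start)
  if (has_p2 && extra_p1) {
    list(token = "multinsulin",
         matched_rules = c(rules, "phase2", "second-phase1"))
  } else if (has_p2) {
    list(token = "dilp7", matched_rules = c(rules, "phase2"))
  } else if (p0_late) {
    list(token = "IGF", matched_rules = c(rules, "phase0-near-end"))
  } else {
    list(token = "GSS_or_octinsulin", matched_rules = rules)
  }
}
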