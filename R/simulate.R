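IRP_FAMILIES <- c("IGF", "GSS", "octinsulin", "dilp7", "multinsulin")

# Family templates. All B cores are 26-mers with CB1/CB2 at relative
# positions 8/20 (the classical 12-residue B spacing, 8 B residues upstream
# of CB1); A cores carry CA1/CA2 adjacent with the modal 3/8 spacings.
# C domains embed a decoy dibasic site (KRW: bulky P1', must be rejected).
# IGF/GSS share a B/A base and dilp7/multinsulin share another, so that
# similarity trees reproduce the expected family neighborhoods.
IRP_SIGNAL <- "MKLIVLLFLVILSLA"

IRP_TEMPLATES <- list(
  GSS = list(
    B = "EVNQHLQGCGSHLVEALYLVCGERGF",
    C = "SAGNDQKRWHALGAGHNTELSG",
    A = "GIVEQCCTDICSVYDLENYCN"),
  octinsulin = list(
    B = "QECQHLAGCGSHLVEALYLVCGERGF",
    C = "SAGNDQKRWQSLGSGHNTELAG",
    A = "GIVEQCCTSICSLYQLENYCN",
    post = "GCNQ"),
  dilp7 = list(
    F = "EVRDLLNQLDAYDLVMDHNNFGQPL",
    B = "DSLRNLAECGRELVDTLKFICSNRAM",
    C = "TDGNELKRWSGTEAHNTDLAGQ",
    A = "GVDRECCLKGCTMDELLRYCA"),
  multinsulin = list(
    B = "DTLRNIAECGRDLVDSLKFICSNRGM",
    C = "SDGNELKRWCGTECHNTDLAGQ",
    A = "GVDKECCLRGCTMEELIRYCA"),
  IGF = list(
    B = "EVDQHLQGCGAHLVDALYLVCGDRGF",
    C = "SAGNDQESLGAG",
    A = "GIVDECCFRSCDLRLLETYC",
    D = "DEQHNELDATFKDNEATNSHDKSAR",
    E = "NEDSEQKDETNEQLDKESNDALHEKDQESTNKDLEHQDSA")
)

# assemble a template: sequence, protected positions (0-based) and planted
# landmarks (KR site P1 positions, decoy P1 positions, extra cysteines)
build_template <- function(family) {
  tpl <- IRP_TEMPLATES[[family]]
  if (is.null(tpl)) stop("unknown family: ", family)
  two_chain <- family %in% c("GSS", "octinsulin", "dilp7", "multinsulin")
  parts <- c(signal = IRP_SIGNAL)
  if (!is.null(tpl$F)) parts <- c(parts, F = tpl$F)
  parts <- c(parts, B = tpl$B)
  if (two_chain) parts <- c(parts, kr1 = "KR")
  parts <- c(parts, C = tpl$C)
  if (two_chain) parts <- c(parts, kr2 = "KR")
  parts <- c(parts, A = tpl$A)
  for (tag in c("post", "D", "E")) {
    if (!is.null(tpl[[tag]])) parts <- c(parts, stats::setNames(tpl[[tag]], tag))
  }
  seq <- paste(parts, collapse = "")
  offsets <- cumsum(c(0L, nchar(parts)))[seq_along(parts)]
  names(offsets) <- names(parts)
  res <- strsplit(seq, "")[[1]]

  protected <- integer()
  kr_p1 <- integer()
  for (tag in c("kr1", "kr2")) {
    if (tag %in% names(offsets)) {
      p1 <- offsets[[tag]] + 1L
      kr_p1 <- c(kr_p1, p1)
      protected <- c(protected, (p1 - 3L):(p1 + 1L))  # P4..P1'
    }
  }
  decoy_p1 <- integer()
  decoy_rel <- regexpr("KRW", parts[["C"]], fixed = TRUE)
  if (decoy_rel > 0L) {
    p1 <- offsets[["C"]] + as.integer(decoy_rel)       # 0-based R of KRW
    decoy_p1 <- p1
    protected <- c(protected, (p1 - 1L):(p1 + 1L))
  }
  furin_p1 <- integer()
  if (family == "IGF") {
    p1 <- offsets[["D"]] + nchar(tpl$D) - 1L           # R of the KSAR motif
    furin_p1 <- p1
    protected <- c(protected, (p1 - 3L):(p1 + 1L))
  }
  cys <- which(res == "C") - 1L
  protected <- sort(unique(c(protected, cys)))         # all cysteines fixed
  list(family = family, seq = seq, parts = parts, offsets = offsets,
       protected = protected, kr_p1 = kr_p1, decoy_p1 = decoy_p1,
       furin_p1 = furin_p1, signal_len = nchar(IRP_SIGNAL))
}

sim_seed <- function(seed, tag) {
  offsets <- c(IGF = 1L, GSS = 2L, octinsulin = 3L, dilp7 = 4L,
               multinsulin = 5L, gene = 6L, synteny = 7L, receptor = 8L)
  off <- if (tag %in% names(offsets)) offsets[[tag]] else 9L
  (abs(as.integer(seed)) %% 200000000L) * 10L + off
}

#' Generate a synthetic irp precursor
#'
#' Instantiates the family template (signal peptide, cysteine framework,
#' planted convertase sites with clean contexts, one decoy dibasic site with
#' a bulky P1', family-specific F domains, charged tails and extra
#' cysteines), then substitutes each mutation-eligible position with
#' probability `noise_rate` by a residue drawn uniformly from the 19
#' alternatives. Cysteines, planted cleavage motifs and their exclusion
#' contexts are never mutated: noise probes the robustness of thresholds,
#' not the destruction of the defining marks. For a fixed seed the mutated
#' position sets are nested across increasing noise rates.
#'
#' @param family One of `IGF`, `GSS`, `octinsulin`, `dilp7`, `multinsulin`.
#' @param seed Integer seed.
#' @param noise_rate Per-eligible-position substitution probability in
#'   `[0, 0.2]`.
#' @param id Optional record id (default `family_s<seed>`).
#' @return A sequence record with attribute `template` (the construction
#'   bookkeeping).
#' @export
make_precursor <- function(family, seed, noise_rate = 0, id = NULL) {
  if (!family %in% IRP_FAMILIES) stop("unknown family: ", family)
  if (noise_rate < 0 || noise_rate > 0.2) stop("noise_rate must be in [0, 0.2]")
  tpl <- build_template(family)
  res <- strsplit(tpl$seq, "")[[1]]
  n <- length(res)
  set.seed(sim_seed(seed, family))
  u <- stats::runif(n)
  alt_idx <- sample.int(19L, n, replace = TRUE)
  eligible <- setdiff(seq_len(n) - 1L, tpl$protected)
  mutate <- intersect(which(u < noise_rate) - 1L, eligible)
  for (i in mutate) {
    alternatives <- setdiff(AA_ALPHABET, res[i + 1L])
    res[i + 1L] <- alternatives[alt_idx[i + 1L]]
  }
  if (is.null(id)) id <- sprintf("%s_s%d", family, as.integer(seed))
  rec <- new_seq_record(id, paste(res, collapse = ""),
                        description = sprintf("synthetic %s precursor", family))
  attr(rec, "template") <- tpl
  rec
}

CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

reverse_translate <- function(protein) {
  paste0(paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

# family intron plans: amino-acid anchor and phase for each intron,
# expressed relative to template part boundaries
intron_plan <- function(tpl) {
  off <- tpl$offsets
  fam <- tpl$family
  c_aa <- off[["C"]] + 7L   # inside the C domain, past the decoy motif
  plan <- switch(fam,
    GSS = list(c(aa = c_aa, phase = 1L)),
    octinsulin = list(c(aa = c_aa, phase = 1L)),
    IGF = {
      n_aa <- nchar(tpl$seq)
      late_aa <- off[["E"]] + 12L
      stopifnot(3L * late_aa >= 0.75 * (3L * n_aa + 3L))
      list(c(aa = c_aa, phase = 1L), c(aa = late_aa, phase = 0L))
    },
    dilp7 = list(c(aa = off[["B"]], phase = 2L), c(aa = c_aa, phase = 1L)),
    multinsulin = list(c(aa = off[["B"]] + 1L, phase = 2L),
                       c(aa = off[["B"]] + 5L, phase = 1L),
                       c(aa = c_aa, phase = 1L)))
  plan
}

#' Generate a synthetic irp gene model with its precursor
#'
#' Emits a CDS (with stop codon) translating exactly to the noise-free
#' family precursor, split into coding exons so that the family's
#' diagnostic intron signature holds: all families carry the phase-1 intron
#' in the C domain; dilp7 orthologs add a phase-2 intron near the F/B
#' boundary (3 coding exons); multinsulins add both the phase-2 intron and
#' a second phase-1 intron in B (4 coding exons); IGF adds a phase-0 intron
#' in the last quarter of the CDS (3 coding exons); GSS and octinsulin keep
#' the C-domain intron as their only one (2 coding exons).
#'
#' @param family Family name.
#' @param seed Integer seed (drives intron lengths and gene start).
#' @return List with `gene` (a `gene_model`), `record` (the matching
#'   noise-free precursor) and `cds` (nucleotide string, including stop).
#' @export
make_gene_model <- function(family, seed) {
  rec <- make_precursor(family, seed, noise_rate = 0)
  tpl <- attr(rec, "template")
  cds <- reverse_translate(rec$residues)
  plan <- intron_plan(tpl)
  offsets <- vapply(plan, function(p) 3L * p[["aa"]] + p[["phase"]], 0L)
  stopifnot(!is.unsorted(offsets, strictly = TRUE),
            all(offsets > 0L), all(offsets < nchar(cds)))
  set.seed(sim_seed(seed, "gene"))
  gene_start <- sample(1000:5000, 1L)
  intron_lens <- sample(200:800, length(offsets), replace = TRUE)
  bounds <- c(0L, offsets, nchar(cds))
  exon_lens <- diff(bounds)
  exons <- matrix(0L, length(exon_lens), 2L)
  cur <- gene_start
  for (i in seq_along(exon_lens)) {
    exons[i, ] <- c(cur, cur + exon_lens[i])
    cur <- cur + exon_lens[i] + if (i < length(exon_lens)) intron_lens[i] else 0L
  }
  gene <- new_gene_model(rec$id, "chrSim", "+", exons)
  list(gene = gene, record = rec, cds = cds)
}

#' Generate a synthetic synteny layout
#'
#' `echinozoa_clustered`: one chromosome carrying octinsulin, IGF, IGF and
#' dilp7 loci next to one another (IGF between octinsulin and dilp7, gaps
#' drawn between 20 and 50 kb) with the GSS locus 6,000,000 bp further
#' downstream. `asterozoa_scattered`: the same five family labels, each on
#' its own scaffold (synteny lost).
#'
#' @param kind `"echinozoa_clustered"` or `"asterozoa_scattered"`.
#' @param seed Integer seed.
#' @return Locus data frame (0-based half-open coordinates) as from
#'   [read_locus_table()].
#' @export
make_synteny_layout <- function(kind = c("echinozoa_clustered",
                                         "asterozoa_scattered"), seed) {
  kind <- match.arg(kind)
  set.seed(sim_seed(seed, "synteny"))
  families <- c("octinsulin", "IGF", "IGF", "dilp7", "GSS")
  ids <- c("oct1", "igf1", "igf2", "dilp7_1", "gss1")
  lens <- sample(5000:15000, 5L, replace = TRUE)
  strands <- sample(c("+", "-"), 5L, replace = TRUE)
  if (kind == "echinozoa_clustered") {
    gaps <- c(sample(20000:50000, 3L, replace = TRUE), 6000000L)
    start <- 100000L
    rows <- list()
    for (i in 1:5) {
      rows[[i]] <- data.frame(gene_id = ids[i], family_label = families[i],
                              seq_region = "chr1", start = start,
                              end = start + lens[i], strand = strands[i],
                              stringsAsFactors = FALSE)
      if (i < 5L) start <- start + lens[i] + gaps[i]
    }
    out <- do.call(rbind, rows)
  } else {
    starts <- sample(100000:1000000, 5L, replace = TRUE)
    out <- data.frame(gene_id = ids, family_label = families,
                      seq_region = paste0("scaf", 1:5), start = starts,
                      end = starts + lens, strand = strands,
                      stringsAsFactors = FALSE)
  }
  out[order(out$seq_region, out$start), , drop = FALSE]
}

REC_LDLA_UNIT <- "CAECSGKCPLTWCADCGSDEEC"
REC_LDLA_SPACER <- "TNDDSDELGSPT"
REC_LRR_UNIT <- "LKALDLSNNQLTSIPEGAFDKE"
REC_TM_UNIT <- "LVILFAVLIVLFLILVVLILF"
REC_LOOP <- "STGPDEKQHTSGPDE"

#' Generate a synthetic LGR-type receptor
#'
#' `GRL101` preset: twelve LDLa repeats, six leucine-rich repeats and seven
#' transmembrane helices in N-to-C order LDLa, LRR, 7-TM; `single_LDLa_LGR`
#' preset: one LDLa repeat, four LRRs and seven transmembrane helices (the
#' dilp7/gonadulin receptor architecture).
#'
#' @param preset `"GRL101"` or `"single_LDLa_LGR"`.
#' @param seed Integer seed (accepted for interface symmetry; the presets
#'   are fixed sequences).
#' @return A sequence record.
#' @export
make_receptor <- function(preset = c("GRL101", "single_LDLa_LGR"), seed = 1L) {
  preset <- match.arg(preset)
  n_ldla <- if (preset == "GRL101") 12L else 1L
  n_lrr <- if (preset == "GRL101") 6L else 4L
  seq <- paste0(
    "MQTEG",
    strrep(paste0(REC_LDLA_UNIT, REC_LDLA_SPACER), n_ldla),
    strrep(REC_LRR_UNIT, n_lrr),
    "GSTQHDKESTGQPD",
    paste(rep(REC_TM_UNIT, 7L), collapse = REC_LOOP),
    "HQSTDEGK")
  new_seq_record(sprintf("%s_s%d", preset, as.integer(seed)), seq,
                 description = sprintf("synthetic %s receptor", preset))
}

#' Generate a batch of precursors across families
#'
#' @param n_per_family Replicates per family.
#' @param seed Base seed; replicate `i` of each family uses `seed * 1000 + i`.
#' @param noise_rate Substitution probability, see [make_precursor()].
#' @param families Families to include.
#' @return List of sequence records with unique ids `family_r<i>`.
#' @export
make_precursor_batch <- function(n_per_family, seed, noise_rate = 0,
                                 families = IRP_FAMILIES) {
  out <- list()
  for (fam in families) {
    for (i in seq_len(n_per_family)) {
      rec <- make_precursor(fam, seed * 1000L + i, noise_rate,
                            id = sprintf("%s_r%d", fam, i))
      out[[rec$id]] <- rec
    }
  }
  out
}
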