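new_cleavage_site <- function(pos, kind, motif, verdict, reasons = character()) {
  data.frame(pos = pos, kind = kind, motif = motif, verdict = verdict,
             reasons = paste(reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(pos = integer(), kind = character(), motif = character(),
             verdict = character(), reasons = character(),
             stringsAsFactors = FALSE)
}

# residue window P6..P2' around a P1 index (0-based), '-' beyond the ends
motif_window <- function(res, p1) {
  idx <- (p1 - 5L):(p1 + 2L)
  chars <- ifelse(idx >= 0L & idx < length(res), res[pmax(idx, 0L) + 1L], "-")
  paste(chars, collapse = "")
}

#' Predict the signal-peptide cleavage position
#'
#' A deliberately transparent heuristic standing in for a full
#' signal-peptide predictor: candidate cleavage positions `p` (the mature
#' peptide starts at 0-based index `p`) in a configurable range are scored
#' with the classical (-3,-1) small-residue rule (one point each when the
#' residues one and three positions before the cleavage are in
#' \{A,G,S,C,T\}) plus the mean Kyte-Doolittle hydropathy of the h-region
#' window (residues `p-13..p-6`) whenever that mean is at least 1.5. The
#' highest-scoring position wins, ties going to the smallest `p`. A
#' user-supplied position always wins.
#'
#' @param seq Amino-acid string (precursor with signal peptide).
#' @param override Optional known cleavage position (0-based index of the
#'   first mature residue); returned as-is when given.
#' @param config Configuration list.
#' @return Integer cleavage position.
#' @export
predict_signal_cleavage <- function(seq, override = NULL,
                                    config = irp_config()) {
  if (!is.null(override)) return(as.integer(override))
  n <- nchar(seq)
  if (n < 25L) stop("sequence too short for signal-peptide prediction")
  res <- strsplit(seq, "")[[1]]
  prof <- hydropathy_profile(seq)
  small <- c("A", "G", "S", "C", "T")
  p_range <- config$`cleavage.signal_min`:min(config$`cleavage.signal_max`, n - 1L)
  scores <- vapply(p_range, function(p) {
    s <- (res[p] %in% small) + (res[p - 2L] %in% small)  # 0-based p-1, p-3
    h <- window_hydropathy(prof, p - config$`cleavage.h_window_start`,
                           p - config$`cleavage.h_window_end` + 1L)
    if (!is.na(h) && h >= config$`cleavage.h_threshold`) s <- s + h
    as.numeric(s)
  }, 0)
  if (all(scores <= 0)) stop("no signal peptide detected")
  p_range[which.max(scores)]
}

#' Find furin cleavage sites
#'
#' The strong tier is the furin consensus `[KR]-X-[KR]-R` over P4..P1; the
#' relaxed tier `[KR]-X-X-R` covers sites such as the human IGF processing
#' motifs KSAR and KSER, which satisfy the minimal P4/P1 requirement but not
#' the P2 basic residue. A proline immediately after the cleavage (P1')
#' rejects the site.
#'
#' @param seq Amino-acid string.
#' @param start 0-based index where the mature region starts (end of signal
#'   peptide); positions before it are not scanned.
#' @param config Configuration list.
#' @return Data frame of cleavage sites (columns `pos` = 0-based P1 index,
#'   `kind`, `motif`, `verdict`, `reasons`).
#' @export
find_furin_sites <- function(seq, start = 0L, config = irp_config()) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  out <- empty_sites()
  basic <- c("K", "R")
  for (p1 in seq.int(start + 3L, n - 1L)) {      # 0-based; need P4 in mature
    i <- p1 + 1L                                  # 1-based index of P1
    if (res[i] != "R") next
    p4 <- res[i - 3L]; p2 <- res[i - 1L]
    if (!(p4 %in% basic)) next
    kind <- if (p2 %in% basic) "furin_strong" else "furin_weak"
    reasons <- character()
    if (i < n && res[i + 1L] == "P") reasons <- c(reasons, "P1'-proline")
    out <- rbind(out, new_cleavage_site(
      p1, kind, motif_window(res, p1),
      if (length(reasons)) "rejected" else "accepted", reasons))
  }
  out
}

#' Find neuroendocrine convertase (dibasic) cleavage sites
#'
#' Candidate motifs at P2-P1 are KR (on by default) and optionally RR, KK,
#' RK, plus optional monobasic R. Each candidate is accepted unless a
#' contextual exclusion fires: a bulky residue (default \{W,F,Y,I,L,V\}) or a
#' proline at P1', a proline at P3 or P4, or a core-framework cysteine within
#' `cleavage.disulfide_window` residues of P1 (steric hindrance by a nearby
#' disulfide bridge).
#'
#' @param seq Amino-acid string.
#' @param start 0-based start of the mature region.
#' @param framework Optional `cys_framework` (enables the
#'   disulfide-proximity exclusion).
#' @param config Configuration list.
#' @return Data frame of cleavage sites.
#' @export
find_dibasic_sites <- function(seq, start = 0L, framework = NULL,
                               config = irp_config()) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  motifs <- c(if (config$`cleavage.dibasic_kr`) "KR",
              if (config$`cleavage.dibasic_rr`) "RR",
              if (config$`cleavage.dibasic_kk`) "KK",
              if (config$`cleavage.dibasic_rk`) "RK")
  bulky <- strsplit(config$`cleavage.bulky`, "")[[1]]
  pre_pro <- as.integer(strsplit(config$`cleavage.pre_proline_positions`, ",")[[1]])
  w <- config$`cleavage.disulfide_window`
  core <- if (!is.null(framework)) framework$core else integer()

  out <- empty_sites()
  scan_one <- function(p1, kind) {
    i <- p1 + 1L
    reasons <- character()
    if (i < n) {
      if (res[i + 1L] %in% bulky) reasons <- c(reasons, "bulky-P1'")
      if (res[i + 1L] == "P") reasons <- c(reasons, "P1'-proline")
    }
    for (k in pre_pro) {
      if (i - k >= 1L && res[i - k + 1L] == "P") {
        reasons <- c(reasons, "pre-site-proline")
        break
      }
    }
    if (length(core) && any(abs(core - p1) <= w)) {
      reasons <- c(reasons, "disulfide-proximity")
    }
    new_cleavage_site(p1, kind, motif_window(res, p1),
                      if (length(reasons)) "rejected" else "accepted", reasons)
  }
  for (p1 in seq.int(start + 1L, n - 1L)) {
    pair <- paste0(res[p1], res[p1 + 1L])    # P2-P1, 0-based p1
    if (pair %in% motifs) out <- rbind(out, scan_one(p1, "dibasic"))
  }
  if (config$`cleavage.monobasic_r`) {
    for (p1 in seq.int(start, n - 1L)) {
      if (res[p1 + 1L] == "R") {
        pair <- if (p1 >= 1L) paste0(res[p1], res[p1 + 1L]) else ""
        if (!pair %in% motifs) out <- rbind(out, scan_one(p1, "monobasic"))
      }
    }
  }
  if (nrow(out)) out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict all convertase cleavage sites of a precursor
#'
#' Convenience wrapper running [find_furin_sites()] and
#' [find_dibasic_sites()] downstream of the signal peptide.
#'
#' @inheritParams find_dibasic_sites
#' @param signal_pos 0-based end of the signal peptide.
#' @return Data frame of cleavage sites sorted by position.
#' @export
find_cleavage_sites <- function(seq, signal_pos, framework = NULL,
                                config = irp_config()) {
  out <- rbind(find_furin_sites(seq, signal_pos, config),
               find_dibasic_sites(seq, signal_pos, framework, config))
  if (nrow(out)) out <- out[order(out$pos, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}
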