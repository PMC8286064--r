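#' Segment a precursor into signal/F/B/C/A/D/E domains
#'
#' Implements the insulin-superfamily precursor domain scheme: the B and A
#' domains are anchored on the cysteine framework, the C domain is the
#' connecting peptide between them, a long N-terminal extension of the B
#' chain is called the F domain, and C-terminal extensions split into D
#' (before the first accepted furin site) and E (after it).
#'
#' Rules: B starts at the maximum of the signal end, the boundary after the
#' nearest accepted cleavage site upstream of CB1, and `CB1 - b_lead`; the
#' pre-B region becomes an F domain when at least `f_min` residues long,
#' otherwise it is merged into B. C runs between the accepted sites flanking
#' it when both exist (two-chain mode) or simply from CB2 to CA1 (single
#' chain). A runs from CA1 through CA4; a short post-CA4 stub (< `d_min`)
#' is merged into A, a longer one opens D up to the first accepted furin
#' site and E after it (no furin site: the whole extension is D).
#'
#' @param seq Amino-acid string.
#' @param signal_pos 0-based end of the signal peptide.
#' @param framework A `cys_framework`; an error when `NULL`.
#' @param sites Data frame of cleavage sites from [find_cleavage_sites()].
#' @param config Configuration list.
#' @return A `domain_annotation`: list with `intervals` (named list of
#'   0-based half-open intervals for tags among signal/F/B/C/A/D/E) and
#'   `chain_mode` (`"single_chain"` or `"two_chain"`).
#' @export
segment_domains <- function(seq, signal_pos, framework, sites,
                            config = irp_config()) {
  if (is.null(framework)) stop("cannot segment: no cysteine framework")
  n <- nchar(seq)
  acc <- sites[sites$verdict == "accepted", , drop = FALSE]
  acc_conv <- acc[acc$kind %in% c("dibasic", "monobasic", "furin_strong",
                                  "furin_weak"), , drop = FALSE]
  iv <- list()
  if (signal_pos > 0L) iv$signal <- c(0L, signal_pos)

  up <- acc_conv$pos[acc_conv$pos < framework$cb1]
  b_start <- max(signal_pos,
                 if (length(up)) max(up) + 1L else -Inf,
                 framework$cb1 - config$`domains.b_lead`)
  b_start <- as.integer(b_start)
  if (b_start > framework$cb1) {
    stop("cannot segment: predicted signal peptide or cleavage boundary ",
         "overlaps the B-chain cysteines")
  }
  if (b_start - signal_pos >= config$`domains.f_min`) {
    iv$F <- c(signal_pos, b_start)
  } else {
    b_start <- signal_pos
  }

  # accepted sites flanking the C domain: one near its start (after CB2)
  # and a distinct one near its end (before CA1)
  within_c <- acc_conv$pos[acc_conv$pos > framework$cb2 &
                             acc_conv$pos < framework$ca1]
  s1 <- if (length(within_c)) min(within_c) else NA_integer_
  s2 <- if (length(within_c)) max(within_c) else NA_integer_
  two_chain <- !is.na(s1) && !is.na(s2) && s1 < s2
  if (two_chain) {
    iv$B <- c(b_start, s1 + 1L)
    iv$C <- c(s1 + 1L, framework$ca1)
  } else {
    iv$B <- c(b_start, framework$cb2 + 1L)
    iv$C <- c(framework$cb2 + 1L, framework$ca1)
  }

  a_end <- framework$ca4 + 1L
  trailing <- n - a_end
  if (trailing > 0L && trailing < config$`domains.d_min`) {
    a_end <- n
    trailing <- 0L
  }
  iv$A <- c(framework$ca1, a_end)
  if (trailing > 0L) {
    furin_after <- acc$pos[acc$kind %in% c("furin_strong", "furin_weak") &
                             acc$pos >= a_end]
    if (length(furin_after)) {
      f1 <- min(furin_after) + 1L
      iv$D <- c(a_end, f1)
      if (f1 < n) iv$E <- c(f1, n)
    } else {
      iv$D <- c(a_end, n)
    }
  }
  structure(list(intervals = iv,
                 chain_mode = if (two_chain) "two_chain" else "single_chain"),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  parts <- vapply(names(x$intervals), function(tag) {
    sprintf("%s[%d,%d)", tag, x$intervals[[tag]][1], x$intervals[[tag]][2])
  }, "")
  cat("<domain_annotation ", paste(parts, collapse = " "), " ",
      x$chain_mode, ">\n", sep = "")
  invisible(x)
}

domain_of_position <- function(annotation, pos) {
  for (tag in names(annotation$intervals)) {
    ivl <- annotation$intervals[[tag]]
    if (pos >= ivl[1] && pos < ivl[2]) return(tag)
  }
  NA_character_
}

#' C-terminal tail features
#'
#' The tail is the concatenation of the D and E domains; the reported
#' fractions quantify its enrichment in basic (K, R) and charged (K, R, D,
#' E) residues, the hallmark of IGF-type C-terminal extensions.
#'
#' @param seq Amino-acid string.
#' @param annotation A `domain_annotation`.
#' @return List with `tail_len`, `basic_fraction`, `charged_fraction` and
#'   `absent` (TRUE when there is no tail; fractions then 0).
#' @export
tail_features <- function(seq, annotation) {
  tail <- ""
  for (tag in c("D", "E")) {
    ivl <- annotation$intervals[[tag]]
    if (!is.null(ivl)) tail <- paste0(tail, substr(seq, ivl[1] + 1L, ivl[2]))
  }
  len <- nchar(tail)
  if (len == 0L) {
    return(list(tail_len = 0L, basic_fraction = 0, charged_fraction = 0,
                absent = TRUE))
  }
  res <- strsplit(tail, "")[[1]]
  basic <- sum(res %in% c("K", "R"))
  charged <- basic + sum(res %in% c("D", "E"))
  list(tail_len = len, basic_fraction = basic / len,
       charged_fraction = charged / len, absent = FALSE)
}

#' F-domain length and conservation
#'
#' @param seq Amino-acid string.
#' @param annotation A `domain_annotation`.
#' @param references Optional character vector of reference F-domain
#'   sequences; when given, the mean pairwise identity between this
#'   precursor's F domain and each reference (after global alignment) is
#'   reported.
#' @param config Configuration list.
#' @return List with `f_len` (0 when absent) and `f_identity` (`NULL`
#'   without references or without an F domain).
#' @export
f_domain_metrics <- function(seq, annotation, references = NULL,
                             config = irp_config()) {
  ivl <- annotation$intervals[["F"]]
  if (is.null(ivl)) return(list(f_len = 0L, f_identity = NULL))
  fseq <- substr(seq, ivl[1] + 1L, ivl[2])
  f_len <- nchar(fseq)
  if (is.null(references) || !length(references)) {
    return(list(f_len = f_len, f_identity = NULL))
  }
  ids <- vapply(references, function(ref) {
    aln <- pairwise_align(fseq, ref, config)
    alignment_identity(aln$a_aligned, aln$b_aligned)
  }, 0)
  list(f_len = f_len, f_identity = mean(ids))
}

#' Write domain annotations as GFF3-style feature lines
#'
#' One feature line per domain per precursor, 1-based inclusive coordinates
#' on the protein sequence.
#'
#' @param annotations Named list of `domain_annotation` objects (names =
#'   precursor ids).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_gff3 <- function(annotations, path) {
  type_of <- c(signal = "signal_peptide", F = "F_domain", B = "B_domain",
               C = "C_domain", A = "A_domain", D = "D_domain", E = "E_domain")
  lines <- "##gff-version 3"
  for (id in names(annotations)) {
    ann <- annotations[[id]]
    for (tag in names(ann$intervals)) {
      ivl <- ann$intervals[[tag]]
      lines <- c(lines, sprintf("%s\tirpannot\t%s\t%d\t%d\t.\t.\t.\tID=%s.%s",
                                id, type_of[[tag]], ivl[1] + 1L, ivl[2],
                                id, tag))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
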