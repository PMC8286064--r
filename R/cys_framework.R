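#' Locate the canonical six-cysteine insulin core framework
#'
#' Searches for the A-chain motif `C-C-x(a)-C-x(b)-C` (CA1..CA4, with CA1 and
#' CA2 adjacent) scanning from the C terminus towards the N terminus, then for
#' the two B-chain cysteines CB1/CB2 upstream of it. Spacing bounds default to
#' a generalization of the classical vertebrate insulin spacings (3, 8 and 12
#' residues); an assignment scores one point for each spacing sitting exactly
#' at its modal value, and the highest-scoring consistent assignment wins.
#' Ties are broken towards the most C-terminal A-chain motif, as the A chain
#' is C-terminal in all families considered.
#'
#' @param seq Amino-acid string (full precursor).
#' @param config Configuration list from [irp_config()].
#' @return A `cys_framework` object with 0-based indices `cb1`, `cb2`,
#'   `ca1`..`ca4`, or `NULL` when no consistent assignment exists.
#' @export
find_core_framework <- function(seq, config = irp_config()) {
  n <- nchar(seq)
  if (n < 40L) return(NULL)
  res <- strsplit(seq, "")[[1]]
  cys <- which(res == "C") - 1L  # 0-based
  if (length(cys) < 6L) return(NULL)

  a_gap <- c(config$`framework.a_gap_min`, config$`framework.a_gap_max`)
  b_gap <- c(config$`framework.b_gap_min`, config$`framework.b_gap_max`)
  bpair <- c(config$`framework.bpair_min`, config$`framework.bpair_max`)
  c_span <- c(config$`framework.c_span_min`, config$`framework.c_span_max`)

  best <- NULL
  best_key <- NULL
  # A-chain motif anchors: adjacent CC pairs, scanned C-terminal first
  ca1s <- cys[(cys + 1L) %in% cys]
  for (ca1 in rev(ca1s)) {
    ca2 <- ca1 + 1L
    ca3s <- cys[cys - ca2 - 1L >= a_gap[1] & cys - ca2 - 1L <= a_gap[2]]
    for (ca3 in ca3s) {
      ca4s <- cys[cys - ca3 - 1L >= b_gap[1] & cys - ca3 - 1L <= b_gap[2]]
      for (ca4 in ca4s) {
        cb2s <- cys[ca1 - cys >= c_span[1] & ca1 - cys <= c_span[2]]
        for (cb2 in cb2s) {
          cb1s <- cys[cb2 - cys >= bpair[1] & cb2 - cys <= bpair[2]]
          for (cb1 in cb1s) {
            score <- (ca3 - ca2 - 1L == config$`framework.a_gap_modal`) +
              (ca4 - ca3 - 1L == config$`framework.b_gap_modal`) +
              (cb2 - cb1 == config$`framework.bpair_modal`)
            key <- c(score, ca1, ca4, cb2, cb1)
            if (is.null(best_key) || key_greater(key, best_key)) {
              best_key <- key
              best <- c(cb1 = cb1, cb2 = cb2, ca1 = ca1, ca2 = ca2,
                        ca3 = ca3, ca4 = ca4)
            }
          }
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(list(cb1 = best[["cb1"]], cb2 = best[["cb2"]], ca1 = best[["ca1"]],
                 ca2 = best[["ca2"]], ca3 = best[["ca3"]], ca4 = best[["ca4"]],
                 core = unname(best)),
            class = "cys_framework")
}

key_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.cys_framework <- function(x, ...) {
  cat(sprintf("<cys_framework CB1=%d CB2=%d CA1=%d CA2=%d CA3=%d CA4=%d (0-based)>\n",
              x$cb1, x$cb2, x$ca1, x$ca2, x$ca3, x$ca4))
  invisible(x)
}

#' Classify cysteines outside the six-cysteine core
#'
#' Every cysteine in the mature region (after the signal peptide) that is not
#' one of the six core positions is reported together with the precursor
#' region it falls in. Tagging is positional relative to the framework: a
#' cysteine beyond CA4 is tagged `D` (or `E` when an E domain contains it)
#' even when the segmentation merged a short C-terminal stub into A, so that
#' the tag reflects where the residue sits relative to the core.
#'
#' @param seq Amino-acid string.
#' @param framework A `cys_framework`.
#' @param annotation A `domain_annotation` from [segment_domains()].
#' @return Data frame with columns `index` (0-based) and `domain_tag`; zero
#'   rows when there are no extra cysteines.
#' @export
classify_extra_cysteines <- function(seq, framework, annotation) {
  if (is.null(framework)) stop("framework required")
  if (is.null(annotation)) {
    stop("domain segmentation must be computed before classifying extra cysteines")
  }
  res <- strsplit(seq, "")[[1]]
  cys <- which(res == "C") - 1L
  signal_end <- annotation$intervals[["signal"]][2]
  if (is.null(signal_end)) signal_end <- 0L
  extras <- setdiff(cys[cys >= signal_end], framework$core)
  if (!length(extras)) {
    return(data.frame(index = integer(), domain_tag = character(),
                      stringsAsFactors = FALSE))
  }
  b_start <- if (!is.null(annotation$intervals[["B"]])) {
    annotation$intervals[["B"]][1]
  } else framework$cb1
  e_iv <- annotation$intervals[["E"]]
  tag_one <- function(idx) {
    if (idx > framework$ca4) {
      if (!is.null(e_iv) && idx >= e_iv[1] && idx < e_iv[2]) "E" else "D"
    } else if (idx >= framework$ca1) "A"
    else if (idx > framework$cb2) "C"
    else if (idx >= b_start) "B"
    else "F"
  }
  data.frame(index = extras,
             domain_tag = vapply(extras, tag_one, ""),
             stringsAsFactors = FALSE)
}

#' Infer the disulfide-bridge count from a cysteine framework
#'
#' Six core cysteines give the canonical three bridges (CA1-CA3, CA2-CB1,
#' CA4-CB2); each additional cysteine pair adds one bridge, predicted to form
#' between the members of the extra pair. An odd extra-cysteine count is
#' reported for the paired subset with a warning flag; the physical pairing of
#' any fourth bridge is flagged, not asserted.
#'
#' @param framework A `cys_framework`.
#' @param extras Data frame from [classify_extra_cysteines()] (or `NULL` for
#'   none).
#' @return List with `n_bridges`, `canonical_pairing` (character vector),
#'   `extra_pairs` and `unpaired_warning`.
#' @export
infer_bridges <- function(framework, extras = NULL) {
  if (is.null(framework)) stop("framework required")
  n_extra <- if (is.null(extras)) 0L else nrow(extras)
  pairing <- c("CA1-CA3", "CA2-CB1", "CA4-CB2")
  n_pairs <- n_extra %/% 2L
  list(n_bridges = 3L + n_pairs,
       canonical_pairing = pairing,
       extra_pairs = n_pairs,
       unpaired_warning = (n_extra %% 2L == 1L))
}
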