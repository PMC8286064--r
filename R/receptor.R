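#' Transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Positions whose centered window mean hydropathy exceeds the threshold
#' are marked; maximal runs of marked positions shorter than `min_run` are
#' discarded and runs separated by fewer than `merge_gap` residues are
#' merged. The classical 19-residue window with threshold 1.6 flags
#' membrane-spanning helices.
#'
#' @param seq Amino-acid string, at least one window long.
#' @param config Configuration list (keys `tm.window`, `tm.threshold`,
#'   `tm.min_run`, `tm.merge_gap`).
#' @return Integer matrix with columns `start`, `end` (0-based half-open
#'   intervals of marked centre positions); zero rows when none.
#' @export
hydropathy_tm_segments <- function(seq, config = irp_config()) {
  w <- config$`tm.window`
  n <- nchar(seq)
  if (n < w) stop("sequence shorter than the hydropathy window (", w, ")")
  prof <- hydropathy_profile(seq)
  half <- (w - 1L) %/% 2L
  means <- stats::filter(prof, rep(1 / w, w), sides = 2)
  centers <- which(!is.na(means) & means > config$`tm.threshold`) - 1L
  runs_to_intervals(centers, n, config$`tm.min_run`, config$`tm.merge_gap`)
}

runs_to_intervals <- function(marked, n, min_run, merge_gap) {
  empty <- matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))
  if (!length(marked)) return(empty)
  breaks <- which(diff(marked) > 1L)
  starts <- marked[c(1L, breaks + 1L)]
  ends <- marked[c(breaks, length(marked))] + 1L
  # merge runs separated by < merge_gap residues
  if (length(starts) > 1L) {
    out_s <- integer(); out_e <- integer()
    cur_s <- starts[1L]; cur_e <- ends[1L]
    for (k in 2L:length(starts)) {
      if (starts[k] - cur_e < merge_gap) {
        cur_e <- ends[k]
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        cur_s <- starts[k]; cur_e <- ends[k]
      }
    }
    out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
    starts <- out_s; ends <- out_e
  }
  keep <- (ends - starts) >= min_run
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(empty)
  cbind(start = starts, end = ends)
}

# all (possibly overlapping) match start positions of a perl regex, 0-based
regex_match_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

#' Find LDLa repeats
#'
#' Non-overlapping, left-to-right shortest matches of the six-cysteine
#' pattern `C-x(2,7)-C-x(3,9)-C-x(4,10)-C-x(2,8)-C-x(5,14)-C`, each of
#' which must be followed within `ldla.acidic_lookahead` residues by a
#' window of `ldla.acidic_window` residues containing at least
#' `ldla.acidic_min` acidic residues (D/E) — the calcium-binding acidic
#' cluster that closes a class-A LDL-receptor module.
#'
#' @param seq Amino-acid string.
#' @param config Configuration list.
#' @return Integer matrix with columns `start`, `end` (0-based half-open);
#'   zero rows when none.
#' @export
find_ldla_repeats <- function(seq, config = irp_config()) {
  pattern <- "C.{2,7}?C.{3,9}?C.{4,10}?C.{2,8}?C.{5,14}?C"
  res <- strsplit(seq, "")[[1]]
  acidic <- res %in% c("D", "E")
  look <- config$`ldla.acidic_lookahead`
  win <- config$`ldla.acidic_window`
  amin <- config$`ldla.acidic_min`
  n <- nchar(seq)
  out_s <- integer(); out_e <- integer()
  from <- 1L
  while (from <= n) {
    m <- regexpr(pattern, substr(seq, from, n), perl = TRUE)
    if (m == -1L) break
    start0 <- from - 1L + (as.integer(m) - 1L)           # 0-based
    end0 <- start0 + attr(m, "match.length")             # half-open
    # acidic cluster requirement downstream of the last cysteine
    tail_idx <- if (end0 < n) seq.int(end0 + 1L, min(end0 + look, n)) else integer()
    ok <- FALSE
    if (length(tail_idx) >= win) {
      for (s in seq_len(length(tail_idx) - win + 1L)) {
        if (sum(acidic[tail_idx[s:(s + win - 1L)]]) >= amin) { ok <- TRUE; break }
      }
    } else if (length(tail_idx) && sum(acidic[tail_idx]) >= amin) {
      ok <- TRUE
    }
    if (ok) {
      out_s <- c(out_s, start0); out_e <- c(out_e, end0)
      from <- end0 + 1L
    } else {
      from <- start0 + 2L  # re-anchor after this cysteine
    }
  }
  if (!length(out_s)) {
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = out_s, end = out_e)
}

#' Find leucine-rich repeats
#'
#' Matches of the LRR consensus `J-x-x-J-x-J-x-x-[NC]-x-J` with
#' `J = {L,I,V,F}`; matches starting closer than `lrr.collapse_dist`
#' residues after a previously kept match are collapsed into it.
#'
#' @param seq Amino-acid string.
#' @param config Configuration list.
#' @return Integer matrix with columns `start`, `end` (0-based half-open,
#'   11 residues each); zero rows when none.
#' @export
find_lrr_repeats <- function(seq, config = irp_config()) {
  starts <- regex_match_starts(seq,
    "[LIVF]..[LIVF].[LIVF]..[NC].[LIVF]")
  keep <- integer()
  last <- -Inf
  for (s in starts) {
    if (s - last >= config$`lrr.collapse_dist`) {
      keep <- c(keep, s)
      last <- s
    }
  }
  if (!length(keep)) {
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = keep, end = keep + 11L)
}

#' Annotate a candidate irp receptor
#'
#' Runs transmembrane, LDLa and LRR detection and calls the ectodomain
#' architecture: `GRL101_like` for seven transmembrane segments with many
#' LDLa repeats (>= `arch.grl101_min_ldla`) plus LRRs,
#' `single_LDLa_LGR_like` for seven transmembrane segments with one or two
#' LDLa repeats plus LRRs, `other` otherwise.
#'
#' @param record A sequence record (or amino-acid string).
#' @param config Configuration list.
#' @return A `receptor_annotation` list: `id`, `tm_segments`, `n_tm`,
#'   `ldla_repeats`, `lrr_repeats`, `n_ldla`, `n_lrr`, `architecture_call`.
#' @export
annotate_receptor <- function(record, config = irp_config()) {
  if (is.character(record)) record <- new_seq_record("receptor", record)
  seq <- record$residues
  tm <- hydropathy_tm_segments(seq, config)
  ldla <- find_ldla_repeats(seq, config)
  lrr <- find_lrr_repeats(seq, config)
  ann <- list(id = record$id, tm_segments = tm, n_tm = nrow(tm),
              ldla_repeats = ldla, lrr_repeats = lrr,
              n_ldla = nrow(ldla), n_lrr = nrow(lrr))
  ann$architecture_call <- receptor_summary(ann, config)
  structure(ann, class = "receptor_annotation")
}

#' Architecture call from a receptor annotation
#'
#' @param annotation List with `n_tm`, `n_ldla`, `n_lrr`.
#' @param config Configuration list.
#' @return `"GRL101_like"`, `"single_LDLa_LGR_like"` or `"other"`.
#' @export
receptor_summary <- function(annotation, config = irp_config()) {
  if (annotation$n_tm == 7L &&
      annotation$n_ldla >= config$`arch.grl101_min_ldla` &&
      annotation$n_lrr >= config$`arch.grl101_min_lrr`) {
    "GRL101_like"
  } else if (annotation$n_tm == 7L && annotation$n_ldla %in% c(1L, 2L) &&
             annotation$n_lrr >= config$`arch.lgr_min_lrr`) {
    "single_LDLa_LGR_like"
  } else {
    "other"
  }
}

#' @export
print.receptor_annotation <- function(x, ...) {
  cat(sprintf("<receptor_annotation %s: %d TM, %d LDLa, %d LRR -> %s>\n",
              x$id, x$n_tm, x$n_ldla, x$n_lrr, x$architecture_call))
  invisible(x)
}

#' Tabulate receptor annotations
#'
#' @param annotations List of `receptor_annotation` objects.
#' @return Data frame with one row per receptor.
#' @export
receptor_report <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    data.frame(id = a$id, n_tm = a$n_tm, n_lrr = a$n_lrr, n_ldla = a$n_ldla,
               architecture_call = a$architecture_call,
               stringsAsFactors = FALSE)
  }))
}
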