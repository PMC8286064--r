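#' Default configuration for the irp annotation pipeline
#'
#' Every numeric threshold and rule table used by the pipeline lives in one
#' flat key-value map, so that all tunables are visible and overridable in a
#' single place. Keys are namespaced as `section.key`.
#'
#' Sections:
#' \describe{
#'   \item{framework.*}{Spacing bounds for the six-cysteine core search.
#'     `a_gap_*` bound the residues between CA2 and CA3, `b_gap_*` between
#'     CA3 and CA4, `bpair_*` the CB2-CB1 index difference and `c_span_*`
#'     the CA1-CB2 difference (the C-domain span). The `*_modal` values are
#'     the spacings of the classical vertebrate insulin core used for
#'     scoring.}
#'   \item{cleavage.*}{Signal-peptide scan range, hydropathy settings and
#'     the convertase rule tables: the bulky P1' exclusion set, the
#'     pre-site proline window, the disulfide proximity window (residues
#'     from any core cysteine to a P1 position), and switches for the
#'     optional RR/KK/RK and monobasic motifs (off by default).}
#'   \item{domains.*}{`b_lead` is the number of B-chain residues allowed
#'     upstream of CB1; a pre-B region at least `f_min` residues long is
#'     called an F domain; a post-CA4 stub shorter than `d_min` residues is
#'     merged into A rather than opening a D domain.}
#'   \item{classify.*}{Family-call thresholds: minimal tail length and
#'     charged fraction for IGF, minimal F identity versus references for
#'     dilp7, and the expected extra-cysteine placements (comma-joined
#'     domain tags) for octinsulin and multinsulin.}
#'   \item{align.* / dist.* / tree.*}{Global-alignment scoring (BLOSUM62,
#'     affine gaps), the Poisson distance ceiling, and the region entering
#'     the similarity tree (`core` = concatenated B+A domains, or
#'     `mature`).}
#'   \item{synteny.max_gap}{Maximal gap (bp) between the coding regions of
#'     adjacent loci within one microsynteny cluster.}
#'   \item{tm.* / ldla.* / lrr.*}{Receptor annotation: Kyte-Doolittle
#'     window/threshold/run settings and the repeat-pattern parameters.}
#' }
#'
#' @param overrides Named list (or named vector) of `section.key = value`
#'   pairs overriding the defaults. Unknown keys are an error.
#' @return Named list with one entry per configuration key.
#' @export
#' @examples
#' cfg <- irp_config()
#' cfg <- irp_config(list(`synteny.max_gap` = 5e5))
irp_config <- function(overrides = NULL) {
  cfg <- list(
    # six-cysteine core search
    `framework.a_gap_min` = 2L, `framework.a_gap_max` = 6L,
    `framework.b_gap_min` = 6L, `framework.b_gap_max` = 14L,
    `framework.bpair_min` = 8L, `framework.bpair_max` = 16L,
    `framework.c_span_min` = 5L, `framework.c_span_max` = 80L,
    `framework.a_gap_modal` = 3L, `framework.b_gap_modal` = 8L,
    `framework.bpair_modal` = 12L,
    # cleavage prediction
    `cleavage.signal_min` = 15L, `cleavage.signal_max` = 35L,
    `cleavage.h_window_start` = 13L, `cleavage.h_window_end` = 6L,
    `cleavage.h_threshold` = 1.5,
    `cleavage.bulky` = "WFYILV",
    `cleavage.pre_proline_positions` = "3,4",
    `cleavage.disulfide_window` = 3L,
    `cleavage.dibasic_kr` = TRUE,
    `cleavage.dibasic_rr` = FALSE, `cleavage.dibasic_kk` = FALSE,
    `cleavage.dibasic_rk` = FALSE,
    `cleavage.monobasic_r` = FALSE,
    # domain segmentation
    `domains.b_lead` = 8L, `domains.f_min` = 15L, `domains.d_min` = 6L,
    # family classification
    `classify.tail_min` = 25L, `classify.charged_min` = 0.3,
    `classify.f_identity_min` = 0.4,
    `classify.octinsulin_extra_domains` = "B,D",
    `classify.multinsulin_extra_domains` = "C,C",
    # alignment / distances / trees
    `align.matrix` = "BLOSUM62",
    `align.gap_open` = 11, `align.gap_extend` = 1,
    `dist.correction` = "poisson", `dist.cap` = 5.0,
    `tree.region` = "core",
    # synteny
    `synteny.max_gap` = 1e6,
    # gene structure
    `genes.igf_tail_frac` = 0.25,
    # receptor annotation
    `tm.window` = 19L, `tm.threshold` = 1.6, `tm.min_run` = 8L,
    `tm.merge_gap` = 3L,
    `ldla.acidic_lookahead` = 12L, `ldla.acidic_window` = 8L,
    `ldla.acidic_min` = 3L,
    `lrr.collapse_dist` = 20L,
    # receptor architecture calls
    `arch.grl101_min_ldla` = 6L, `arch.grl101_min_lrr` = 3L,
    `arch.lgr_min_lrr` = 3L
  )
  apply_overrides(cfg, overrides)
}

apply_overrides <- function(cfg, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(cfg)
  overrides <- as.list(overrides)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
    stop("config overrides must be named")
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in names(overrides)) {
    cfg[[key]] <- coerce_config_value(key, overrides[[key]], cfg[[key]])
  }
  cfg
}

coerce_config_value <- function(key, value, default) {
  if (is.logical(default)) {
    out <- if (is.character(value)) {
      toupper(value) %in% c("TRUE", "T", "YES", "ON", "1")
    } else as.logical(value)
    if (is.na(out)) stop("config key ", key, " must be logical")
    return(out)
  }
  if (is.numeric(default)) {
    out <- suppressWarnings(as.numeric(value))
    if (is.na(out)) stop("config key ", key, " must be numeric, got '", value, "'")
    if (is.integer(default)) out <- as.integer(round(out))
    return(out)
  }
  as.character(value)
}

#' Read a flat key-value configuration file
#'
#' The file format is one `section.key = value` assignment per line; blank
#' lines and lines starting with `#` are ignored. Keys must exist among the
#' [irp_config()] defaults and values are type-checked against them.
#'
#' @param path Path to the configuration file.
#' @return Full configuration list (defaults overridden by the file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected key = value): ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    overrides[[key]] <- val
  }
  irp_config(overrides)
}
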