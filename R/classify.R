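#' Extract the classification feature vector of a precursor
#'
#' Deterministic aggregation of the upstream annotations; no thresholds are
#' applied here. When the cysteine framework is absent a flagged vector is
#' returned so the classifier can report `unclassified` with its reason.
#'
#' @param framework `cys_framework` or `NULL`.
#' @param extras Data frame from [classify_extra_cysteines()].
#' @param annotation `domain_annotation`.
#' @param tail List from [tail_features()].
#' @param f_metrics List from [f_domain_metrics()].
#' @param sites Cleavage-site data frame.
#' @param gene_sig Optional gene-structure signature list from
#'   [gene_signature()].
#' @return List of features (`framework_absent`, `n_extra_cys`,
#'   `extra_cys_domains`, `chain_mode`, `f_len`, `f_identity`, `tail_len`,
#'   `basic_fraction`, `charged_fraction`, `n_accepted_kr_sites`,
#'   `gene_signature`).
#' @export
extract_features <- function(framework, extras = NULL, annotation = NULL,
                             tail = NULL, f_metrics = NULL, sites = NULL,
                             gene_sig = NULL) {
  if (is.null(framework)) {
    return(list(framework_absent = TRUE, n_extra_cys = NA_integer_,
                extra_cys_domains = character(), chain_mode = NA_character_,
                f_len = NA_integer_, f_identity = NULL, tail_len = NA_integer_,
                basic_fraction = NA_real_, charged_fraction = NA_real_,
                n_accepted_kr_sites = NA_integer_,
                gene_signature = if (is.null(gene_sig)) NULL else gene_sig$token))
  }
  acc_kr <- sites[sites$verdict == "accepted" & sites$kind == "dibasic", ,
                  drop = FALSE]
  list(framework_absent = FALSE,
       n_extra_cys = nrow(extras),
       extra_cys_domains = sort(extras$domain_tag),
       chain_mode = annotation$chain_mode,
       f_len = f_metrics$f_len,
       f_identity = f_metrics$f_identity,
       tail_len = tail$tail_len,
       basic_fraction = tail$basic_fraction,
       charged_fraction = tail$charged_fraction,
       n_accepted_kr_sites = nrow(acc_kr),
       gene_signature = if (is.null(gene_sig)) NULL else gene_sig$token)
}

# TRUE when the configured extra-cysteine pair is present among the observed
# extra-cysteine domain tags (with multiplicity). Containment rather than
# equality: a stray unpaired cysteine - already flagged by the bridge parity
# rule - must not void the diagnostic pair.
placement_matches <- function(domains, configured) {
  expected <- sort(trimws(strsplit(configured, ",")[[1]]))
  if (length(domains) < length(expected)) return(FALSE)
  remaining <- domains
  for (tag in expected) {
    hit <- match(tag, remaining)
    if (is.na(hit)) return(FALSE)
    remaining <- remaining[-hit]
  }
  TRUE
}

#' Classify a precursor into an irp family
#'
#' Evidence-weighted decision rules, most specific structural marks first:
#' \enumerate{
#'   \item extra cysteines in the octinsulin placement plus at least one
#'     accepted KR site: octinsulin;
#'   \item an F domain (identity versus references at least
#'     `classify.f_identity_min` when references were supplied) in a
#'     two-chain precursor: dilp7 ortholog;
#'   \item a long charged C-terminal tail in a single-chain precursor: IGF;
#'   \item a two-chain precursor with no extra cysteine pair (one unpaired
#'     stray is flagged, not diagnostic), no F domain and a short tail: GSS;
#'   \item a two-chain precursor without an F domain whose extra cysteines
#'     include the multinsulin placement pair, or whose gene signature says
#'     multinsulin: multinsulin.
#' }
#' When both the GSS and multinsulin rules fire, the gene signature
#' decides; without one the call is GSS with runner-up multinsulin at low
#' confidence. Confidence is `high` with at least two concordant marks
#' (gene-structure agreement counts as a mark and is required for a high
#' structural multinsulin call), `medium` otherwise; `unclassified` calls
#' are always `low` and carry the reason in their evidence.
#'
#' @param fv Feature list from [extract_features()].
#' @param config Configuration list.
#' @return List with `label`, `confidence`, `evidence` and `runner_up`.
#' @export
classify_family <- function(fv, config = irp_config()) {
  call <- function(label, confidence, evidence, runner_up = NA_character_) {
    list(label = label, confidence = confidence, evidence = evidence,
         runner_up = runner_up)
  }
  if (isTRUE(fv$framework_absent)) {
    return(call("unclassified", "low", "no-cysteine-framework"))
  }
  f_min <- config$`domains.f_min`
  two_chain <- identical(fv$chain_mode, "two_chain")
  gs <- fv$gene_signature

  # (1) octinsulin
  if (placement_matches(fv$extra_cys_domains,
                        config$`classify.octinsulin_extra_domains`) &&
      fv$n_accepted_kr_sites >= 1L) {
    ev <- c("extra-cys-octinsulin-placement", "accepted-kr-sites")
    if (identical(gs, "GSS_or_octinsulin")) ev <- c(ev, "gene-signature-concordant")
    return(call("octinsulin", "high", ev))
  }
  # (2) dilp7
  f_ok <- fv$f_len >= f_min &&
    (is.null(fv$f_identity) || fv$f_identity >= config$`classify.f_identity_min`)
  if (f_ok && two_chain) {
    ev <- c("f-domain-present", "two-chain")
    if (!is.null(fv$f_identity)) ev <- c(ev, "f-domain-conserved")
    if (identical(gs, "dilp7")) ev <- c(ev, "gene-signature-concordant")
    return(call("dilp7", "high", ev))
  }
  # (3) IGF
  if (fv$tail_len >= config$`classify.tail_min` &&
      fv$charged_fraction >= config$`classify.charged_min` &&
      identical(fv$chain_mode, "single_chain")) {
    ev <- c("long-charged-tail", "single-chain")
    if (identical(gs, "IGF")) ev <- c(ev, "gene-signature-concordant")
    return(call("IGF", "high", ev))
  }
  # (4) GSS and (5) multinsulin share the two-chain, F-less residual space.
  # GSS requires no extra cysteine PAIR; a single unpaired cysteine is the
  # bridge-parity anomaly, flagged but not family-diagnostic.
  gss_fires <- two_chain && fv$tail_len < config$`classify.tail_min` &&
    fv$f_len < f_min && fv$n_extra_cys <= 1L
  mult_fires <- two_chain && fv$f_len < f_min &&
    (placement_matches(fv$extra_cys_domains,
                       config$`classify.multinsulin_extra_domains`) ||
       identical(gs, "multinsulin"))
  if (gss_fires && mult_fires) {
    if (identical(gs, "multinsulin")) {
      return(call("multinsulin", "high",
                  c("gene-signature-multinsulin", "two-chain", "no-f-domain"),
                  runner_up = "GSS"))
    }
    return(call("GSS", "low", c("two-chain", "residual-tie"),
                runner_up = "multinsulin"))
  }
  if (mult_fires) {
    ev <- c("two-chain", "no-f-domain")
    n_marks <- 0L
    if (placement_matches(fv$extra_cys_domains,
                          config$`classify.multinsulin_extra_domains`)) {
      ev <- c("extra-cys-multinsulin-placement", ev)
      n_marks <- n_marks + 1L
    }
    if (identical(gs, "multinsulin")) {
      ev <- c(ev, "gene-signature-concordant")
      n_marks <- n_marks + 1L
    }
    return(call("multinsulin", if (n_marks >= 2L) "high" else "medium", ev))
  }
  if (gss_fires) {
    ev <- c("two-chain", "no-extra-cys-pair", "short-tail", "no-f-domain")
    conf <- "high"
    if (fv$n_extra_cys == 1L) {
      ev <- c(ev, "unpaired-extra-cys")
      conf <- "medium"
    }
    if (identical(gs, "GSS_or_octinsulin")) ev <- c(ev, "gene-signature-concordant")
    return(call("GSS", conf, ev))
  }
  call("unclassified", "low", "no-family-rule-fired")
}
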