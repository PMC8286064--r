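#' Annotate a single precursor end to end
#'
#' Runs the full stage order: cysteine framework, signal peptide, cleavage
#' sites, domain segmentation, tail and F-domain features, optional gene
#' structure, family classification.
#'
#' @param record Sequence record (or amino-acid string).
#' @param gene Optional `gene_model` for the same protein.
#' @param f_references Optional character vector of reference F-domain
#'   sequences for the conservation score.
#' @param signal_override Optional known signal cleavage position.
#' @param config Configuration list.
#' @return List with all intermediate results (`framework`, `signal_pos`,
#'   `sites`, `annotation`, `extras`, `bridges`, `tail`, `f_metrics`,
#'   `introns`, `gene_sig`, `features`, `call`).
#' @export
annotate_precursor <- function(record, gene = NULL, f_references = NULL,
                               signal_override = NULL, config = irp_config()) {
  if (is.character(record)) record <- new_seq_record("query", record)
  seq <- record$residues
  fw <- find_core_framework(seq, config)
  if (is.null(fw)) {
    fv <- extract_features(NULL)
    return(list(id = record$id, framework = NULL, signal_pos = NA_integer_,
                sites = empty_sites(), annotation = NULL, extras = NULL,
                bridges = NULL, tail = NULL, f_metrics = NULL, introns = NULL,
                gene_sig = NULL, features = fv,
                call = classify_family(fv, config)))
  }
  signal_pos <- predict_signal_cleavage(seq, signal_override, config)
  sites <- find_cleavage_sites(seq, signal_pos, fw, config)
  annotation <- segment_domains(seq, signal_pos, fw, sites, config)
  extras <- classify_extra_cysteines(seq, fw, annotation)
  bridges <- infer_bridges(fw, extras)
  tail <- tail_features(seq, annotation)
  f_metrics <- f_domain_metrics(seq, annotation, f_references, config)
  introns <- NULL
  gene_sig <- NULL
  if (!is.null(gene)) {
    introns <- compute_intron_phases(gene)
    introns <- map_introns_to_domains(introns, annotation, gene, nchar(seq))
    gene_sig <- gene_signature(introns, gene$cds_length, config)
  }
  fv <- extract_features(fw, extras, annotation, tail, f_metrics, sites,
                         gene_sig)
  list(id = record$id, framework = fw, signal_pos = signal_pos, sites = sites,
       annotation = annotation, extras = extras, bridges = bridges,
       tail = tail, f_metrics = f_metrics, introns = introns,
       gene_sig = gene_sig, features = fv, call = classify_family(fv, config))
}

#' Annotate a batch of precursors
#'
#' Per-record failures are caught and reported as rows with a failure
#' reason; one input record always yields exactly one report row, and a
#' failing record never aborts the batch.
#'
#' @param records List of sequence records.
#' @param genes Optional named list of `gene_model` objects (names matched
#'   against record ids).
#' @param f_references Optional reference F-domain sequences.
#' @param config Configuration list.
#' @return List with `report` (data frame, one row per record) and
#'   `annotations` (named list of per-record results, `NULL` on failure).
#' @export
run_annotate <- function(records, genes = NULL, f_references = NULL,
                         config = irp_config()) {
  rows <- vector("list", length(records))
  anns <- stats::setNames(vector("list", length(records)),
                          vapply(records, `[[`, "", "id"))
  for (k in seq_along(records)) {
    rec <- records[[k]]
    gene <- if (!is.null(genes) && rec$id %in% names(genes)) genes[[rec$id]]
    ann <- tryCatch(
      annotate_precursor(rec, gene, f_references, config = config),
      error = function(e) e)
    if (inherits(ann, "error")) {
      rows[[k]] <- data.frame(
        id = rec$id, status = "failed", label = "unclassified",
        confidence = "low", runner_up = NA_character_,
        evidence = paste0("error: ", conditionMessage(ann)),
        core_cys_positions = NA_character_, n_extra_cys = NA_integer_,
        n_bridges = NA_integer_, chain_mode = NA_character_,
        f_len = NA_integer_, tail_len = NA_integer_,
        charged_fraction = NA_real_, n_accepted_kr_sites = NA_integer_,
        gene_signature = NA_character_, stringsAsFactors = FALSE)
      next
    }
    anns[[rec$id]] <- ann
    fw <- ann$framework
    rows[[k]] <- data.frame(
      id = rec$id, status = "ok", label = ann$call$label,
      confidence = ann$call$confidence,
      runner_up = ann$call$runner_up,
      evidence = paste(ann$call$evidence, collapse = ";"),
      core_cys_positions = if (is.null(fw)) NA_character_ else
        paste(fw$core + 1L, collapse = ","),
      n_extra_cys = if (is.null(ann$extras)) NA_integer_ else nrow(ann$extras),
      n_bridges = if (is.null(ann$bridges)) NA_integer_ else
        ann$bridges$n_bridges,
      chain_mode = if (is.null(ann$annotation)) NA_character_ else
        ann$annotation$chain_mode,
      f_len = if (is.null(ann$f_metrics)) NA_integer_ else ann$f_metrics$f_len,
      tail_len = if (is.null(ann$tail)) NA_integer_ else ann$tail$tail_len,
      charged_fraction = if (is.null(ann$tail)) NA_real_ else
        ann$tail$charged_fraction,
      n_accepted_kr_sites = ann$features$n_accepted_kr_sites,
      gene_signature = if (is.null(ann$gene_sig)) NA_character_ else
        ann$gene_sig$token,
      stringsAsFactors = FALSE)
  }
  list(report = do.call(rbind, rows), annotations = anns)
}

#' Write the annotation report as TSV
#'
#' @param report Data frame from [run_annotate()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
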