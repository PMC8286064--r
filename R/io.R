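#' @importFrom methods as is
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

new_seq_record <- function(id, residues, description = "") {
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s: %d aa%s>\n", x$id, nchar(x$residues),
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

check_residues <- function(residues, id = "?", allow_x = TRUE) {
  ok <- c(AA_ALPHABET, if (allow_x) "X")
  bad <- setdiff(strsplit(residues, "")[[1]], ok)
  if (length(bad)) {
    stop("record '", id, "' contains non-amino-acid character(s): ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a protein FASTA file
#'
#' Residues are uppercased, `*` stop symbols are stripped with a warning, and
#' `X` is kept as the unknown residue. Record ids (the first whitespace-token
#' of each header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @return List of sequence records, each with `id`, `description` and
#'   `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    residues <- toupper(as.character(set[[i]]))
    if (grepl("\\*", residues)) {
      warning("record '", ids[i], "': '*' stop symbol(s) stripped")
      residues <- gsub("*", "", residues, fixed = TRUE)
    }
    if (grepl("\\s", residues)) residues <- gsub("\\s+", "", residues)
    if (!nzchar(residues)) stop("record '", ids[i], "' has empty sequence")
    check_residues(residues, ids[i])
    out[[i]] <- new_seq_record(ids[i], residues, descs[i])
  }
  names(out) <- ids
  out
}

#' Write sequence records to FASTA
#'
#' @param records List of sequence records (as from [read_fasta()] or
#'   [make_precursor()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  headers <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "residues"))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

new_gene_model <- function(gene_id, seq_region, strand, cds_exons,
                           complete = NA) {
  stopifnot(strand %in% c("+", "-"))
  if (!is.matrix(cds_exons) || ncol(cds_exons) != 2L) {
    stop("cds_exons must be a two-column matrix of 0-based half-open intervals")
  }
  if (any(cds_exons[, 2] <= cds_exons[, 1])) stop("empty CDS exon interval")
  genomic <- cds_exons[order(cds_exons[, 1]), , drop = FALSE]
  if (nrow(genomic) > 1L &&
      any(genomic[-1L, 1] < genomic[-nrow(genomic), 2])) {
    stop("overlapping CDS exons in gene ", gene_id)
  }
  # transcript orientation: 5'-most exon first
  if (strand == "-") genomic <- genomic[rev(seq_len(nrow(genomic))), , drop = FALSE]
  len <- sum(genomic[, 2] - genomic[, 1])
  if (is.na(complete)) complete <- (len %% 3L == 0L)
  structure(list(gene_id = gene_id, seq_region = seq_region, strand = strand,
                 cds_exons = genomic, cds_length = len, complete = complete),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s: %d CDS exon(s), %d nt, %s strand%s>\n",
              x$gene_id, nrow(x$cds_exons), x$cds_length, x$strand,
              if (x$complete) ", complete" else ""))
  invisible(x)
}

#' Read CDS gene models from a GFF3 file
#'
#' CDS features are grouped per transcript via their `Parent` attribute and
#' ordered in transcript orientation (5' to 3'); GFF3 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file containing CDS features.
#' @return List of gene models, one per transcript.
#' @export
read_gff3_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0L) stop("no CDS features in ", path)
  parents <- gr$Parent
  if (is.null(parents) || any(vapply(parents, length, 0L) == 0L)) {
    stop("CDS feature(s) without a Parent attribute in ", path)
  }
  parent <- vapply(parents, `[[`, "", 1L)
  out <- list()
  for (tx in unique(parent)) {
    sel <- gr[parent == tx]
    strands <- unique(as.character(BiocGenerics::strand(sel)))
    if (length(strands) != 1L || !strands %in% c("+", "-")) {
      stop("mixed or missing strand within transcript ", tx)
    }
    exons <- cbind(BiocGenerics::start(sel) - 1L, BiocGenerics::end(sel))
    out[[tx]] <- new_gene_model(tx, as.character(GenomicRanges::seqnames(sel))[1],
                                strands, exons)
  }
  out
}

#' Write gene models as GFF3 CDS features
#'
#' @param genes List of gene models.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3_gene_models <- function(genes, path) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  lines <- "##gff-version 3"
  for (g in genes) {
    ex <- g$cds_exons[order(g$cds_exons[, 1]), , drop = FALSE]
    lines <- c(lines,
      sprintf("%s\tirpannot\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$seq_region, min(ex[, 1]) + 1L, max(ex[, 2]), g$strand,
              paste0(g$gene_id, ".gene")),
      sprintf("%s\tirpannot\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$seq_region, min(ex[, 1]) + 1L, max(ex[, 2]), g$strand,
              g$gene_id, paste0(g$gene_id, ".gene")),
      sprintf("%s\tirpannot\tCDS\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$seq_region, ex[, 1] + 1L, ex[, 2], g$strand,
              paste0(g$gene_id, ".cds"), g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene locus table for synteny analysis
#'
#' Expects a TSV with columns `gene_id`, `family_label`, `seq_region`,
#' `start`, `end`, `strand` (1-based inclusive coordinates in the file,
#' converted to 0-based half-open internally). Rows are returned sorted by
#' `(seq_region, start)`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of loci.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("locus table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "family_label", "seq_region", "start", "end", "strand")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("locus table lacks column(s): ", paste(missing, collapse = ", "))
  }
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in locus table")
  if (any(start < 1)) stop("coordinates must be positive (1-based in file)")
  if (any(start >= end)) {
    bad <- df$gene_id[start >= end][1]
    stop("locus '", bad, "' has start >= end")
  }
  start0 <- start - 1
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(gene_id = df$gene_id, family_label = df$family_label,
                    seq_region = df$seq_region, start = start0, end = end,
                    strand = df$strand, stringsAsFactors = FALSE)
  out[order(out$seq_region, out$start), , drop = FALSE]
}

#' Write a gene locus table
#'
#' @param loci Data frame of loci (internal 0-based half-open coordinates).
#' @param path Output path; coordinates are serialized 1-based inclusive.
#' @return Invisibly, `path`.
#' @export
write_locus_table <- function(loci, path) {
  out <- loci
  out$start <- out$start + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

needs_newick_quoting <- function(label) {
  grepl("[]['(),:;\\s]", label, perl = TRUE)
}

#' Serialize a tree to a Newick string
#'
#' Branch lengths are written at full precision and labels containing Newick
#' metacharacters are single-quoted. Duplicate leaf labels are an error.
#'
#' @param tree A `phylo` tree (from [neighbor_joining()] or [ape]).
#' @param path Optional path; when given the string is also written there.
#' @return The Newick string (terminated with `;`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  # labels with Newick metacharacters go through placeholders so that the
  # serializer cannot rewrite them, then come back single-quoted
  quoted <- tree
  needs <- which(vapply(tree$tip.label, needs_newick_quoting, TRUE))
  placeholders <- sprintf("xQUOTEDLBL%dx", seq_along(needs))
  quoted$tip.label[needs] <- placeholders
  str <- ape::write.tree(quoted, digits = 15)
  for (k in seq_along(needs)) {
    escaped <- gsub("'", "''", tree$tip.label[needs[k]])
    str <- sub(placeholders[k], sprintf("'%s'", escaped), str, fixed = TRUE)
  }
  if (!is.null(path)) writeLines(str, path)
  str
}

#' Parse a Newick string or file
#'
#' Inverse of [write_newick()]: single-quoted labels are unquoted.
#'
#' @param text Newick string, or `NULL` when `path` is given.
#' @param path Optional path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  # shield single-quoted labels from the parser, restore them afterwards
  pattern <- "'((?:[^']|'')*)'"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  labels <- character()
  if (m[1] != -1L) {
    raw <- regmatches(text, list(m))[[1]]
    labels <- gsub("''", "'", substr(raw, 2L, nchar(raw) - 1L))
    for (k in seq_along(raw)) {
      text <- sub(raw[k], sprintf("xQUOTEDLBL%dx", k), text, fixed = TRUE)
    }
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  for (k in seq_along(labels)) {
    tree$tip.label[tree$tip.label == sprintf("xQUOTEDLBL%dx", k)] <- labels[k]
  }
  tree
}
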