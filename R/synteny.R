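#' Detect microsynteny clusters of gene loci
#'
#' Within each sequence region, maximal runs of loci whose successive gaps
#' (next start minus current end, i.e. the distance between coding regions)
#' do not exceed `max_gap` form one cluster; singletons are clusters of size
#' one. Strand is carried along but does not affect clustering.
#'
#' @param loci Data frame from [read_locus_table()] or
#'   [make_synteny_layout()].
#' @param max_gap Maximal intra-cluster gap in bp (default from config,
#'   1 Mb).
#' @param config Configuration list.
#' @return List of clusters; each has `seq_region`, `members` (data frame,
#'   sorted by start) and `gaps_kb` (length `nrow(members) - 1`; an
#'   overlapping pair reports gap 0).
#' @export
cluster_loci <- function(loci, max_gap = NULL, config = irp_config()) {
  if (is.null(max_gap)) max_gap <- config$`synteny.max_gap`
  stopifnot(max_gap > 0)
  out <- list()
  for (region in unique(loci$seq_region)) {
    sub <- loci[loci$seq_region == region, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gaps <- if (nrow(sub) > 1L) {
      pmax(sub$start[-1L] - sub$end[-nrow(sub)], 0)
    } else numeric()
    breaks <- which(gaps > max_gap)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, nrow(sub))
    for (k in seq_along(starts)) {
      idx <- starts[k]:ends[k]
      members <- sub[idx, , drop = FALSE]
      rownames(members) <- NULL
      gk <- if (length(idx) > 1L) gaps[idx[-length(idx)]] / 1000 else numeric()
      out[[length(out) + 1L]] <- structure(
        list(seq_region = region, members = members, gaps_kb = gk),
        class = "synteny_cluster")
    }
  }
  out
}

#' @export
print.synteny_cluster <- function(x, ...) {
  cat(sprintf("<synteny_cluster %s: %s>\n", x$seq_region,
              paste(x$members$family_label, collapse = "-")))
  invisible(x)
}

#' Check for the conserved octinsulin-IGF-dilp7 arrangement
#'
#' Returns `"triplet_with_IGF_middle"` when the cluster contains octinsulin
#' (or gonadulin), IGF and dilp7 loci with at least one IGF locus strictly
#' between an octinsulin and a dilp7 locus in coordinate order — the
#' arrangement conserved between hemichordates and arthropods — and
#' `"other"` otherwise.
#'
#' @param cluster A `synteny_cluster` whose members carry `family_label`.
#' @return `"triplet_with_IGF_middle"` or `"other"`.
#' @export
conserved_arrangement_check <- function(cluster) {
  fam <- cluster$members$family_label
  oct_pos <- which(fam %in% c("octinsulin", "gonadulin"))
  igf_pos <- which(fam == "IGF")
  d7_pos <- which(fam == "dilp7")
  if (!length(oct_pos) || !length(igf_pos) || !length(d7_pos)) return("other")
  for (i in igf_pos) {
    if ((any(oct_pos < i) && any(d7_pos > i)) ||
        (any(d7_pos < i) && any(oct_pos > i))) {
      return("triplet_with_IGF_middle")
    }
  }
  "other"
}

cluster_composition <- function(cluster) {
  paste(sort(cluster$members$family_label), collapse = "+")
}

#' Compare synteny layouts across species
#'
#' For each species pair, reports the multiset intersection of cluster
#' family compositions together with a same/different verdict per
#' composition.
#'
#' @param layouts Named list (species -> list of clusters from
#'   [cluster_loci()]); at least two species.
#' @return Data frame with columns `species_a`, `species_b`, `composition`,
#'   `count_a`, `count_b`, `verdict` (`"shared"` when both species have the
#'   composition, `"different"` otherwise).
#' @export
compare_layouts <- function(layouts) {
  if (length(layouts) < 2L) stop("need >=2 species")
  if (is.null(names(layouts))) stop("layouts must be named by species")
  comp <- lapply(layouts, function(cl) table(vapply(cl, cluster_composition, "")))
  species <- names(layouts)
  rows <- list()
  for (i in seq_len(length(species) - 1L)) {
    for (j in (i + 1L):length(species)) {
      all_comp <- union(names(comp[[i]]), names(comp[[j]]))
      for (cc in sort(all_comp)) {
        ca <- if (cc %in% names(comp[[i]])) comp[[i]][[cc]] else 0L
        cb <- if (cc %in% names(comp[[j]])) comp[[j]][[cc]] else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          species_a = species[i], species_b = species[j], composition = cc,
          count_a = ca, count_b = cb,
          verdict = if (ca > 0L && cb > 0L) "shared" else "different",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write synteny clusters as a TSV report
#'
#' @param clusters List of clusters from [cluster_loci()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_table <- function(clusters, path) {
  rows <- lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    data.frame(cluster_id = k, seq_region = cl$seq_region,
               members = paste(sprintf("%s(%s)", cl$members$gene_id,
                                       cl$members$strand), collapse = ","),
               families = paste(cl$members$family_label, collapse = ","),
               gaps_kb = paste(format(cl$gaps_kb, trim = TRUE), collapse = ","),
               arrangement = conserved_arrangement_check(cl),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
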