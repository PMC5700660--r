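#' Build a comparative gene-neighborhood map for a query
#'
#' The end-to-end pipeline: find every gene whose product carries the
#' queried COG or Pfam model, extract an orientation-normalized window of
#' \code{k} genes around each, order the windows (by target-protein
#' similarity via a multiple alignment, by taxonomy, or not at all),
#' compute the per-model occurrence percentage across the windows, and
#' assign colors to every model at or above the occurrence threshold.
#'
#' @param genomes list of \code{replicon} objects.
#' @param annotations a \code{protein_annotations} object.
#' @param query COG identifier or Pfam accession (string or
#'   \code{ng_query}).
#' @param k neighborhood size in genes (3 to 15).
#' @param threshold occurrence-percentage threshold (1 to 100).
#' @param sort \code{"taxonomy"}, \code{"msa"} or \code{"none"}.
#' @param clans optional Pfam clan table (named vector).
#' @param aligner alignment engine for \code{sort = "msa"}; see
#'   \code{\link{order_by_msa}}.
#' @param palette_seed deterministic palette rotation.
#' @return object of class \code{"neighborhood_map"}: \code{query},
#'   \code{targets}, \code{neighborhoods} (display order),
#'   \code{display_order}, \code{occurrence}, \code{colors},
#'   \code{descriptions}, plus the inputs needed by the writers.
#' @export
neighborhood_map <- function(genomes, annotations, query, k = 9L,
                             threshold = 1, sort = c("taxonomy", "msa",
                                                     "none"),
                             clans = NULL, aligner = mafft_aligner(),
                             palette_seed = 1L) {
  sort <- match.arg(sort)
  if (is.character(query)) query <- parse_query(query)
  targets <- find_targets(annotations, genomes, query)
  if (!nrow(targets)) stop("query ", query$accession,
                           " matches no annotated gene")
  nbs <- lapply(seq_len(nrow(targets)), function(i)
    extract_neighborhood(genomes[[targets$replicon_idx[i]]],
                         targets$gene_id[i], k))
  ord <- switch(sort,
    taxonomy = order_by_taxonomy(nbs),
    msa = {
      seqs <- vapply(seq_len(nrow(targets)), function(i) {
        rep <- genomes[[targets$replicon_idx[i]]]
        tr <- rep$genes$translation[match(targets$gene_id[i],
                                          rep$genes$gene_id)]
        if (is.na(tr)) "" else tr
      }, character(1))
      names(seqs) <- make.unique(targets$protein_id)
      order_by_msa(seqs, aligner)
    },
    none = structure(list(order = seq_along(nbs), mode = "NONE"),
                     class = "display_order"))
  occ <- occurrence(nbs, annotations)
  cmap <- colorize(occ, threshold, clans, palette_seed)
  descs <- model_descriptions(annotations)
  structure(list(query = query, targets = targets,
                 neighborhoods = nbs[ord$order], display_order = ord,
                 occurrence = occ, colors = cmap, descriptions = descs,
                 genomes = genomes, annotations = annotations,
                 k = k, threshold = threshold),
            class = "neighborhood_map")
}

## Model descriptions harvested from the hit tables (first non-NA wins).
model_descriptions <- function(annotations) {
  h <- annotations$hits
  h <- h[!is.na(h$model_desc), , drop = FALSE]
  h <- h[!duplicated(h$model_acc), , drop = FALSE]
  stats::setNames(h$model_desc, h$model_acc)
}

#' @export
print.neighborhood_map <- function(x, ...) {
  cat("<neighborhood_map> query ", x$query$accession, " (",
      x$query$kind, " mode)\n", sep = "")
  cat("  ", nrow(x$targets), " target gene(s) in ",
      length(unique(x$targets$replicon_id)), " replicon(s); k = ", x$k,
      ", threshold = ", x$threshold, "%\n", sep = "")
  cat("  occurrence (top):\n")
  top <- utils::head(x$occurrence, 8L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-10s %5.1f%%  (%d/%d)\n", top$model_acc[i],
                top$percent[i], top$n_present[i], top$n_total[i]))
  invisible(x)
}

#' @export
summary.neighborhood_map <- function(object, ...) {
  print(object)
  cat("  colored models:",
      paste(attr(object$colors, "colored"), collapse = ", "), "\n")
  invisible(object)
}

#' Write all pipeline outputs to a directory
#'
#' Emits the comparative figure (SVG and PDF), the per-gene neighborhood
#' table, the occurrence table, the legend, the per-hit annotation audit
#' table and the JSON annotation sidecar.
#'
#' @param nm a \code{neighborhood_map}.
#' @param dir output directory (created if needed).
#' @param scale pixels per kilobase for the figure.
#' @return named list of written paths.
#' @export
write_outputs <- function(nm, dir, scale = 40) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- figure_spec(nm$neighborhoods, NULL, nm$colors, nm$descriptions,
                      scale = scale)
  paths <- list(
    svg = file.path(dir, "neighborhoods.svg"),
    pdf = file.path(dir, "neighborhoods.pdf"),
    genes = file.path(dir, "neighborhoods.tsv"),
    occurrence = file.path(dir, "occurrence.tsv"),
    legend = file.path(dir, "legend.tsv"),
    hits = file.path(dir, "annotation_audit.tsv"),
    sidecar = file.path(dir, "annotations.json"))
  render_figure(spec, nm$annotations, paths$svg)
  render_pdf(spec, nm$annotations, paths$pdf)
  utils::write.table(neighborhood_table(nm), paths$genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(nm$occurrence), paths$occurrence,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_legend_tsv(nm$colors, nm$descriptions, paths$legend)
  write_annotation_table(nm$annotations, paths$hits)
  emit_annotations(nm$neighborhoods, nm$annotations, nm$genomes,
                   paths$sidecar)
  paths
}

#' Per-gene table of a neighborhood map
#'
#' One row per rendered gene: neighborhood index (display order), slot,
#' gene, its accepted models and whether any of them is colored.
#'
#' @param nm a \code{neighborhood_map}.
#' @return data frame.
#' @export
neighborhood_table <- function(nm) {
  colored <- attr(nm$colors, "colored")
  rows <- list()
  for (ni in seq_along(nm$neighborhoods)) {
    nb <- nm$neighborhoods[[ni]]
    for (s in seq_len(nrow(nb$genes))) {
      pid <- nb$genes$protein_id[s]
      models <- if (!is.na(pid)) accepted_models(nm$annotations, pid)
                else character()
      rows[[length(rows) + 1L]] <- data.frame(
        neighborhood = ni, slot = s, replicon = nb$replicon_id,
        gene_id = nb$genes$gene_id[s],
        is_target = nb$genes$is_target[s],
        rendered_dir = nb$genes$rendered_dir[s],
        length = nb$genes$length[s],
        models = paste(models, collapse = ","),
        colored = any(models %in% colored),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the pipeline on a dataset directory
#'
#' Convenience entry point matching the on-disk layout written by
#' \code{\link{make_dataset}} (and by any conforming preprocessing): a set
#' of GenBank files, per-kind HMM hit tables and an optional clan table.
#'
#' @param dir directory with \code{*.gbk} genomes, \code{cog_hits.domtbl},
#'   \code{pfam_hits.domtbl} and optionally \code{clans.tsv}.
#' @param query,k,threshold,sort,palette_seed passed to
#'   \code{\link{neighborhood_map}}.
#' @param min_score,min_len_frac,max_overlap_frac hit-filter settings, see
#'   \code{\link{annotate_proteins}}.
#' @param out optional output directory for \code{\link{write_outputs}}.
#' @return the \code{neighborhood_map}, invisibly when \code{out} is given.
#' @export
run_pipeline <- function(dir, query, k = 9L, threshold = 1,
                         sort = "taxonomy", palette_seed = 1L,
                         min_score = 25.0, min_len_frac = 0.25,
                         max_overlap_frac = 0.5, out = NULL) {
  ## list.files returns paths in sorted order already
  gbk <- list.files(dir, pattern = "\\.(gb|gbk|gbff)$", full.names = TRUE)
  genomes <- do.call(c, lapply(gbk, load_genbank))
  hits <- empty_hits()
  cogf <- file.path(dir, "cog_hits.domtbl")
  pfamf <- file.path(dir, "pfam_hits.domtbl")
  if (file.exists(cogf)) hits <- rbind(hits, parse_hit_table(cogf, "COG"))
  if (file.exists(pfamf)) hits <- rbind(hits, parse_hit_table(pfamf, "PFAM"))
  class(hits) <- c("domain_hits", "data.frame")
  ann <- annotate_proteins(hits, min_score, min_len_frac, max_overlap_frac)
  clansf <- file.path(dir, "clans.tsv")
  clans <- if (file.exists(clansf) && file.size(clansf) > 0)
    read_clan_table(clansf) else NULL
  nm <- neighborhood_map(genomes, ann, query, k, threshold, sort, clans,
                         palette_seed = palette_seed)
  if (!is.null(out)) {
    write_outputs(nm, out)
    return(invisible(nm))
  }
  nm
}
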