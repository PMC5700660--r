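#' Parse a neighborhood query
#'
#' A query is either a COG identifier (\code{COG} followed by four digits)
#' or a Pfam domain accession (\code{PF} followed by five digits).
#'
#' @param accession query string.
#' @return list of class \code{"ng_query"} with \code{kind} (\code{"COG"} or
#'   \code{"PFAM"}) and \code{accession}.
#' @export
parse_query <- function(accession) {
  if (grepl("^COG[0-9]{4}$", accession)) kind <- "COG"
  else if (grepl("^PF[0-9]{5}$", accession)) kind <- "PFAM"
  else stop("query must look like COG0001 or PF00001, got: ", accession)
  structure(list(kind = kind, accession = accession), class = "ng_query")
}

#' Find all target genes of a query
#'
#' In COG mode, every gene whose product was attributed to the queried COG;
#' in Pfam mode, every gene whose product contains at least one accepted hit
#' of the queried domain.  All paralogs are returned; there is no clustering
#' and no cap on the number of targets.  A protein carrying the queried
#' domain several times still yields its gene once.
#'
#' @param annotations a \code{protein_annotations} object.
#' @param genomes list of \code{replicon} objects.
#' @param query an \code{ng_query} or a query string.
#' @return data frame: \code{replicon_idx}, \code{replicon_id},
#'   \code{gene_id}, \code{protein_id}, \code{start}, \code{end},
#'   \code{strand}.
#' @export
find_targets <- function(annotations, genomes, query) {
  if (is.character(query)) query <- parse_query(query)
  rows <- list()
  for (ri in seq_along(genomes)) {
    rep <- genomes[[ri]]
    for (gi in seq_len(nrow(rep$genes))) {
      pid <- rep$genes$protein_id[gi]
      if (is.na(pid)) next
      if (query$accession %in% accepted_models(annotations, pid, query$kind)) {
        g <- rep$genes[gi, ]
        rows[[length(rows) + 1L]] <- data.frame(
          replicon_idx = ri, replicon_id = rep$replicon_id,
          gene_id = g$gene_id, protein_id = pid,
          start = g$start, end = g$end, strand = g$strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    warning("no gene annotated with ", query$accession)
    return(data.frame(replicon_idx = integer(), replicon_id = character(),
                      gene_id = character(), protein_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract an orientation-normalized gene neighborhood
#'
#' Takes a window of up to \code{k} genes centered on the target in
#' gene-order index space: \code{floor((k-1)/2)} genes on the rendered left
#' of the target and the rest on the rendered right (the extra gene of an
#' even \code{k} falls on the rendered right, i.e. downstream of the
#' target's coding direction).  The window truncates at the ends of a linear
#' replicon and wraps around the origin of a circular one.  When the target
#' lies on the reverse strand the whole window is mirrored so that the
#' target always points rightward in the rendered figure; every gene's
#' rendered direction is flipped accordingly.
#'
#' @param rep a \code{replicon}.
#' @param target_gene_id gene identifier of the target.
#' @param k neighborhood size in genes, including the target; must be
#'   between 3 and 15.
#' @return object of class \code{"gene_neighborhood"}: \code{replicon_id},
#'   \code{organism}, \code{taxonomy}, \code{topology}, \code{target_gene_id},
#'   \code{flipped}, \code{genes} (data frame in left-to-right rendered
#'   order, with \code{length} and \code{rendered_dir} columns and
#'   \code{is_target} flag) and \code{gaps} (data frame of the k-1
#'   intergenic segments between consecutive rendered genes: genomic
#'   \code{start}/\code{end} when a gap exists, and \code{length}, 0 for
#'   abutting or overlapping genes).
#' @export
extract_neighborhood <- function(rep, target_gene_id, k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 3L || k > 15L)
    stop("neighborhood size k must be an integer between 3 and 15")
  k <- as.integer(k)
  n <- nrow(rep$genes)
  i <- match(target_gene_id, rep$genes$gene_id)
  if (is.na(i)) stop("no such gene in replicon: ", target_gene_id)
  flipped <- rep$genes$strand[i] == "-"
  ## floor((k-1)/2) genes on the rendered left of the target, the rest on
  ## the rendered right; in genomic index space the two sides swap when the
  ## window is mirrored, which keeps extraction an exact involution under
  ## reverse-complementation of the replicon for every k
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  if (flipped) { tmp <- left; left <- right; right <- tmp }
  if (rep$topology == "circular" && n > 1L) {
    offs <- (-left):right
    idx <- ((i - 1L + offs) %% n) + 1L
    idx <- idx[!duplicated(idx)]
    ## when k >= n the window is the whole replicon, rotated
  } else {
    idx <- max(1L, i - left):min(n, i + right)
  }
  genes <- rep$genes[idx, , drop = FALSE]
  genes$length <- vapply(seq_len(nrow(genes)), function(r)
    gene_span(genes[r, ], rep), integer(1))
  genes$is_target <- genes$gene_id == target_gene_id
  ## gaps between consecutive genes in genomic window order
  gap_between <- function(a, b) {
    ## gap after gene a (row) before gene b, wrap-aware
    if (b$start < a$start && rep$topology == "circular") {
      ## wrap across the origin: a ends near the replicon end, b starts at 1
      len <- (rep$length - a$end) + (b$start - 1L)
      if (len > 0L)
        data.frame(start = a$end + 1L, end = b$start - 1L, length = len)
      else data.frame(start = NA_integer_, end = NA_integer_, length = 0L)
    } else if (b$start > a$end + 1L) {
      data.frame(start = a$end + 1L, end = b$start - 1L,
                 length = b$start - a$end - 1L)
    } else {
      data.frame(start = NA_integer_, end = NA_integer_, length = 0L)
    }
  }
  gaps <- if (nrow(genes) > 1L) {
    do.call(rbind, lapply(seq_len(nrow(genes) - 1L), function(r)
      gap_between(genes[r, ], genes[r + 1L, ])))
  } else {
    data.frame(start = integer(), end = integer(), length = integer())
  }
  if (flipped) {
    genes <- genes[rev(seq_len(nrow(genes))), , drop = FALSE]
    if (nrow(gaps)) gaps <- gaps[rev(seq_len(nrow(gaps))), , drop = FALSE]
  }
  genes$rendered_dir <- ifelse(xor(genes$strand == "-", flipped),
                               "left", "right")
  rownames(genes) <- rownames(gaps) <- NULL
  structure(list(replicon_id = rep$replicon_id, organism = rep$organism,
                 taxonomy = rep$taxonomy, topology = rep$topology,
                 target_gene_id = target_gene_id, flipped = flipped,
                 genes = genes, gaps = gaps, k = k),
            class = "gene_neighborhood")
}

#' @export
print.gene_neighborhood <- function(x, ...) {
  arrows <- ifelse(x$genes$rendered_dir == "right", "→", "←")
  lab <- ifelse(x$genes$is_target, paste0("[", x$genes$gene_id, arrows, "]"),
                paste0(x$genes$gene_id, arrows))
  cat("<gene_neighborhood> ", x$replicon_id, " (",
      if (x$flipped) "flipped" else "as-is", "): ",
      paste(lab, collapse = "  "), "\n", sep = "")
  invisible(x)
}

## Accepted models present on any gene of a neighborhood (presence set).
neighborhood_models <- function(nb, annotations) {
  pids <- nb$genes$protein_id[!is.na(nb$genes$protein_id)]
  unique(unlist(lapply(pids, function(p) accepted_models(annotations, p))))
}

#' Occurrence percentage of models across neighborhoods
#'
#' For every COG or Pfam model annotated on any gene of any neighborhood,
#' counts the number of neighborhoods that contain at least one gene with
#' that model (a model is counted at most once per neighborhood; the target
#' gene counts too) and expresses it as a percentage of all neighborhoods.
#'
#' @param neighborhoods list of \code{gene_neighborhood} objects (nonempty).
#' @param annotations a \code{protein_annotations} object.
#' @return data frame of class \code{"occurrence_table"}: \code{model_acc},
#'   \code{n_present}, \code{n_total}, \code{percent}, sorted by percent
#'   descending then accession.
#' @export
occurrence <- function(neighborhoods, annotations) {
  if (!length(neighborhoods)) stop("no neighborhoods")
  n_total <- length(neighborhoods)
  tallies <- table(unlist(lapply(neighborhoods, neighborhood_models,
                                 annotations = annotations)))
  out <- data.frame(model_acc = names(tallies),
                    n_present = as.integer(tallies),
                    n_total = n_total,
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$n_present / out$n_total
  out <- out[order(-out$percent, out$model_acc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrence_table", "data.frame")
  out
}

## Fixed qualitative palette; cycles with progressive darkening when more
## models are colored than the palette holds.
ng_palette <- c(
  "#E6194B", "#3CB44B", "#FFE119", "#4363D8", "#F58231", "#911EB4",
  "#46F0F0", "#F032E6", "#BCF60C", "#FABEBE", "#008080", "#E6BEFF",
  "#9A6324", "#FFFAC8", "#800000", "#AAFFC3", "#808075", "#FFD8B1",
  "#000075", "#2A9D8F"
)

darken_hex <- function(hex, factor) {
  m <- grDevices::col2rgb(hex) * factor
  grDevices::rgb(m[1, ] / 255, m[2, ] / 255, m[3, ] / 255)
}

#' Assign colors to models above an occurrence threshold
#'
#' Models whose occurrence percentage reaches the threshold get distinct
#' colors from a fixed qualitative palette; all Pfam domains sharing a Pfam
#' clan share one color (assigned when the first clan member is seen).
#' Models below the threshold map to neutral gray.  The assignment is
#' deterministic given the occurrence table, the clan table and the palette
#' seed: models are visited in order of decreasing percentage, ties broken
#' by accession; the seed rotates the palette starting point.
#'
#' @param occ an \code{occurrence_table}.
#' @param threshold occurrence-percentage threshold, between 1 and 100.
#' @param clans optional named vector (Pfam accession -> clan).
#' @param palette_seed integer; rotates the palette deterministically.
#' @param neutral color for models below threshold.
#' @return named character vector of class \code{"color_map"} (accession ->
#'   hex color), with attributes \code{threshold} and \code{colored}
#'   (accessions above threshold, in assignment order).
#' @export
colorize <- function(occ, threshold, clans = NULL, palette_seed = 1L,
                     neutral = "#C8C8C8") {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 1 || threshold > 100)
    stop("occurrence threshold must lie between 1 and 100")
  ord <- order(-occ$percent, occ$model_acc)
  occ <- occ[ord, , drop = FALSE]
  colored <- occ$model_acc[occ$percent >= threshold]
  pal <- ng_palette
  offset <- as.integer(palette_seed) %% length(pal)
  pal <- c(pal[(offset + 1L):length(pal)], pal[seq_len(offset)])
  cmap <- stats::setNames(rep(neutral, nrow(occ)), occ$model_acc)
  clan_color <- list()
  next_i <- 0L
  for (acc in colored) {
    clan <- if (!is.null(clans) && acc %in% names(clans)) clans[[acc]]
            else NA_character_
    if (!is.na(clan) && !is.null(clan_color[[clan]])) {
      cmap[[acc]] <- clan_color[[clan]]
      next
    }
    cycle <- next_i %/% length(pal)
    col <- pal[next_i %% length(pal) + 1L]
    if (cycle > 0L) col <- darken_hex(col, 0.75^cycle)
    next_i <- next_i + 1L
    cmap[[acc]] <- col
    if (!is.na(clan)) clan_color[[clan]] <- col
  }
  structure(cmap, class = "color_map", threshold = threshold,
            colored = colored)
}

#' @export
print.color_map <- function(x, ...) {
  colored <- attr(x, "colored")
  cat("<color_map> ", length(colored), " colored model(s) at threshold ",
      attr(x, "threshold"), "%\n", sep = "")
  for (acc in colored) cat("  ", acc, " ", x[[acc]], "\n", sep = "")
  invisible(x)
}
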