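#' Assemble a figure specification
#'
#' Collects everything the renderer needs: the neighborhoods in display
#' order, the color map, model descriptions for the legend, and the layout
#' constants.  Arrow and line lengths are proportional to gene and
#' intergenic lengths at \code{scale} pixels per kilobase.
#'
#' @param neighborhoods list of \code{gene_neighborhood} objects.
#' @param display_order optional \code{display_order}; defaults to input
#'   order.
#' @param colors a \code{color_map} from \code{\link{colorize}}.
#' @param descriptions optional named character vector, model accession ->
#'   description, used in the legend.
#' @param scale pixels per kilobase (default 40).
#' @param config layout constants: \code{row_height}, \code{arrow_height},
#'   \code{head_px} (arrow-head length), \code{label_width},
#'   \code{margin}, \code{max_gap_nt} (longer gaps are clipped and marked
#'   with a break glyph), \code{legend_row}.
#' @return object of class \code{"figure_spec"}.
#' @export
figure_spec <- function(neighborhoods, display_order = NULL, colors,
                        descriptions = NULL, scale = 40,
                        config = list()) {
  if (!length(neighborhoods)) stop("figure needs at least one neighborhood")
  defaults <- list(row_height = 30, arrow_height = 14, head_px = 8,
                   label_width = 190, margin = 16, max_gap_nt = 5000,
                   legend_row = 18)
  config <- utils::modifyList(defaults, config)
  ord <- if (is.null(display_order)) seq_along(neighborhoods)
         else display_order$order
  stopifnot(length(ord) == length(neighborhoods))
  structure(list(neighborhoods = neighborhoods, order = ord,
                 colors = colors, descriptions = descriptions,
                 scale = scale, config = config),
            class = "figure_spec")
}

## Color of one gene: the highest-ranked colored model on it, else neutral
## gray when it carries only sub-threshold models, else white (uncolored).
gene_fill <- function(models, colors) {
  if (!length(models)) return(list(fill = "#FFFFFF", model = NA_character_))
  colored <- attr(colors, "colored")
  hit <- colored[colored %in% models]
  if (length(hit)) return(list(fill = colors[[hit[1]]], model = hit[1]))
  known <- models[models %in% names(colors)]
  if (length(known)) return(list(fill = colors[[known[1]]],
                                 model = known[1]))
  list(fill = "#FFFFFF", model = NA_character_)
}

## Compute drawable geometry for the whole figure: per-gene arrow polygons,
## per-gap lines, row labels and legend entries, in final display order.
build_layout <- function(spec, annotations) {
  cf <- spec$config
  px_per_nt <- spec$scale / 1000
  nbs <- spec$neighborhoods[spec$order]
  rows <- list()
  for (r in seq_along(nbs)) {
    nb <- nbs[[r]]
    g <- nb$genes
    gw <- g$length * px_per_nt
    gaplen <- pmin(nb$gaps$length, cf$max_gap_nt)
    clipped <- nb$gaps$length > cf$max_gap_nt
    gapw <- gaplen * px_per_nt
    ti <- which(g$is_target)[1]
    pre <- if (ti > 1L) sum(gw[seq_len(ti - 1L)]) + sum(gapw[seq_len(ti - 1L)])
           else 0
    rows[[r]] <- list(nb = nb, gw = gw, gapw = gapw, clipped = clipped,
                      pre = pre)
  }
  maxpre <- max(vapply(rows, `[[`, numeric(1), "pre"))
  y0 <- cf$margin
  arrows <- list(); gaplines <- list(); labels <- list(); breaks <- list()
  for (r in seq_along(rows)) {
    rw <- rows[[r]]
    nb <- rw$nb
    ymid <- y0 + (r - 1) * cf$row_height + cf$row_height / 2
    x <- cf$label_width + cf$margin + (maxpre - rw$pre)
    tax2 <- paste(utils::head(nb$taxonomy, 2), collapse = "/")
    labels[[r]] <- list(x = cf$margin, y = ymid,
                        text = trimws(paste(tax2, nb$replicon_id)))
    g <- nb$genes
    for (s in seq_len(nrow(g))) {
      w <- rw$gw[s]
      models <- if (!is.na(g$protein_id[s]))
        accepted_models(annotations, g$protein_id[s]) else character()
      fill <- gene_fill(models, spec$colors)
      arrows[[length(arrows) + 1L]] <- list(
        row = r, slot = s, gene_id = g$gene_id[s], x = x, w = w,
        ymid = ymid, dir = g$rendered_dir[s], fill = fill$fill,
        model = fill$model, len_nt = g$length[s],
        is_target = g$is_target[s])
      x <- x + w
      if (s < nrow(g)) {
        gw2 <- rw$gapw[s]
        gaplines[[length(gaplines) + 1L]] <- list(
          row = r, slot = s, x = x, w = gw2, ymid = ymid,
          len_nt = nb$gaps$length[s], clipped = rw$clipped[s])
        if (rw$clipped[s])
          breaks[[length(breaks) + 1L]] <- list(x = x + gw2 / 2, y = ymid)
        x <- x + gw2
      }
    }
  }
  width <- max(vapply(arrows, function(a) a$x + a$w, numeric(1))) + cf$margin
  body_h <- y0 + length(rows) * cf$row_height
  colored <- attr(spec$colors, "colored")
  legend <- lapply(seq_along(colored), function(i) {
    acc <- colored[i]
    desc <- if (!is.null(spec$descriptions) && acc %in% names(spec$descriptions))
      spec$descriptions[[acc]] else ""
    list(x = cf$margin, y = body_h + cf$margin + (i - 1) * cf$legend_row,
         color = spec$colors[[acc]], acc = acc, desc = desc)
  })
  height <- body_h + cf$margin +
    length(legend) * cf$legend_row + cf$margin
  list(arrows = arrows, gaplines = gaplines, labels = labels,
       breaks = breaks, legend = legend,
       width = max(width, 300), height = height,
       arrow_height = cf$arrow_height, head_px = cf$head_px)
}

arrow_points <- function(a, hh, head_px) {
  y1 <- a$ymid - hh / 2; y2 <- a$ymid + hh / 2
  h <- min(head_px, a$w)
  if (a$dir == "right") {
    xs <- c(a$x, a$x + a$w - h, a$x + a$w, a$x + a$w - h, a$x)
    ys <- c(y1, y1, a$ymid, y2, y2)
  } else {
    xs <- c(a$x + a$w, a$x + h, a$x, a$x + h, a$x + a$w)
    ys <- c(y1, y1, a$ymid, y2, y2)
  }
  list(x = xs, y = ys)
}

fmt_px <- function(x) sprintf("%.2f", x)

#' Render the comparative neighborhood figure as SVG
#'
#' One row per neighborhood in display order; every gene is an arrow whose
#' length is proportional to the gene length and whose direction shows the
#' coding strand relative to the target (the target always points right);
#' intergenic regions are lines of proportional length; a legend beneath
#' the figure lists every colored model with its description.  Output is
#' byte-deterministic for identical inputs.
#'
#' @param spec a \code{figure_spec}.
#' @param annotations the \code{protein_annotations} used to color genes.
#' @param file optional path; when given the SVG is written there.
#' @return the SVG document as a single string (invisibly when written to
#'   file).
#' @export
render_figure <- function(spec, annotations, file = NULL) {
  lay <- build_layout(spec, annotations)
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" font-family="Helvetica" font-size="11">',
    fmt_px(lay$width), fmt_px(lay$height)))
  for (lb in lay$labels)
    out <- c(out, sprintf(
      '<text x="%s" y="%s" dominant-baseline="middle">%s</text>',
      fmt_px(lb$x), fmt_px(lb$y + 4), xml_escape(lb$text)))
  for (gl in lay$gaplines)
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#555555" stroke-width="1" data-row="%d" data-slot="%d" data-gap-len="%d"/>',
      fmt_px(gl$x), fmt_px(gl$ymid), fmt_px(gl$x + gl$w), fmt_px(gl$ymid),
      gl$row, gl$slot, gl$len_nt))
  for (br in lay$breaks)
    out <- c(out, sprintf(
      '<text x="%s" y="%s" text-anchor="middle">//</text>',
      fmt_px(br$x), fmt_px(br$y - 2)))
  for (a in lay$arrows) {
    p <- arrow_points(a, lay$arrow_height, lay$head_px)
    pts <- paste(paste(fmt_px(p$x), fmt_px(p$y), sep = ","), collapse = " ")
    out <- c(out, sprintf(
      '<polygon points="%s" fill="%s" stroke="#333333" stroke-width="1" data-row="%d" data-slot="%d" data-gene="%s" data-len="%d" data-dir="%s" data-model="%s" data-target="%s"/>',
      pts, a$fill, a$row, a$slot, xml_escape(a$gene_id), a$len_nt, a$dir,
      ifelse(is.na(a$model), "", a$model), tolower(a$is_target)))
  }
  for (le in lay$legend) {
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="12" height="12" fill="%s" stroke="#333333" data-legend="%s"/>',
      fmt_px(le$x), fmt_px(le$y), le$color, le$acc))
    out <- c(out, sprintf(
      '<text x="%s" y="%s">%s</text>',
      fmt_px(le$x + 18), fmt_px(le$y + 10),
      xml_escape(trimws(paste(le$acc, le$desc)))))
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export the neighborhood figure as PDF
#'
#' Draws the same geometry as \code{\link{render_figure}} on a PDF device.
#'
#' @inheritParams render_figure
#' @param file output PDF path.
#' @export
render_pdf <- function(spec, annotations, file) {
  lay <- build_layout(spec, annotations)
  grDevices::pdf(file, width = lay$width / 72, height = lay$height / 72)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, lay$width), ylim = c(lay$height, 0),
                        xaxs = "i", yaxs = "i")
  for (gl in lay$gaplines)
    graphics::segments(gl$x, gl$ymid, gl$x + gl$w, gl$ymid, col = "#555555")
  for (br in lay$breaks)
    graphics::text(br$x, br$y - 2, "//", cex = 0.7)
  for (a in lay$arrows) {
    p <- arrow_points(a, lay$arrow_height, lay$head_px)
    graphics::polygon(p$x, p$y, col = a$fill, border = "#333333")
  }
  for (lb in lay$labels)
    graphics::text(lb$x, lb$y, lb$text, adj = 0, cex = 0.7)
  for (le in lay$legend) {
    graphics::rect(le$x, le$y, le$x + 12, le$y + 12, col = le$color,
                   border = "#333333")
    graphics::text(le$x + 18, le$y + 8, trimws(paste(le$acc, le$desc)),
                   adj = 0, cex = 0.7)
  }
  invisible(file)
}

## Sequence of a genomic span on a replicon, wrap-aware.
span_sequence <- function(rep, start, end) {
  if (is.null(rep$sequence) || is.na(start)) return(NA_character_)
  if (start <= end) substr(rep$sequence, start, end)
  else paste0(substr(rep$sequence, start, rep$length),
              substr(rep$sequence, 1L, end))
}

#' Emit machine-readable annotation records for a figure
#'
#' One record per rendered gene and per intergenic region, keyed by
#' neighborhood index (in display order) and slot.  A gene record carries
#' the product description, optional external cross-references, genomic
#' coordinates, taxonomy, the accepted COG and Pfam hits verbatim
#' (coordinates, scores, E-values), and the protein and gene sequences when
#' available.  An intergenic record carries coordinates, taxonomy, the gap
#' sequence and its reverse complement.
#'
#' @param neighborhoods list of \code{gene_neighborhood} objects, already in
#'   display order.
#' @param annotations a \code{protein_annotations} object.
#' @param genomes list of \code{replicon} objects (for sequences).
#' @param file optional path for the JSON sidecar.
#' @param xrefs optional named vector protein_id -> external database id,
#'   passed through verbatim.
#' @return the records as a named list (invisibly when written to file).
#' @export
emit_annotations <- function(neighborhoods, annotations, genomes,
                             file = NULL, xrefs = NULL) {
  by_id <- stats::setNames(genomes,
                           vapply(genomes, `[[`, "", "replicon_id"))
  records <- list()
  hit_fields <- function(h) {
    if (!nrow(h)) return(list())
    lapply(seq_len(nrow(h)), function(i) list(
      model_acc = h$model_acc[i], ali_from = h$ali_from[i],
      ali_to = h$ali_to[i], score = h$score[i], evalue = h$evalue[i]))
  }
  for (ni in seq_along(neighborhoods)) {
    nb <- neighborhoods[[ni]]
    rep <- by_id[[nb$replicon_id]]
    g <- nb$genes
    for (s in seq_len(nrow(g))) {
      pid <- g$protein_id[s]
      ann <- if (!is.na(pid)) annotations$proteins[[pid]] else NULL
      rec <- list(
        type = "gene", gene_id = g$gene_id[s],
        description = g$product[s],
        xref = if (!is.null(xrefs) && !is.na(pid) && pid %in% names(xrefs))
          xrefs[[pid]] else NULL,
        coordinates = list(replicon = nb$replicon_id, start = g$start[s],
                           end = g$end[s], strand = g$strand[s]),
        taxonomy = as.list(nb$taxonomy),
        cog_hits = if (!is.null(ann)) hit_fields(ann$cogs) else list(),
        pfam_hits = if (!is.null(ann)) hit_fields(ann$pfam_architecture)
                    else list(),
        protein_sequence = if (!is.na(g$translation[s])) g$translation[s]
                           else NULL,
        gene_sequence = if (!is.null(rep) && !is.null(rep$sequence))
          gene_sequence(rep, g$gene_id[s]) else NULL)
      records[[sprintf("nb%d_gene%d", ni, s)]] <- rec
    }
    if (nrow(nb$gaps)) for (s in seq_len(nrow(nb$gaps))) {
      gp <- nb$gaps[s, ]
      if (gp$length == 0L) next
      seqs <- if (!is.null(rep)) span_sequence(rep, gp$start, gp$end)
              else NA_character_
      records[[sprintf("nb%d_gap%d", ni, s)]] <- list(
        type = "intergenic",
        coordinates = list(replicon = nb$replicon_id, start = gp$start,
                           end = gp$end),
        taxonomy = as.list(nb$taxonomy),
        sequence = if (is.na(seqs)) NULL else seqs,
        reverse_complement = if (is.na(seqs)) NULL else revcomp(seqs))
    }
  }
  if (!is.null(file)) {
    jsonlite::write_json(records, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(records))
  }
  records
}

#' Write the color legend as TSV
#' @param colors a \code{color_map}.
#' @param descriptions optional named vector of model descriptions.
#' @param path output path.
#' @export
write_legend_tsv <- function(colors, descriptions = NULL, path) {
  colored <- attr(colors, "colored")
  d <- data.frame(
    model_acc = colored,
    color = vapply(colored, function(a) colors[[a]], character(1)),
    description = vapply(colored, function(a)
      if (!is.null(descriptions) && a %in% names(descriptions))
        descriptions[[a]] else "", character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
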