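#' Construct a replicon
#'
#' A replicon is one chromosome or plasmid: an identifier, the organism it
#' comes from, its taxonomy lineage, its topology, its length, its protein
#' coding genes (sorted by coordinate) and optionally its nucleotide
#' sequence.  Coordinates are 1-based inclusive throughout.  A gene of a
#' circular replicon may span the origin; it is stored with
#' \code{start > end} and its length is \code{(length - start + 1) + end}.
#'
#' @param replicon_id identifier of the nucleotide record.
#' @param organism organism name.
#' @param taxonomy character vector, highest rank first.  The first two
#'   entries are the high-level taxonomy units shown next to each record.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param length replicon length in nucleotides.
#' @param genes data frame with columns \code{gene_id}, \code{start},
#'   \code{end}, \code{strand} (\code{"+"}/\code{"-"}), \code{protein_id}
#'   (NA for non-coding features), \code{product}, and optionally
#'   \code{translation}.
#' @param sequence optional nucleotide string of length \code{length}.
#' @return object of class \code{"replicon"}.
#' @export
replicon <- function(replicon_id, organism = NA_character_,
                     taxonomy = character(), topology = c("linear", "circular"),
                     length, genes, sequence = NULL) {
  topology <- match.arg(topology)
  length <- as.integer(length)
  genes <- as.data.frame(genes)
  need <- c("gene_id", "start", "end", "strand", "protein_id", "product")
  missing <- setdiff(need, names(genes))
  if (length(missing))
    stop("gene table lacks columns: ", paste(missing, collapse = ", "))
  if (!"translation" %in% names(genes)) genes$translation <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes)) {
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    wrapped <- genes$start > genes$end
    if (any(wrapped) && topology != "circular")
      stop("origin-spanning gene on a linear replicon")
    if (any(genes$start < 1L) || any(genes$end > length) ||
        any(genes$start > length))
      stop("gene coordinates outside [1, length]")
    pid <- genes$protein_id[!is.na(genes$protein_id)]
    if (anyDuplicated(pid))
      stop("duplicate protein_id within replicon")
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") disagrees with stated length (", length, ")")
  }
  structure(list(replicon_id = replicon_id, organism = organism,
                 taxonomy = as.character(taxonomy), topology = topology,
                 length = length, genes = genes, sequence = sequence),
            class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat("<replicon> ", x$replicon_id, " (", x$topology, ", ", x$length,
      " nt), ", nrow(x$genes), " genes, ", x$organism, "\n", sep = "")
  if (length(x$taxonomy))
    cat("  taxonomy:", paste(utils::head(x$taxonomy, 2), collapse = " / "), "\n")
  invisible(x)
}

#' Length of a gene, origin-wrap aware
#' @param gene one row of a replicon's gene table.
#' @param rep the replicon the gene belongs to.
#' @return gene length in nucleotides.
#' @export
gene_span <- function(gene, rep) {
  if (gene$start <= gene$end) gene$end - gene$start + 1L
  else (rep$length - gene$start + 1L) + gene$end
}

revcomp <- function(x) {
  if (!nchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Nucleotide sequence of a gene
#'
#' Extracts the gene's span from the replicon sequence, reverse-complemented
#' when the gene is on the reverse strand; origin-spanning genes of circular
#' replicons are stitched across the origin.
#'
#' @param rep a \code{replicon} carrying a sequence.
#' @param gene_id identifier of the gene.
#' @return nucleotide string.
#' @export
gene_sequence <- function(rep, gene_id) {
  if (is.null(rep$sequence)) stop("replicon carries no sequence")
  i <- match(gene_id, rep$genes$gene_id)
  if (is.na(i)) stop("no such gene: ", gene_id)
  g <- rep$genes[i, ]
  if (g$end > rep$length || g$start > rep$length)
    stop("gene extends beyond replicon end")
  s <- if (g$start <= g$end) substr(rep$sequence, g$start, g$end)
       else paste0(substr(rep$sequence, g$start, rep$length),
                   substr(rep$sequence, 1L, g$end))
  if (g$strand == "-") revcomp(s) else s
}

#' Look up a gene by the protein it encodes
#' @param genomes list of \code{replicon} objects.
#' @param protein_id protein identifier.
#' @return list with \code{replicon} and \code{gene} (one-row data frame),
#'   or NULL when absent.
#' @export
find_protein <- function(genomes, protein_id) {
  for (rep in genomes) {
    i <- match(protein_id, rep$genes$protein_id)
    if (!is.na(i)) return(list(replicon = rep, gene = rep$genes[i, ]))
  }
  NULL
}

#' Intergenic region between two adjacent genes
#'
#' The gap between gene \code{i} (end \code{e}) and gene \code{i+1}
#' (start \code{s}) exists iff \code{s > e + 1} and then covers
#' \code{[e+1, s-1]}.  Abutting or overlapping genes yield an empty region.
#' Both the gap sequence and its reverse complement are returned when the
#' replicon carries a sequence.
#'
#' @param rep a \code{replicon}.
#' @param left_gene_id,right_gene_id gene identifiers, adjacent in
#'   coordinate-sorted order (left before right).
#' @return list of class \code{"intergenic_region"}: \code{replicon_id},
#'   \code{start}, \code{end} (NA when empty), \code{length}, \code{empty},
#'   \code{flanking} (the two gene ids), \code{sequence}, \code{revcomp}.
#' @export
intergenic <- function(rep, left_gene_id, right_gene_id) {
  i <- match(left_gene_id, rep$genes$gene_id)
  j <- match(right_gene_id, rep$genes$gene_id)
  if (is.na(i) || is.na(j)) stop("no such gene")
  if (j != i + 1L) stop("genes are not adjacent in sorted order")
  e <- rep$genes$end[i]
  s <- rep$genes$start[j]
  if (s > e + 1L) {
    seqs <- if (!is.null(rep$sequence)) substr(rep$sequence, e + 1L, s - 1L)
            else NA_character_
    structure(list(replicon_id = rep$replicon_id, start = e + 1L,
                   end = s - 1L, length = s - e - 1L, empty = FALSE,
                   flanking = c(left_gene_id, right_gene_id),
                   sequence = seqs,
                   revcomp = if (is.na(seqs)) NA_character_ else revcomp(seqs)),
              class = "intergenic_region")
  } else {
    structure(list(replicon_id = rep$replicon_id, start = NA_integer_,
                   end = NA_integer_, length = 0L, empty = TRUE,
                   flanking = c(left_gene_id, right_gene_id),
                   sequence = NA_character_, revcomp = NA_character_),
              class = "intergenic_region")
  }
}

## ---- GenBank flat file reader -------------------------------------------

## Parses a location string of the forms a..b, complement(...), join(a..b,c..d).
## An origin-spanning join on a circular record is collapsed to start > end.
parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", parts))
    if (any(vapply(m, length, 1L) != 3L)) stop("unsupported location: ", loc)
    starts <- as.integer(vapply(m, `[`, "", 2L))
    ends <- as.integer(vapply(m, `[`, "", 3L))
    return(list(start = starts[1], end = ends[length(ends)], strand = strand))
  }
  m <- regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc)[[1]]
  mm <- regmatches(loc, list(m))[[1]]
  if (length(mm) != 3L) stop("unsupported location: ", loc)
  list(start = as.integer(mm[2]), end = as.integer(mm[3]), strand = strand)
}

read_genbank_record <- function(lines) {
  locus <- lines[1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  replicon_id <- toks[2]
  len <- as.integer(toks[3])
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  organism <- NA_character_
  taxonomy <- character()
  i_org <- grep("^  ORGANISM", lines)
  if (length(i_org)) {
    organism <- trimws(sub("^  ORGANISM", "", lines[i_org[1]]))
    j <- i_org[1] + 1L
    tax_lines <- character()
    while (j <= length(lines) && grepl("^\\s{4,}", lines[j]) &&
           !grepl("^FEATURES", lines[j])) {
      tax_lines <- c(tax_lines, trimws(lines[j]))
      j <- j + 1L
    }
    tax <- paste(tax_lines, collapse = " ")
    tax <- sub("\\.$", "", tax)
    if (nzchar(tax))
      taxonomy <- trimws(strsplit(tax, ";")[[1]])
  }
  ## features
  i_feat <- grep("^FEATURES", lines)
  i_orig <- grep("^ORIGIN", lines)
  genes <- list()
  if (length(i_feat)) {
    end_feat <- if (length(i_orig)) i_orig[1] - 1L else length(lines)
    flines <- lines[(i_feat[1] + 1L):end_feat]
    ## a new feature starts with exactly 5 spaces then a key
    starts <- grep("^ {5}\\S", flines)
    bounds <- c(starts, length(flines) + 1L)
    for (k in seq_along(starts)) {
      block <- flines[starts[k]:(bounds[k + 1L] - 1L)]
      key <- sub("^ {5}(\\S+).*", "\\1", block[1])
      if (key != "CDS") next
      loc <- sub("^ {5}\\S+\\s+", "", block[1])
      ## location may continue before the first qualifier
      qstart <- grep("^\\s+/", block)
      extra <- if (length(qstart)) {
        if (qstart[1] > 2L) paste(trimws(block[2:(qstart[1] - 1L)]), collapse = "")
        else ""
      } else if (length(block) > 1L) {
        paste(trimws(block[-1]), collapse = "")
      } else ""
      loc <- paste0(loc, extra)
      pos <- parse_gb_location(loc)
      quals <- parse_gb_qualifiers(block[qstart], if (length(qstart))
        block else character())
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = quals[["locus_tag"]] %||%
          quals[["protein_id"]] %||% paste0("feat", k),
        start = pos$start, end = pos$end, strand = pos$strand,
        protein_id = quals[["protein_id"]] %||% NA_character_,
        product = quals[["product"]] %||% NA_character_,
        translation = quals[["translation"]] %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes)
           else data.frame(gene_id = character(), start = integer(),
                           end = integer(), strand = character(),
                           protein_id = character(), product = character(),
                           translation = character(),
                           stringsAsFactors = FALSE)
  ## sequence
  seqs <- NULL
  if (length(i_orig)) {
    slines <- lines[(i_orig[1] + 1L):length(lines)]
    slines <- slines[!grepl("^//", slines)]
    seqs <- toupper(gsub("[^A-Za-z]", "", paste(slines, collapse = "")))
    if (!nchar(seqs)) seqs <- NULL
  }
  if (nrow(genes) && any(genes$end > len & genes$start <= genes$end))
    stop("feature end beyond stated sequence length in ", replicon_id)
  replicon(replicon_id, organism, taxonomy, topology, len, genes, seqs)
}

## Parse /key="value" qualifiers (values may span lines).
parse_gb_qualifiers <- function(qlines, block) {
  quals <- list()
  if (!length(block)) return(quals)
  qidx <- grep("^\\s+/", block)
  if (!length(qidx)) return(quals)
  bounds <- c(qidx, length(block) + 1L)
  for (k in seq_along(qidx)) {
    chunk <- block[qidx[k]:(bounds[k + 1L] - 1L)]
    text <- paste(trimws(chunk), collapse = if (grepl("/translation",
                                                      chunk[1])) "" else " ")
    m <- regexec("^/([A-Za-z_]+)=\"?([^\"]*)\"?$", text)[[1]]
    mm <- regmatches(text, list(m))[[1]]
    if (length(mm) == 3L) quals[[mm[2]]] <- mm[3]
  }
  quals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load annotated genomes
#'
#' Reads one or more replicons from either a GenBank flat file or a GFF3
#' file paired with a FASTA of the landmark sequences.  Coding-sequence
#' features become gene records; replicon topology is taken from the record
#' header (GenBank LOCUS line, or \code{Is_circular} on the GFF3 region
#' feature), defaulting to linear.
#'
#' @param path path to a GenBank flat file (\code{.gb}, \code{.gbk},
#'   \code{.gbff}) or a GFF3 file (\code{.gff}, \code{.gff3}).
#' @param fasta companion FASTA path, required for GFF3 input.
#' @return list of \code{replicon} objects.
#' @export
load_genome <- function(path, fasta = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gb", "gbk", "gbff", "genbank")) {
    load_genbank(path)
  } else if (ext %in% c("gff", "gff3")) {
    if (is.null(fasta)) stop("GFF3 input needs a companion FASTA")
    load_gff3(path, fasta)
  } else {
    stop("unrecognized genome format: ", path)
  }
}

#' @rdname load_genome
#' @export
load_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("not a GenBank flat file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k)
    read_genbank_record(lines[starts[k]:ends[k]]))
}

#' @rdname load_genome
#' @export
load_gff3 <- function(path, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (!length(seqs)) stop("empty FASTA: ", fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  out <- list()
  for (sid in unique(as.character(md$seqnames))) {
    if (!sid %in% names(seqs))
      stop("GFF3 landmark ", sid, " absent from FASTA")
    sub <- md[md$seqnames == sid, , drop = FALSE]
    reg <- sub[sub$type %in% c("region", "chromosome"), , drop = FALSE]
    topo <- "linear"
    organism <- NA_character_
    if (nrow(reg)) {
      if ("Is_circular" %in% names(reg) &&
          isTRUE(tolower(as.character(reg$Is_circular[1])) == "true"))
        topo <- "circular"
      if ("organism" %in% names(reg)) organism <- as.character(reg$organism[1])
    }
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    get_col <- function(d, col) {
      if (col %in% names(d)) as.character(d[[col]]) else rep(NA_character_, nrow(d))
    }
    genes <- data.frame(
      gene_id = {
        ids <- get_col(cds, "ID")
        ifelse(is.na(ids), paste0(sid, "_cds", seq_len(nrow(cds))), ids)
      },
      start = cds$start, end = cds$end,
      strand = ifelse(as.character(cds$strand) == "-", "-", "+"),
      protein_id = get_col(cds, "protein_id"),
      product = get_col(cds, "product"),
      translation = get_col(cds, "translation"),
      stringsAsFactors = FALSE)
    if (nrow(genes) && any(genes$end > nchar(as.character(seqs[[sid]]))))
      stop("feature end beyond sequence length for ", sid)
    out[[length(out) + 1L]] <- replicon(
      sid, organism, character(), topo,
      nchar(as.character(seqs[[sid]])), genes,
      as.character(seqs[[sid]]))
  }
  out
}

#' Write the gene table of a set of replicons as TSV
#' @param genomes list of \code{replicon} objects.
#' @param path output path.
#' @export
write_gene_table <- function(genomes, path) {
  rows <- lapply(genomes, function(rep) {
    if (!nrow(rep$genes)) return(NULL)
    data.frame(gene_id = rep$genes$gene_id, replicon = rep$replicon_id,
               start = rep$genes$start, end = rep$genes$end,
               strand = rep$genes$strand, protein_id = rep$genes$protein_id,
               product = rep$genes$product, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse-complement a whole replicon
#'
#' Flips all gene coordinates and strands and reverse-complements the
#' sequence; gene content is unchanged.  Mainly useful for checking that
#' neighborhood rendering is orientation-invariant.
#'
#' @param rep a \code{replicon}.
#' @return the mirrored \code{replicon}.
#' @export
revcomp_replicon <- function(rep) {
  g <- rep$genes
  if (nrow(g)) {
    new_start <- rep$length - g$end + 1L
    new_end <- rep$length - g$start + 1L
    wrapped <- g$start > g$end
    if (any(wrapped)) {
      new_start[wrapped] <- rep$length - g$end[wrapped] + 1L
      new_end[wrapped] <- rep$length - g$start[wrapped] + 1L
    }
    g$start <- new_start
    g$end <- new_end
    g$strand <- ifelse(g$strand == "+", "-", "+")
  }
  replicon(rep$replicon_id, rep$organism, rep$taxonomy, rep$topology,
           rep$length, g,
           if (!is.null(rep$sequence)) revcomp(rep$sequence) else NULL)
}
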