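#' Order neighborhoods by similarity of their target proteins
#'
#' Aligns the target amino-acid sequences with a pluggable alignment engine
#' and orders the neighborhoods by the position of their target in the
#' engine's output: multiple aligners emit sequences grouped by their guide
#' tree, so similar targets end up adjacent.  With a single sequence the
#' identity permutation is returned; if the engine fails the input order is
#' kept with a warning.
#'
#' @param target_seqs named character vector, neighborhood name -> protein
#'   sequence, in neighborhood input order.
#' @param aligner a function taking a named character vector of sequences
#'   and returning the aligned sequences, named, in the engine's output
#'   order (see \code{\link{mafft_aligner}}); defaults to the bundled
#'   MAFFT wrapper.
#' @return object of class \code{"display_order"}: list with \code{order}
#'   (permutation of input indices) and \code{mode = "MSA"}.
#' @export
order_by_msa <- function(target_seqs, aligner = mafft_aligner()) {
  stopifnot(length(target_seqs) >= 1L, !is.null(names(target_seqs)))
  if (length(target_seqs) == 1L)
    return(structure(list(order = 1L, mode = "MSA"),
                     class = "display_order"))
  perm <- tryCatch({
    out <- aligner(target_seqs)
    p <- match(names(out), names(target_seqs))
    if (anyNA(p) || length(p) != length(target_seqs) || anyDuplicated(p))
      stop("aligner did not return a permutation of the input sequences")
    p
  }, error = function(e) {
    warning("alignment engine failed (", conditionMessage(e),
            "); keeping input order")
    seq_along(target_seqs)
  })
  structure(list(order = perm, mode = "MSA"), class = "display_order")
}

#' MAFFT alignment engine
#'
#' Wraps the \command{mafft} executable behind the aligner contract used by
#' \code{\link{order_by_msa}}: FASTA in, aligned FASTA out, sequences
#' emitted in guide-tree order (\code{--reorder}) so that similar sequences
#' come out adjacent.  Two refinement iterations are requested by default.
#'
#' @param maxiterate number of refinement iterations passed to the engine.
#' @param exe executable name or path.
#' @return a function usable as the \code{aligner} argument of
#'   \code{\link{order_by_msa}}.
#' @export
mafft_aligner <- function(maxiterate = 2L, exe = "mafft") {
  force(maxiterate); force(exe)
  function(seqs) {
    if (Sys.which(exe) == "") stop("alignment engine not found: ", exe)
    fin <- tempfile(fileext = ".faa")
    on.exit(unlink(fin), add = TRUE)
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fin)
    out <- suppressWarnings(system2(
      exe, c("--maxiterate", maxiterate, "--reorder", "--quiet", "--auto",
             fin),
      stdout = TRUE, stderr = FALSE))
    if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
      stop("alignment engine exited with status ", attr(out, "status"))
    read_fasta_lines(out)
  }
}

## Minimal FASTA-from-lines reader (aligner output only).
read_fasta_lines <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no sequences in aligner output")
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), character(1))
  stats::setNames(seqs, sub("^>(\\S+).*", "\\1", lines[hdr]))
}

#' Order neighborhoods by taxonomy
#'
#' Lexicographic order on (taxonomy lineage, organism name, replicon id,
#' target gene start coordinate).  Several target genes of one organism end
#' up on consecutive rows, ordered along the replicon.  Neighborhoods with
#' no taxonomy sort last.
#'
#' @param neighborhoods list of \code{gene_neighborhood} objects.
#' @return object of class \code{"display_order"} with \code{order} and
#'   \code{mode = "TAXONOMY"}.
#' @export
order_by_taxonomy <- function(neighborhoods) {
  key <- vapply(neighborhoods, function(nb) {
    lin <- if (length(nb$taxonomy)) paste(nb$taxonomy, collapse = ";") else NA
    paste(lin, nb$organism, nb$replicon_id, sep = "\r")
  }, character(1))
  no_tax <- vapply(neighborhoods, function(nb) !length(nb$taxonomy),
                   logical(1))
  start <- vapply(neighborhoods, function(nb)
    nb$genes$start[nb$genes$is_target][1], integer(1))
  perm <- order(no_tax, key, start)
  structure(list(order = perm, mode = "TAXONOMY"), class = "display_order")
}

#' @export
print.display_order <- function(x, ...) {
  cat("<display_order> mode=", x$mode, ": ",
      paste(x$order, collapse = " "), "\n", sep = "")
  invisible(x)
}
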