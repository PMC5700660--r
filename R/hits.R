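#' Construct a table of profile-HMM domain hits
#'
#' A domain hit is one region of one protein whose similarity to a profile
#' HMM (a COG profile or a Pfam domain model) is non-random.  Hits are kept
#' as a plain data frame with one row per hit; this constructor validates
#' the column set and the coordinate invariants.
#'
#' @param protein_id character; opaque protein identifiers.
#' @param model_acc character; COG identifiers (e.g. \code{"COG0001"}) or
#'   Pfam accessions (e.g. \code{"PF00001"}).
#' @param model_kind \code{"COG"} or \code{"PFAM"} (recycled).
#' @param model_len integer; length of the profile HMM in match columns.
#' @param ali_from,ali_to 1-based inclusive alignment coordinates on the
#'   protein, \code{ali_from <= ali_to}.
#' @param score bit score of the hit.
#' @param evalue E-value of the hit (non-negative).
#' @param model_desc optional free-text model description.
#' @return A \code{data.frame} of class \code{"domain_hits"}.
#' @export
domain_hits <- function(protein_id, model_acc, model_kind, model_len,
                        ali_from, ali_to, score, evalue,
                        model_desc = NA_character_) {
  h <- data.frame(
    protein_id = as.character(protein_id),
    model_acc = as.character(model_acc),
    model_kind = as.character(model_kind),
    model_len = as.integer(model_len),
    ali_from = as.integer(ali_from),
    ali_to = as.integer(ali_to),
    score = as.numeric(score),
    evalue = as.numeric(evalue),
    model_desc = as.character(model_desc),
    stringsAsFactors = FALSE
  )
  validate_hits(h)
  class(h) <- c("domain_hits", "data.frame")
  h
}

empty_hits <- function() {
  domain_hits(character(), character(), character(), integer(),
              integer(), integer(), numeric(), numeric(), character())
}

validate_hits <- function(h) {
  stopifnot(is.data.frame(h))
  need <- c("protein_id", "model_acc", "model_kind", "model_len",
            "ali_from", "ali_to", "score", "evalue")
  missing <- setdiff(need, names(h))
  if (length(missing))
    stop("hit table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(h) == 0) return(invisible(h))
  if (!all(h$model_kind %in% c("COG", "PFAM")))
    stop("model_kind must be 'COG' or 'PFAM'")
  if (any(h$ali_from < 1L))
    stop("ali_from must be >= 1")
  if (any(h$ali_to < h$ali_from))
    stop("ali_to must be >= ali_from")
  if (any(h$model_len < 1L))
    stop("model_len must be >= 1")
  if (any(h$evalue < 0))
    stop("evalue must be non-negative")
  invisible(h)
}

hit_length <- function(h) h$ali_to - h$ali_from + 1L

#' Parse per-domain tabular output of an HMM search
#'
#' Reads the whitespace-delimited per-domain table written by profile-HMM
#' search tools (the common 22-column \code{--domtblout} layout: target
#' model, model accession, model length, query protein, per-domain score and
#' E-value, alignment coordinates, trailing description).  Comment lines
#' starting with \code{#} are skipped.  Column positions can be overridden
#' for variant layouts.
#'
#' @param path path to the table.
#' @param model_kind \code{"COG"} or \code{"PFAM"}; stamped on every hit.
#' @param columns named integer vector mapping the fields
#'   \code{protein_id}, \code{model_name}, \code{model_acc}, \code{model_len},
#'   \code{ali_from}, \code{ali_to}, \code{score}, \code{evalue} to 1-based
#'   column indices.  Defaults match the standard per-domain layout
#'   (per-domain independent E-value and per-domain bit score).
#' @return A \code{domain_hits} data frame in file order.
#' @export
parse_hit_table <- function(path, model_kind,
                            columns = c(protein_id = 4L, model_name = 1L,
                                        model_acc = 2L, model_len = 3L,
                                        ali_from = 18L, ali_to = 19L,
                                        score = 14L, evalue = 13L)) {
  if (!model_kind %in% c("COG", "PFAM"))
    stop("unknown model_kind: ", model_kind)
  if (!file.exists(path)) stop("no such hit table: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_hits())
  maxcol <- max(columns)
  parse_one <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < maxcol)
      stop("malformed hit table line ", i, ": expected >= ", maxcol,
           " columns, found ", length(f))
    acc <- f[columns[["model_acc"]]]
    if (acc == "-") acc <- f[columns[["model_name"]]]
    from <- suppressWarnings(as.integer(f[columns[["ali_from"]]]))
    to <- suppressWarnings(as.integer(f[columns[["ali_to"]]]))
    len <- suppressWarnings(as.integer(f[columns[["model_len"]]]))
    sc <- suppressWarnings(as.numeric(f[columns[["score"]]]))
    ev <- suppressWarnings(as.numeric(f[columns[["evalue"]]]))
    if (anyNA(c(from, to, len, sc, ev)))
      stop("malformed hit table line ", i, ": non-numeric field")
    if (is.na(from) || is.na(to) || from < 1L || to < from)
      stop("malformed hit table line ", i, ": bad alignment coordinates ",
           from, "..", to)
    desc <- if (length(f) > 22L) paste(f[23:length(f)], collapse = " ")
            else NA_character_
    list(protein_id = f[columns[["protein_id"]]], model_acc = acc,
         model_len = len, ali_from = from, ali_to = to,
         score = sc, evalue = ev, model_desc = desc)
  }
  rows <- lapply(idx, parse_one)
  g <- function(k) sapply(rows, `[[`, k)
  domain_hits(g("protein_id"), g("model_acc"), model_kind, g("model_len"),
              g("ali_from"), g("ali_to"), g("score"), g("evalue"),
              g("model_desc"))
}

#' Read a Pfam clan membership table
#'
#' Two-column tab-separated file: Pfam accession, clan accession.  Domains
#' absent from the table belong to no clan.
#'
#' @param path path to the TSV.
#' @return named character vector, accession -> clan.
#' @export
read_clan_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("accession", "clan"),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(d$accession))
    stop("clan table maps an accession to more than one clan")
  stats::setNames(d$clan, d$accession)
}

#' Discard insignificant profile-HMM hits
#'
#' A hit is discarded if its bit score is less than \code{min_score} or if
#' its aligned length is less than \code{min_len_frac} of the profile HMM
#' length.  Both comparisons are strict, so a hit at exactly the score
#' threshold or at exactly the length fraction is retained.
#'
#' @param hits a \code{domain_hits} data frame.
#' @param min_score minimum bit score (default 25.0 bits).
#' @param min_len_frac minimum hit length as a fraction of the model length
#'   (default 0.25).
#' @return the surviving hits, input order preserved.
#' @export
filter_significant <- function(hits, min_score = 25.0, min_len_frac = 0.25) {
  validate_hits(hits)
  if (nrow(hits) == 0) return(hits)
  keep <- hits$score >= min_score &
    hit_length(hits) >= min_len_frac * hits$model_len
  hits[keep, , drop = FALSE]
}

## Shared residues between two closed intervals; 0 when disjoint.
overlap_len <- function(from1, to1, from2, to2) {
  pmax(0L, pmin(to1, to2) - pmax(from1, from2) + 1L)
}

## Priority order of hits for overlap resolution: higher score first; ties
## broken by normalized length (hit length / model length, compared with a
## small tolerance), then raw hit length, then model accession, then input
## order.  The first three criteria are the resolution cascade; the last two
## make the order total and deterministic.
hit_priority_order <- function(h, tol = 1e-9) {
  norm_q <- round((hit_length(h) / h$model_len) / tol)
  order(-h$score, -norm_q, -hit_length(h), h$model_acc, seq_len(nrow(h)))
}

#' Resolve overlapping hits into a consistent architecture
#'
#' Overlapping hits on one protein are resolved by a greedy cascade: hits
#' are visited in decreasing priority (bit score; ties by length normalized
#' on the profile HMM length; further ties by raw length) and accepted
#' unless an already-accepted hit covers more than \code{max_overlap_frac}
#' of the candidate's length.  A hit rejected earlier never suppresses a
#' later hit.
#'
#' @param hits a \code{domain_hits} data frame for a single protein and a
#'   single model kind, already passed through \code{\link{filter_significant}}.
#' @param max_overlap_frac fraction of the lower-priority hit's length above
#'   which the overlap is disqualifying (default 0.5, strict).
#' @param tol equality tolerance for the normalized-length comparison.
#' @return accepted hits, sorted by \code{ali_from} (ties by \code{ali_to},
#'   then accession).
#' @export
resolve_overlaps <- function(hits, max_overlap_frac = 0.5, tol = 1e-9) {
  validate_hits(hits)
  if (nrow(hits) <= 1L) return(hits)
  if (length(unique(hits$protein_id)) != 1L)
    stop("resolve_overlaps: hits from more than one protein")
  if (length(unique(hits$model_kind)) != 1L)
    stop("resolve_overlaps: hits of more than one model kind")
  ord <- hit_priority_order(hits, tol)
  accepted <- integer()
  for (i in ord) {
    veto <- FALSE
    for (a in accepted) {
      shared <- overlap_len(hits$ali_from[a], hits$ali_to[a],
                            hits$ali_from[i], hits$ali_to[i])
      if (shared > max_overlap_frac * (hits$ali_to[i] - hits$ali_from[i] + 1L)) {
        veto <- TRUE
        break
      }
    }
    if (!veto) accepted <- c(accepted, i)
  }
  out <- hits[accepted, , drop = FALSE]
  out <- out[order(out$ali_from, out$ali_to, out$model_acc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate one protein with COG memberships and a Pfam architecture
#'
#' COG and Pfam hits are filtered and overlap-resolved independently: a COG
#' hit never suppresses a Pfam hit.  Non-overlapping membership in several
#' COGs is retained.
#'
#' @param cog_hits,pfam_hits \code{domain_hits} for one protein (either may
#'   be empty).
#' @param min_score,min_len_frac,max_overlap_frac see
#'   \code{\link{filter_significant}} and \code{\link{resolve_overlaps}}.
#' @return object of class \code{"protein_annotation"}: a list with
#'   \code{protein_id}, \code{cogs} (accepted COG hits), \code{pfam_architecture}
#'   (accepted Pfam hits ordered along the protein) and \code{unannotated}.
#' @export
annotate_protein <- function(cog_hits = empty_hits(),
                             pfam_hits = empty_hits(),
                             min_score = 25.0, min_len_frac = 0.25,
                             max_overlap_frac = 0.5) {
  ids <- unique(c(cog_hits$protein_id, pfam_hits$protein_id))
  if (length(ids) > 1L) stop("hits from more than one protein")
  cogs <- resolve_overlaps(filter_significant(cog_hits, min_score, min_len_frac),
                           max_overlap_frac)
  arch <- resolve_overlaps(filter_significant(pfam_hits, min_score, min_len_frac),
                           max_overlap_frac)
  structure(list(
    protein_id = if (length(ids)) ids else NA_character_,
    cogs = cogs,
    pfam_architecture = arch,
    unannotated = nrow(cogs) == 0L && nrow(arch) == 0L
  ), class = "protein_annotation")
}

#' Annotate a set of proteins from raw hit tables
#'
#' Applies the significance filters and the overlap-resolution cascade to
#' every protein in the input, keeping a per-hit audit trail of why each
#' raw hit was accepted or rejected.
#'
#' @param hits a \code{domain_hits} data frame mixing proteins and both
#'   model kinds (e.g. the concatenation of a COG and a Pfam hit table).
#' @inheritParams annotate_protein
#' @return object of class \code{"protein_annotations"}: list with
#'   \code{proteins} (named list of \code{protein_annotation}),
#'   \code{hits} (the input plus \code{accepted} and \code{reason} columns;
#'   reason one of \code{accepted}, \code{low_score}, \code{short_hit},
#'   \code{overlap}) and \code{params}.
#' @export
annotate_proteins <- function(hits, min_score = 25.0, min_len_frac = 0.25,
                              max_overlap_frac = 0.5) {
  validate_hits(hits)
  audit <- as.data.frame(hits)
  audit$accepted <- FALSE
  audit$reason <- "accepted"
  low <- audit$score < min_score
  short <- hit_length(audit) < min_len_frac * audit$model_len
  audit$reason[short] <- "short_hit"
  audit$reason[low] <- "low_score"  # score check reported first
  proteins <- list()
  if (nrow(hits)) {
    for (pid in unique(hits$protein_id)) {
      sel_c <- hits$protein_id == pid & hits$model_kind == "COG"
      sel_p <- hits$protein_id == pid & hits$model_kind == "PFAM"
      ann <- annotate_protein(hits[sel_c, , drop = FALSE],
                              hits[sel_p, , drop = FALSE],
                              min_score, min_len_frac, max_overlap_frac)
      proteins[[pid]] <- ann
      acc <- rbind(as.data.frame(ann$cogs), as.data.frame(ann$pfam_architecture))
      ok <- which((sel_c | sel_p))
      for (i in ok) {
        hit_in <- audit[i, ]
        if (hit_in$reason != "accepted") next
        m <- acc$model_acc == hit_in$model_acc &
          acc$ali_from == hit_in$ali_from & acc$ali_to == hit_in$ali_to &
          acc$score == hit_in$score & acc$model_kind == hit_in$model_kind
        if (any(m)) audit$accepted[i] <- TRUE
        else audit$reason[i] <- "overlap"
      }
    }
  }
  structure(list(
    proteins = proteins,
    hits = audit,
    params = list(min_score = min_score, min_len_frac = min_len_frac,
                  max_overlap_frac = max_overlap_frac)
  ), class = "protein_annotations")
}

#' @export
print.protein_annotation <- function(x, ...) {
  cat("<protein_annotation>", x$protein_id, "\n")
  cat("  COGs:", if (nrow(x$cogs)) paste(x$cogs$model_acc, collapse = ", ")
                 else "(none)", "\n")
  cat("  Pfam architecture:",
      if (nrow(x$pfam_architecture))
        paste(x$pfam_architecture$model_acc, collapse = " - ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
print.protein_annotations <- function(x, ...) {
  n <- length(x$proteins)
  un <- sum(vapply(x$proteins, `[[`, logical(1), "unannotated"))
  cat("<protein_annotations> ", n, " proteins (", n - un, " annotated, ",
      un, " unannotated), ", nrow(x$hits), " raw hits (",
      sum(x$hits$accepted), " accepted)\n", sep = "")
  invisible(x)
}

## Accepted model accessions for one protein (both kinds), or a specific kind.
accepted_models <- function(annotations, protein_id, kind = NULL) {
  ann <- annotations$proteins[[protein_id]]
  if (is.null(ann)) return(character())
  out <- character()
  if (is.null(kind) || kind == "COG") out <- c(out, ann$cogs$model_acc)
  if (is.null(kind) || kind == "PFAM") out <- c(out, ann$pfam_architecture$model_acc)
  unique(out)
}

#' Write the per-protein annotation audit table
#'
#' One row per raw hit: protein, model kind and accession, alignment
#' coordinates, score, E-value, whether the hit was accepted, and the
#' rejection reason otherwise.
#'
#' @param annotations a \code{protein_annotations} object.
#' @param path output TSV path.
#' @export
write_annotation_table <- function(annotations, path) {
  h <- annotations$hits
  out <- h[, c("protein_id", "model_kind", "model_acc", "ali_from", "ali_to",
               "score", "evalue", "accepted", "reason")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
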