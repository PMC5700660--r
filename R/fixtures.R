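#' Configuration for the synthetic-genome generator
#'
#' The generator emulates the inputs of the pipeline: annotated prokaryotic
#' replicons, per-domain HMM-search hit tables and a Pfam clan table, with
#' a conserved operon planted in a known subset of genomes.  The target
#' model gene is present in every genome; the companion genes of the operon
#' template accompany it in exactly \code{k_planted} genomes, so the true
#' occurrence percentage of every companion is
#' \code{100 * k_planted / (n_genomes * paralogs)}.
#'
#' @param n_genomes number of genomes (one replicon each).
#' @param genes_per_genome genes per replicon, operon included.
#' @param k_planted number of genomes carrying the full operon.
#' @param operon template: data frame with \code{model_acc},
#'   \code{model_kind} and \code{rel_strand} (strand of each member
#'   relative to the first, which is the target).
#' @param paralogs copies of the target gene per genome (extra copies come
#'   without companions).
#' @param circular_frac fraction of replicons that are circular.
#' @param gene_len_range nucleotide length range for genes (rounded to
#'   codons).
#' @param gap_range intergenic gap length range (nucleotides, may be 0).
#' @param decoys also emit sub-threshold, short and overlapping decoy hits
#'   that must be rejected by the filters.
#' @param clans named vector Pfam accession -> clan, written as the clan
#'   table.
#' @param seed integer seed fixing all randomness.
#' @return list of class \code{"fixture_config"}.
#' @export
fixture_config <- function(n_genomes = 10L, genes_per_genome = 12L,
                           k_planted = 4L,
                           operon = data.frame(
                             model_acc = c("COG1009", "COG3002"),
                             model_kind = c("COG", "COG"),
                             rel_strand = c("+", "+"),
                             stringsAsFactors = FALSE),
                           paralogs = 1L, circular_frac = 0.5,
                           gene_len_range = c(300L, 2400L),
                           gap_range = c(0L, 300L), decoys = TRUE,
                           clans = NULL, seed = 1L) {
  stopifnot(k_planted <= n_genomes, nrow(operon) >= 1L, paralogs >= 1L)
  if (nrow(operon) + (paralogs - 1L) > genes_per_genome)
    stop("infeasible config: operon and paralogs do not fit in a genome")
  structure(list(n_genomes = as.integer(n_genomes),
                 genes_per_genome = as.integer(genes_per_genome),
                 k_planted = as.integer(k_planted), operon = operon,
                 paralogs = as.integer(paralogs),
                 circular_frac = circular_frac,
                 gene_len_range = as.integer(gene_len_range),
                 gap_range = as.integer(gap_range), decoys = decoys,
                 clans = clans, seed = as.integer(seed)),
            class = "fixture_config")
}

rand_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

fake_phyla <- c("Proteobacteria", "Firmicutes", "Actinobacteria",
                "Bacteroidetes", "Cyanobacteria", "Spirochaetes")

#' Generate a synthetic dataset with a planted operon
#'
#' Builds \code{n_genomes} replicons with random gene lengths and gaps.
#' Every genome carries the target-model gene; in \code{k_planted} genomes
#' the full operon template is planted contiguously at a random locus on a
#' random strand (reverse-strand planting mirrors the member order so the
#' transcription-direction layout is conserved).  Hit tables contain one
#' strong hit per planted gene plus, optionally, decoy hits that the
#' significance and overlap filters must reject.  A truth record states
#' every planted fact.
#'
#' @param cfg a \code{\link{fixture_config}}.
#' @param dir optional output directory; when given, GenBank files, a
#'   protein FASTA, per-kind hit tables, the clan table and the truth
#'   record (YAML) are written there.
#' @return list with \code{genomes} (replicons), \code{hits}
#'   (\code{domain_hits}), \code{clans}, \code{truth} and \code{files}.
#' @export
make_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  oplen <- nrow(cfg$operon)
  target_model <- cfg$operon$model_acc[1]
  target_kind <- cfg$operon$model_kind[1]
  planted <- sort(sample(cfg$n_genomes, cfg$k_planted))
  genomes <- vector("list", cfg$n_genomes)
  hit_rows <- list()
  truth_loci <- list()
  add_hit <- function(pid, acc, kind, mlen, from, to, score, evalue,
                      desc = NA_character_) {
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      protein_id = pid, model_acc = acc, model_kind = kind,
      model_len = mlen, ali_from = from, ali_to = to, score = score,
      evalue = evalue, model_desc = desc, stringsAsFactors = FALSE)
  }
  for (g in seq_len(cfg$n_genomes)) {
    rid <- sprintf("SYNREP%03d", g)
    organism <- sprintf("Synthetica organismus %03d", g)
    taxonomy <- c("Bacteria", fake_phyla[(g - 1L) %% length(fake_phyla) + 1L],
                  sprintf("Synthoclass%02d", (g - 1L) %% 4L + 1L))
    topo <- if (stats::runif(1) < cfg$circular_frac) "circular" else "linear"
    is_planted <- g %in% planted
    ng <- cfg$genes_per_genome
    ## choose roles for each gene slot
    span <- if (is_planted) oplen else 1L
    p <- sample(ng - span + 1L, 1L)
    extra <- integer()
    if (cfg$paralogs > 1L) {
      free <- setdiff(seq_len(ng), p:(p + span - 1L))
      extra <- sort(sample(free, cfg$paralogs - 1L))
    }
    op_strand <- sample(c("+", "-"), 1L)
    member_of <- rep(NA_integer_, ng)  # index into operon template
    if (is_planted) {
      idx <- seq_len(oplen)
      if (op_strand == "-") idx <- rev(idx)
      member_of[p:(p + oplen - 1L)] <- idx
    } else {
      member_of[p] <- 1L
    }
    ## build coordinates
    pos <- 0L
    rows <- list()
    for (j in seq_len(ng)) {
      gap <- sample(cfg$gap_range[1]:cfg$gap_range[2], 1L)
      len <- 3L * sample((cfg$gene_len_range[1] %/% 3L):
                           (cfg$gene_len_range[2] %/% 3L), 1L)
      start <- pos + gap + 1L
      end <- start + len - 1L
      pos <- end
      pid <- sprintf("%s_p%02d", rid, j)
      mi <- member_of[j]
      is_extra <- j %in% extra
      strand <- if (!is.na(mi)) {
        rs <- cfg$operon$rel_strand[mi]
        if (rs == "+") op_strand else setdiff(c("+", "-"), op_strand)
      } else if (is_extra) {
        sample(c("+", "-"), 1L)
      } else sample(c("+", "-"), 1L)
      prot_len <- len %/% 3L - 1L
      product <- if (!is.na(mi))
        sprintf("%s family protein", cfg$operon$model_acc[mi])
      else if (is_extra) sprintf("%s family protein", target_model)
      else "hypothetical protein"
      rows[[j]] <- data.frame(
        gene_id = sprintf("%s_g%02d", rid, j), start = start, end = end,
        strand = strand, protein_id = pid, product = product,
        translation = rand_aa(prot_len), stringsAsFactors = FALSE)
      ## hits
      model_for <- function(acc, kind) {
        mlen <- max(30L, as.integer(round(prot_len * 0.9)))
        from <- 3L
        to <- min(prot_len, from + as.integer(round(mlen * 0.95)))
        add_hit(pid, acc, kind, mlen, from, to,
                round(stats::runif(1, 80, 200), 1),
                signif(10^-stats::runif(1, 20, 60), 3),
                sprintf("%s family protein", acc))
        c(from, to)
      }
      if (!is.na(mi)) {
        acc <- cfg$operon$model_acc[mi]
        kind <- cfg$operon$model_kind[mi]
        ali <- model_for(acc, kind)
        if (cfg$decoys && mi == 1L) {
          ## overlapping lower-scored decoy fully inside the real hit
          add_hit(pid, "COG9903", kind, 200L, ali[1] + 2L,
                  max(ali[1] + 12L, ali[2] - 2L), 40.0, 1e-5,
                  "overlap decoy")
        }
      } else if (is_extra) {
        model_for(target_model, target_kind)
      } else if (cfg$decoys) {
        pick <- stats::runif(1)
        if (pick < 0.45) {
          add_hit(pid, "COG9901", "COG", 100L, 1L,
                  min(prot_len, 60L), 24.9, 0.01, "low-score decoy")
        } else if (pick < 0.9) {
          add_hit(pid, "COG9902", "COG", 100L, 1L, 24L, 150.0, 1e-20,
                  "short decoy")
        } ## else: no hit at all
      }
    }
    genes <- do.call(rbind, rows)
    rep_len <- pos + sample(cfg$gap_range[1]:cfg$gap_range[2], 1L) + 1L
    genomes[[g]] <- replicon(rid, organism, taxonomy, topo, rep_len,
                             genes, rand_dna(rep_len))
    truth_loci[[rid]] <- list(
      planted = is_planted, position = p, strand = op_strand,
      target_gene = sprintf("%s_g%02d", rid, p +
        if (is_planted && op_strand == "-") oplen - 1L else 0L),
      paralog_slots = as.integer(extra))
  }
  hits <- do.call(rbind, hit_rows)
  class(hits) <- c("domain_hits", "data.frame")
  validate_hits(hits)
  companions <- cfg$operon$model_acc[-1]
  n_neigh <- cfg$n_genomes * cfg$paralogs
  truth <- list(
    seed = cfg$seed, n_genomes = cfg$n_genomes, k_planted = cfg$k_planted,
    planted_replicons = sprintf("SYNREP%03d", planted),
    target_model = target_model, companions = companions,
    expected_occurrence = c(
      stats::setNames(rep(100, 1), target_model),
      stats::setNames(rep(100 * cfg$k_planted / n_neigh,
                          length(companions)), companions)),
    n_neighborhoods = n_neigh, loci = truth_loci)
  files <- NULL
  if (!is.null(dir)) files <- write_dataset(genomes, hits, cfg, truth, dir)
  list(genomes = genomes, hits = hits, clans = cfg$clans, truth = truth,
       config = cfg, files = files)
}

## ---- file emission -------------------------------------------------------

format_genbank <- function(rep) {
  out <- c(sprintf("LOCUS       %-16s %11d bp    DNA     %-8s BCT 01-JAN-2026",
                   rep$replicon_id, rep$length, rep$topology),
           sprintf("DEFINITION  %s synthetic replicon.", rep$organism),
           sprintf("SOURCE      %s", rep$organism),
           sprintf("  ORGANISM  %s", rep$organism),
           sprintf("            %s.", paste(rep$taxonomy, collapse = "; ")),
           "FEATURES             Location/Qualifiers")
  wrap60 <- function(x) substring(x, seq(1, nchar(x), 48),
                                  pmin(nchar(x), seq(48, nchar(x) + 47, 48)))
  for (i in seq_len(nrow(rep$genes))) {
    g <- rep$genes[i, ]
    loc <- sprintf("%d..%d", g$start, g$end)
    if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     CDS             %s", loc),
             sprintf("                     /locus_tag=\"%s\"", g$gene_id),
             sprintf("                     /protein_id=\"%s\"", g$protein_id),
             sprintf("                     /product=\"%s\"", g$product))
    tr <- wrap60(g$translation)
    tr[1] <- sprintf("/translation=\"%s", tr[1])
    tr[length(tr)] <- paste0(tr[length(tr)], "\"")
    out <- c(out, paste0("                     ", tr))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(rep$sequence)
  for (off in seq(1, nchar(s), 60)) {
    chunk <- substr(s, off, min(nchar(s), off + 59))
    grp <- substring(chunk, seq(1, nchar(chunk), 10),
                     pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    out <- c(out, sprintf("%9d %s", off, paste(grp, collapse = " ")))
  }
  c(out, "//")
}

format_domtbl <- function(h) {
  c("#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
    vapply(seq_len(nrow(h)), function(i) {
      sprintf("%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
              h$model_acc[i], h$model_acc[i], h$model_len[i],
              h$protein_id[i], "-", h$ali_to[i] + 10L, h$evalue[i],
              h$score[i], 0.0, 1L, 1L, h$evalue[i], h$evalue[i],
              h$score[i], 0.0, 1L, h$model_len[i], h$ali_from[i],
              h$ali_to[i], h$ali_from[i], h$ali_to[i], 0.95,
              ifelse(is.na(h$model_desc[i]), "-", h$model_desc[i]))
    }, character(1)))
}

write_dataset <- function(genomes, hits, cfg, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(genomes = character())
  for (rep in genomes) {
    f <- file.path(dir, paste0(tolower(rep$replicon_id), ".gbk"))
    writeLines(format_genbank(rep), f)
    files$genomes <- c(files$genomes, f)
  }
  prot <- do.call(rbind, lapply(genomes, function(r) r$genes))
  files$proteins <- file.path(dir, "proteins.faa")
  writeLines(paste0(">", prot$protein_id, "\n", prot$translation),
             files$proteins)
  for (kind in c("COG", "PFAM")) {
    sub <- hits[hits$model_kind == kind, , drop = FALSE]
    f <- file.path(dir, sprintf("%s_hits.domtbl", tolower(kind)))
    writeLines(format_domtbl(sub), f)
    files[[paste0(tolower(kind), "_hits")]] <- f
  }
  files$clans <- file.path(dir, "clans.tsv")
  if (!is.null(cfg$clans)) {
    utils::write.table(
      data.frame(accession = names(cfg$clans), clan = unname(cfg$clans)),
      files$clans, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  } else {
    writeLines(character(), files$clans)
  }
  files$truth <- file.path(dir, "truth.yaml")
  yaml::write_yaml(truth, files$truth)
  files
}
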