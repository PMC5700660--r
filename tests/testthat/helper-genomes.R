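## Hand-built tiny replicon: genes specified as start, end, strand triples.
tiny_replicon <- function(coords, sequence = NULL, topology = "linear",
                          id = "REP1", organism = "Testus organismus",
                          taxonomy = c("Bacteria", "Testphyla"),
                          length = NULL, products = NULL) {
  n <- length(coords)
  g <- do.call(rbind, lapply(seq_len(n), function(i) {
    x <- coords[[i]]
    data.frame(gene_id = paste0("g", i), start = x[[1]], end = x[[2]],
               strand = x[[3]], protein_id = paste0("p", i),
               product = if (is.null(products)) paste0("product ", i)
                         else products[i],
               translation = NA_character_, stringsAsFactors = FALSE)
  }))
  if (is.null(length))
    length <- max(c(g$start, g$end)) + 10L
  replicon(id, organism, taxonomy, topology, length, g, sequence)
}

## Annotations assigning one strong accepted hit per protein_id -> model.
stub_annotations <- function(models, kind = "COG") {
  n <- length(models)
  h <- domain_hits(protein_id = names(models), model_acc = unname(models),
                   model_kind = kind, model_len = 100L, ali_from = 1L,
                   ali_to = 100L, score = 100, evalue = 1e-20)
  annotate_proteins(h)
}

## Deterministic fake alignment engines for the ordering contract.
fake_aligner_reversed <- function(seqs) rev(seqs)
fake_aligner_failing <- function(seqs) stop("engine exploded")
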