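## Independent brute-force oracle for overlap resolution.
##
## A hit is accepted iff no accepted hit of higher priority covers more
## than half of its length.  Priority applies the printed rule cascade
## pairwise: higher bit score wins; at equal score the greater length
## normalized on the model length wins; then the greater raw length; the
## remaining ties fall back to accession and input position.  Computed by
## memoized recursion over each hit (no greedy accumulation loop).
oracle_resolve <- function(hits, max_overlap_frac = 0.5, tol = 1e-9) {
  n <- nrow(hits)
  if (n <= 1L) return(hits)
  len <- hits$ali_to - hits$ali_from + 1L
  norm <- len / hits$model_len
  ## TRUE when hit a outranks hit b under the pairwise cascade
  outranks <- function(a, b) {
    if (hits$score[a] != hits$score[b]) return(hits$score[a] > hits$score[b])
    if (abs(norm[a] - norm[b]) > tol) return(norm[a] > norm[b])
    if (len[a] != len[b]) return(len[a] > len[b])
    if (hits$model_acc[a] != hits$model_acc[b])
      return(hits$model_acc[a] < hits$model_acc[b])
    a < b
  }
  shared <- function(a, b) {
    max(0L, min(hits$ali_to[a], hits$ali_to[b]) -
          max(hits$ali_from[a], hits$ali_from[b]) + 1L)
  }
  status <- rep(NA, n)
  accepted <- function(i) {
    if (!is.na(status[i])) return(status[i])
    ok <- TRUE
    for (j in seq_len(n)) {
      if (j == i || !outranks(j, i)) next
      if (accepted(j) && shared(j, i) > max_overlap_frac * len[i]) {
        ok <- FALSE
        break
      }
    }
    status[i] <<- ok
    ok
  }
  keep <- vapply(seq_len(n), accepted, logical(1))
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$ali_from, out$ali_to, out$model_acc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Random resolution instance: up to max_n hits on one protein, with
## deliberately frequent score ties and heavy overlap.  Accessions are
## unique per hit so the tie-break key is total.
random_hit_instance <- function(max_n = 8L) {
  n <- sample(1:max_n, 1L)
  from <- sample(1:120, n, replace = TRUE)
  len <- sample(5:80, n, replace = TRUE)
  domain_hits(
    protein_id = "P1",
    model_acc = sprintf("COG%04d", sample(9999, n)),
    model_kind = "COG",
    model_len = sample(20:120, n, replace = TRUE),
    ali_from = from, ali_to = from + len - 1L,
    score = sample(c(25, 30, 40, 40, 50, 50, 50, 75.5, 100), n,
                   replace = TRUE),
    evalue = signif(10^-stats::runif(n, 3, 40), 3)
  )
}

## Convenience single-protein hit builder for hand-written cases.
mk_hits <- function(from, to, score, model_len, acc = NULL, kind = "COG") {
  n <- length(from)
  if (is.null(acc)) acc <- sprintf("COG%04d", seq_len(n))
  domain_hits(protein_id = "P1", model_acc = acc, model_kind = kind,
              model_len = model_len, ali_from = from, ali_to = to,
              score = score, evalue = 1e-10)
}
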