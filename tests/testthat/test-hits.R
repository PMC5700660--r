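test_that("hit tables parse from per-domain tabular output", {
  f <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(c(
    "# comment line",
    paste("COG0001              COG0001      320 PROT1                -",
          "  350   1.2e-50  180.0   0.1   1   2   2.2e-40   1.1e-38  120.5",
          "  0.0     1   300     11   280    10   285 0.95 some protein"),
    paste("COG0002              COG0002      150 PROT1                -",
          "  350   1.2e-10   40.0   0.1   2   2   2.2e-08   1.1e-06   38.5",
          "  0.0     1   140     300   340   298   344 0.90 other protein")
  ), f)
  h <- parse_hit_table(f, "COG")
  expect_s3_class(h, "domain_hits")
  expect_equal(nrow(h), 2L)
  expect_equal(h$protein_id, c("PROT1", "PROT1"))   # file order preserved
  expect_equal(h$model_acc, c("COG0001", "COG0002"))
  expect_equal(h$ali_from, c(11L, 300L))
  expect_equal(h$ali_to, c(280L, 340L))
  expect_equal(h$score, c(120.5, 38.5))
  expect_equal(h$evalue, c(1.1e-38, 1.1e-06))
  expect_equal(h$model_desc[1], "some protein")
})

test_that("empty and malformed hit tables are handled", {
  f <- withr::local_tempfile(fileext = ".domtbl")
  writeLines("# only a comment", f)
  expect_equal(nrow(parse_hit_table(f, "COG")), 0L)

  writeLines("COG0001 COG0001 notanumber", f)
  expect_error(parse_hit_table(f, "COG"), "line 1")

  ## coordinates reversed on the data line
  writeLines(paste("COG0001 COG0001 320 PROT1 - 350 1e-50 180 0.1 1 1",
                   "1e-40 1e-38 120.5 0.0 1 300 280 11 10 285 0.95"), f)
  expect_error(parse_hit_table(f, "COG"), "coordinates")

  expect_error(parse_hit_table(f, "BLAST"), "model_kind")
})

test_that("significance filter applies strict score and length cutoffs", {
  h <- mk_hits(from = c(1, 1, 1, 1), to = c(50, 25, 24, 24),
               score = c(24.9, 25.0, 300.0, 300.0),
               model_len = c(100, 100, 100, 96))
  out <- filter_significant(h)
  ## 24.9 bits removed; 25.0 bits at exactly 25% kept; 24/100 = 24% removed;
  ## 24/96 = 25% kept
  expect_equal(out$model_acc, c("COG0002", "COG0004"))
  expect_equal(nrow(filter_significant(h[0, ])), 0L)
})

test_that("significance filter is idempotent", {
  set.seed(11)
  for (i in 1:25) {
    h <- random_hit_instance()
    once <- filter_significant(h)
    expect_identical(filter_significant(once), once)
  }
})

test_that("overlap resolution follows the printed rule cascade", {
  ## >50% of the lower-scored hit covered -> dropped
  h <- mk_hits(c(1, 30), c(100, 90), score = c(100, 40),
               model_len = c(100, 100))
  expect_equal(resolve_overlaps(h)$model_acc, "COG0001")

  ## 11/111 residues ~ 9.9% of the lower-scored hit -> both kept
  h <- mk_hits(c(1, 90), c(100, 200), score = c(100, 40),
               model_len = c(100, 100))
  expect_equal(resolve_overlaps(h)$model_acc, c("COG0001", "COG0002"))

  ## equal score: greater normalized length wins
  h <- mk_hits(c(1, 1), c(80, 80), score = c(50, 50),
               model_len = c(100, 200))
  expect_equal(resolve_overlaps(h)$model_acc, "COG0001")

  ## equal score and normalized length: the longer hit wins
  h <- mk_hits(c(1, 21), c(80, 60), score = c(50, 50),
               model_len = c(100, 50))
  expect_equal(resolve_overlaps(h)$model_acc, "COG0001")

  ## non-overlapping hits are never suppressed
  h <- mk_hits(c(1, 200), c(100, 260), score = c(100, 30),
               model_len = c(100, 80))
  expect_equal(nrow(resolve_overlaps(h)), 2L)

  ## mixed proteins refused
  h <- mk_hits(c(1, 10), c(50, 60), c(50, 40), c(100, 100))
  h$protein_id <- c("P1", "P2")
  expect_error(resolve_overlaps(h), "more than one protein")
})

test_that("a rejected hit cannot veto later hits", {
  ## A beats B; B overlaps C entirely but was itself rejected, and A
  ## overlaps C by under half, so C survives
  h <- mk_hits(from = c(1, 40, 96), to = c(100, 110, 160),
               score = c(100, 60, 30), model_len = c(100, 100, 100))
  out <- resolve_overlaps(h)
  expect_setequal(out$model_acc, c("COG0001", "COG0003"))
})

test_that("greedy resolver agrees with the brute-force oracle", {
  set.seed(4217)
  for (i in 1:1000) {
    h <- random_hit_instance()
    expect_identical(resolve_overlaps(h), oracle_resolve(h),
                     info = paste("instance", i))
  }
})

test_that("resolver output never contains a forbidden overlap pair", {
  ## no surviving lower-scored hit may have more than half of its own
  ## length covered by a surviving higher-scored hit
  set.seed(99)
  for (i in 1:200) {
    out <- resolve_overlaps(random_hit_instance())
    if (nrow(out) < 2L) next
    len <- out$ali_to - out$ali_from + 1L
    for (a in seq_len(nrow(out) - 1L)) for (b in (a + 1L):nrow(out)) {
      if (out$score[a] == out$score[b]) next
      shared <- max(0L, min(out$ali_to[a], out$ali_to[b]) -
                      max(out$ali_from[a], out$ali_from[b]) + 1L)
      lower <- if (out$score[a] < out$score[b]) a else b
      expect_lte(shared, 0.5 * len[lower])
    }
  }
})

test_that("resolution is invariant under permutation of the input", {
  set.seed(31)
  for (i in 1:100) {
    h <- random_hit_instance()
    base <- resolve_overlaps(h)
    perm <- h[sample(nrow(h)), , drop = FALSE]
    rownames(perm) <- NULL
    expect_identical(resolve_overlaps(perm), base)
  }
})

test_that("proteins keep non-overlapping multi-COG membership", {
  cog <- mk_hits(c(1, 200), c(100, 300), score = c(80, 60),
                 model_len = c(100, 110), acc = c("COG0007", "COG0008"))
  ann <- annotate_protein(cog_hits = cog)
  expect_equal(sort(ann$cogs$model_acc), c("COG0007", "COG0008"))
  expect_false(ann$unannotated)

  none <- annotate_protein()
  expect_true(none$unannotated)
})

test_that("COG and Pfam hits are resolved independently", {
  cog <- mk_hits(1, 100, 100, 100, acc = "COG0001")
  pfam <- mk_hits(1, 100, 30, 100, acc = "PF00010", kind = "PFAM")
  ann <- annotate_protein(cog_hits = cog, pfam_hits = pfam)
  ## the stronger COG hit does not suppress the fully-overlapped Pfam hit
  expect_equal(ann$cogs$model_acc, "COG0001")
  expect_equal(ann$pfam_architecture$model_acc, "PF00010")
})

test_that("pfam architecture is ordered along the protein", {
  pfam <- mk_hits(c(200, 1, 90), c(300, 80, 170), score = c(60, 50, 40),
                  model_len = c(100, 90, 85),
                  acc = c("PF00003", "PF00001", "PF00002"), kind = "PFAM")
  ann <- annotate_protein(pfam_hits = pfam)
  expect_equal(ann$pfam_architecture$model_acc,
               c("PF00001", "PF00002", "PF00003"))
})

test_that("the audit table records every rejection reason", {
  h <- rbind(
    mk_hits(1, 60, 24.9, 100, acc = "COG0001"),     # low score
    mk_hits(1, 20, 100, 100, acc = "COG0002"),      # short hit
    mk_hits(1, 100, 100, 100, acc = "COG0003"),     # accepted
    mk_hits(10, 90, 50, 100, acc = "COG0004"))      # lost to COG0003
  class(h) <- c("domain_hits", "data.frame")
  ann <- annotate_proteins(h)
  expect_equal(ann$hits$reason,
               c("low_score", "short_hit", "accepted", "overlap"))
  expect_equal(ann$hits$accepted, c(FALSE, FALSE, TRUE, FALSE))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("protein_id", "model_kind", "model_acc", "ali_from",
                      "ali_to", "score", "evalue", "accepted", "reason"))
})

test_that("clan tables reject duplicate accessions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("PF00001\tCL0001", "PF00002\tCL0001"), f)
  cl <- read_clan_table(f)
  expect_equal(unname(cl[c("PF00001", "PF00002")]), c("CL0001", "CL0001"))
  writeLines(c("PF00001\tCL0001", "PF00001\tCL0002"), f)
  expect_error(read_clan_table(f), "more than one clan")
})
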