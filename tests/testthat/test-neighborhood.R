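test_that("queries are recognized as COG or Pfam", {
  expect_equal(parse_query("COG0001")$kind, "COG")
  expect_equal(parse_query("PF00001")$kind, "PFAM")
  expect_error(parse_query("COG1"), "COG0001")
  expect_error(parse_query("PF001"), "COG0001")
})

test_that("target finding returns every paralog and never caps", {
  rep <- tiny_replicon(list(list(1L, 300L, "+"), list(400L, 700L, "+"),
                            list(800L, 1100L, "-")))
  ann <- stub_annotations(c(p1 = "COG0005", p2 = "COG0005", p3 = "COG0009"))
  tg <- find_targets(ann, list(rep), "COG0005")
  expect_equal(tg$gene_id, c("g1", "g2"))  # both paralogs, no clustering

  expect_warning(t0 <- find_targets(ann, list(rep), "COG9999"),
                 "no gene annotated")
  expect_equal(nrow(t0), 0L)
})

test_that("a repeated domain still yields its gene once", {
  rep <- tiny_replicon(list(list(1L, 300L, "+")))
  h <- domain_hits(protein_id = c("p1", "p1"), model_acc = "PF00007",
                   model_kind = "PFAM", model_len = 50L,
                   ali_from = c(1L, 61L), ali_to = c(50L, 110L),
                   score = 80, evalue = 1e-12)
  ann <- annotate_proteins(h)
  tg <- find_targets(ann, list(rep), "PF00007")
  expect_equal(nrow(tg), 1L)
})

test_that("target count scales with the number of qualifying genes", {
  ## no cap: 30 paralogs across genomes are all returned
  reps <- lapply(1:10, function(i) {
    tiny_replicon(list(list(1L, 300L, "+"), list(400L, 700L, "+"),
                       list(800L, 1100L, "+")),
                  id = paste0("R", i))
  })
  pids <- paste0("p", 1:3)
  anns <- list()
  for (i in 1:10) for (p in pids)
    anns[[paste0("R", i, p)]] <- "COG0042"
  ## rebuild replicons with globally unique protein ids
  reps <- lapply(1:10, function(i) {
    r <- reps[[i]]
    r$genes$protein_id <- paste0("R", i, pids)
    r
  })
  ann <- stub_annotations(unlist(anns))
  tg <- find_targets(ann, reps, "COG0042")
  expect_equal(nrow(tg), 30L)
})

test_that("window extraction centers, truncates and validates k", {
  coords <- lapply(seq(1, by = 400, length.out = 5),
                   function(s) list(s, s + 300L, "+"))
  rep <- tiny_replicon(coords)

  nb <- extract_neighborhood(rep, "g3", 3L)
  expect_equal(nb$genes$gene_id, c("g2", "g3", "g4"))
  expect_false(nb$flipped)
  expect_equal(nb$genes$rendered_dir, rep("right", 3))

  ## k larger than the replicon truncates without error
  nb15 <- extract_neighborhood(rep, "g2", 15L)
  expect_equal(nb15$genes$gene_id, paste0("g", 1:5))

  expect_error(extract_neighborhood(rep, "g3", 2L), "between 3 and 15")
  expect_error(extract_neighborhood(rep, "g3", 16L), "between 3 and 15")
  expect_error(extract_neighborhood(rep, "g3", NA), "between 3 and 15")
})

test_that("reverse-strand targets mirror the window", {
  coords <- list(list(1L, 300L, "+"), list(400L, 700L, "-"),
                 list(800L, 1100L, "+"))
  rep <- tiny_replicon(coords)
  nb <- extract_neighborhood(rep, "g2", 3L)
  expect_true(nb$flipped)
  expect_equal(nb$genes$gene_id, c("g3", "g2", "g1"))
  ## the target always points right; flanks flip with the window
  expect_equal(nb$genes$rendered_dir[nb$genes$is_target], "right")
  expect_equal(nb$genes$rendered_dir, c("left", "right", "left"))
  ## gap lengths are preserved under mirroring (99 between g2,g3 first)
  expect_equal(nb$gaps$length, c(99L, 99L))
})

test_that("windows wrap on circular replicons only", {
  coords <- lapply(seq(1, by = 400, length.out = 5),
                   function(s) list(s, s + 300L, "+"))
  circ <- tiny_replicon(coords, topology = "circular", length = 2200L)
  lin <- tiny_replicon(coords, length = 2200L)

  nbc <- extract_neighborhood(circ, "g1", 3L)
  expect_equal(nbc$genes$gene_id, c("g5", "g1", "g2"))
  ## the wrap gap spans the origin: from the end of g5 to the start of g1
  expect_equal(nbc$gaps$length[1], (2200L - 1901L) + (1L - 1L))

  nbl <- extract_neighborhood(lin, "g1", 3L)
  expect_equal(nbl$genes$gene_id, c("g1", "g2"))
})

test_that("even k puts the extra gene downstream of the target", {
  coords <- lapply(seq(1, by = 400, length.out = 6),
                   function(s) list(s, s + 300L, "+"))
  rep <- tiny_replicon(coords)
  nb4 <- extract_neighborhood(rep, "g3", 4L)
  expect_equal(nb4$genes$gene_id, c("g2", "g3", "g4", "g5"))

  revc <- lapply(coords, function(x) list(x[[1]], x[[2]], "-"))
  repr <- tiny_replicon(revc)
  nb4r <- extract_neighborhood(repr, "g3", 4L)
  ## mirrored: one gene on the rendered left, two on the rendered right
  expect_equal(nb4r$genes$gene_id, c("g4", "g3", "g2", "g1"))
})

test_that("occurrence counts presence per neighborhood", {
  reps <- lapply(1:10, function(i)
    tiny_replicon(list(list(1L, 300L, "+"), list(400L, 700L, "+")),
                  id = paste0("R", i)))
  models <- character()
  for (i in 1:10) {
    models[paste0("R", i, "t")] <- "COG0001"
    ## companion model in 2 of 10 neighborhoods
    models[paste0("R", i, "n")] <- if (i <= 2) "COG0002" else
      sprintf("COG09%02d", i)
  }
  reps <- lapply(1:10, function(i) {
    r <- reps[[i]]
    r$genes$protein_id <- paste0("R", i, c("t", "n"))
    r
  })
  ann <- stub_annotations(models)
  nbs <- lapply(reps, extract_neighborhood, target_gene_id = "g1", k = 3L)
  occ <- occurrence(nbs, ann)
  expect_equal(occ$percent[occ$model_acc == "COG0001"], 100)
  expect_equal(occ$percent[occ$model_acc == "COG0002"], 20)
  expect_equal(occ$n_total, rep(10L, nrow(occ)))
  expect_error(occurrence(list(), ann), "no neighborhoods")
})

test_that("a model repeated inside one neighborhood counts once", {
  rep <- tiny_replicon(list(list(1L, 300L, "+"), list(400L, 700L, "+"),
                            list(800L, 1100L, "+")))
  ann <- stub_annotations(c(p1 = "COG0008", p2 = "COG0008", p3 = "COG0008"))
  nb <- extract_neighborhood(rep, "g2", 3L)
  occ <- occurrence(list(nb), ann)
  expect_equal(occ$n_present[occ$model_acc == "COG0008"], 1L)
  expect_equal(occ$percent, 100)
})

test_that("color assignment respects threshold, clans and determinism", {
  occ <- structure(data.frame(
    model_acc = c("COG0001", "PF00001", "PF00002", "COG0777"),
    n_present = c(10L, 6L, 5L, 1L), n_total = 10L,
    percent = c(100, 60, 50, 10), stringsAsFactors = FALSE),
    class = c("occurrence_table", "data.frame"))
  clans <- c(PF00001 = "CL0001", PF00002 = "CL0001")

  cm <- colorize(occ, threshold = 50, clans = clans, palette_seed = 1)
  expect_setequal(attr(cm, "colored"), c("COG0001", "PF00001", "PF00002"))
  ## clan members share one color
  expect_equal(cm[["PF00001"]], cm[["PF00002"]])
  expect_false(cm[["COG0001"]] == cm[["PF00001"]])
  ## below threshold -> neutral gray
  expect_equal(cm[["COG0777"]], "#C8C8C8")

  ## identical call, identical map
  expect_identical(colorize(occ, 50, clans, 1), cm)

  ## threshold 100 colors only the ubiquitous model
  cm100 <- colorize(occ, 100, clans, 1)
  expect_equal(attr(cm100, "colored"), "COG0001")

  ## threshold 1 colors everything present
  cm1 <- colorize(occ, 1, clans, 1)
  expect_setequal(attr(cm1, "colored"), occ$model_acc)

  expect_error(colorize(occ, 0.5), "between 1 and 100")
  expect_error(colorize(occ, 101), "between 1 and 100")
})

test_that("raising the threshold never adds a colored model", {
  set.seed(77)
  cfg <- fixture_config(n_genomes = 8, k_planted = 5, seed = 77)
  ds <- make_dataset(cfg)
  ann <- annotate_proteins(ds$hits)
  nbs <- lapply(find_targets(ann, ds$genomes, "COG1009")$gene_id,
                function(gid) {
                  loc <- find_protein(ds$genomes, sub("_g", "_p", gid))
                  extract_neighborhood(loc$replicon, gid, 5L)
                })
  occ <- occurrence(nbs, ann)
  prev <- NULL
  for (th in c(1, 20, 40, 60, 80, 100)) {
    cur <- attr(colorize(occ, th), "colored")
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})
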