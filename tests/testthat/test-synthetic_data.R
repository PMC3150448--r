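test_that("generation is byte-identical for a fixed seed", {
  spec <- synthetic_locus_spec(n_orphans = 2, seed = 42)
  s1 <- generate_locus(spec); s2 <- generate_locus(spec)
  expect_identical(s1$sequence$seq, s2$sequence$seq)
  expect_identical(s1$truth$modules, s2$truth$modules)
  s3 <- generate_locus(synthetic_locus_spec(n_orphans = 2, seed = 43))
  expect_false(identical(s1$sequence$seq, s3$sequence$seq))
})

test_that("ground truth carries main plus n labelled orphans", {
  sim <- generate_locus(synthetic_locus_spec(n_orphans = 2, seed = 42))
  labs <- vapply(sim$truth$modules, `[[`, character(1), "label")
  expect_equal(labs, c("main", "o1", "o2"))
  expect_equal(vapply(sim$truth$modules, `[[`, character(1), "klass"),
               c("main", "orphan", "orphan"))
  expect_length(sim$truth$motif_positions, 3L)
  L <- sim$sequence$length
  for (m in sim$truth$modules) {
    expect_lte(m$ct$end, L)
    if (!is.null(m$immunity)) expect_lte(m$immunity$end, L)
  }
})

test_that("the full scan pipeline reproduces noise-free ground truth exactly", {
  for (sd in c(101, 102, 103)) {
    n <- sd %% 4L
    motif <- if (sd %% 2L) motif_venn() else motif_dpxgl()
    sim <- generate_locus(synthetic_locus_spec(n_orphans = n, motif = motif,
                                               seed = sd))
    map <- scan_locus(sim$sequence, motif)
    tdf <- as.data.frame(truth_to_locus_map(sim$sequence, sim$truth))
    rdf <- as.data.frame(map)
    cols <- c("label", "class", "ct_start", "ct_end",
              "immunity_start", "immunity_end")
    expect_equal(rdf[cols], tdf[cols])
    expect_equal(map$full_length_gene$start, sim$truth$full_length_gene$start)
    expect_equal(map$full_length_gene$end, sim$truth$full_length_gene$end)
  }
})

test_that("orphan CT fragments never carry initiation signals", {
  for (sd in c(111, 112)) {
    sim <- generate_locus(synthetic_locus_spec(n_orphans = 3, seed = sd))
    g <- sim$sequence
    orfs <- find_orfs(g, 90L)
    for (m in sim$truth$modules[-1]) {
      host <- NULL
      for (o in orfs) {
        if (o$strand == "+" && o$location$start <= m$ct$start &&
            o$location$end >= m$ct$end) host <- o
      }
      expect_false(is.null(host))
      expect_false(host$has_start_codon)
      sd_cls <- classify_initiation(host, NULL)
      expect_equal(sd_cls, "fragment")
    }
  }
})

test_that("deletion_fusion arithmetic is exact and validated", {
  spec <- synthetic_locus_spec(n_orphans = 1, ct_len_range = c(1800, 1800),
                               immunity_len_range = c(600, 600),
                               gap_range = c(1200, 1200), seed = 7)
  sim <- generate_locus(spec)
  del <- apply_rearrangement(sim$sequence, sim$truth, "deletion_fusion",
                             list(orphan = 1, deletion_len = 3557))
  expect_equal(sim$sequence$length - del$sequence$length, 3557L)
  ev <- del$truth$events[[length(del$truth$events)]]
  expect_equal(ev$kind, "deletion_fusion")
  expect_equal(ev$deletion_len_nt, 3557L)
  expect_error(
    apply_rearrangement(sim$sequence, sim$truth, "deletion_fusion",
                        list(orphan = 1, deletion_len = 0)),
    "positive")
  expect_error(
    apply_rearrangement(sim$sequence, sim$truth, "deletion_fusion",
                        list(orphan = 1, deletion_len = 50)),
    "inside the main CT")
})

test_that("module_copy plants a shared module and updates truth", {
  a <- generate_locus(synthetic_locus_spec(n_orphans = 2, seed = 121))
  b <- generate_locus(synthetic_locus_spec(n_orphans = 1, seed = 122))
  out <- apply_rearrangement(a$sequence, a$truth, "module_copy",
                             list(orphan = 2, target = b))
  ev <- out$truth$events[[length(out$truth$events)]]
  expect_equal(ev$kind, "interchange")
  expect_equal(ev$module_labels, c("o2", "main"))
  src <- a$truth$modules[[3]]
  copied <- substr(out$sequence$seq, ev$b_coords$start + 1, ev$b_coords$end)
  original <- substr(a$sequence$seq, src$motif$start + 1, src$immunity$end)
  expect_identical(copied, original)
})

test_that("truth JSON is written with seed and module coordinates", {
  sim <- generate_locus(synthetic_locus_spec(n_orphans = 1, seed = 131))
  f <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$seed, 131L)
  expect_equal(length(j$modules), 2L)
  expect_equal(j$modules[[2]]$label, "o1")
  expect_equal(j$modules[[2]]$ct$start, sim$truth$modules[[2]]$ct$start)
})
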