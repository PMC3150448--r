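test_that("global identity handles identity, mismatch and peptide inputs", {
  expect_equal(global_percent_identity("ACGT", "ACGT")[1:2],
               list(identity_pct = 100, aligned_len = 4L))
  expect_equal(global_percent_identity("ACGT", "ACGA")[1:2],
               list(identity_pct = 75, aligned_len = 4L))
  pep <- global_percent_identity("MKVLA", "MKVLA")
  expect_equal(pep$identity_pct, 100)
  expect_error(global_percent_identity("", "ACGT"), "non-empty")
})

test_that("global identity agrees with the exhaustive affine-gap DP oracle", {
  set.seed(51)
  ntm <- nt_submatrix()
  aam <- aa_submatrix()
  for (i in 1:60) {
    a <- random_dna(sample(1:12, 1)); b <- random_dna(sample(1:12, 1))
    got <- global_percent_identity(a, b)
    want <- oracle_nw(a, b, ntm, open = 5, ext = 1)
    expect_equal(got$score, want$score)
    expect_true(any(abs(got$identity_pct - want$identities) < 1e-9))
    expect_true(got$aligned_len %in% want$lengths)
  }
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    a <- paste(sample(aas, sample(2:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:12, 1), replace = TRUE), collapse = "")
    got <- global_percent_identity(a, b)
    want <- oracle_nw(a, b, aam, open = 11, ext = 1)
    expect_equal(got$score, want$score)
    expect_true(any(abs(got$identity_pct - want$identities) < 1e-9))
  }
})

test_that("self-comparison yields one full-coverage block and no events", {
  set.seed(52)
  g <- genome_sequence("self", random_dna(5000))
  blocks <- anchor_blocks(g, g)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$q_start, 0L)
  expect_equal(blocks$q_end, 5000L)
  expect_equal(blocks$identity_pct, 100)
  expect_equal(blocks$strand, "+")
  map <- assemble_locus_map(g, list())
  expect_length(detect_divergence_breakpoint(blocks, map, map), 0L)
  expect_length(detect_deletion_fusion(blocks, map, map), 0L)
})

test_that("a planted replacement splits the comparison into flanking blocks", {
  set.seed(53)
  a <- genome_sequence("a", random_dna(5000))
  bseq <- paste0(substr(a$seq, 1, 2000), random_dna(300),
                 substr(a$seq, 2301, 5000))
  b <- genome_sequence("b", bseq)
  blocks <- anchor_blocks(a, b)
  expect_equal(nrow(blocks), 2L)
  expect_lte(abs(blocks$q_end[1] - 2000L), 10L)
  expect_lte(abs(blocks$q_start[2] - 2300L), 10L)
  # nothing called inside the replaced window
  expect_false(any(blocks$q_start > 2010 & blocks$q_end < 2290))
})

test_that("reverse-complement subjects produce minus-strand blocks", {
  set.seed(54)
  a <- genome_sequence("a", random_dna(4000))
  b <- revcomp(a); b$id <- "b_rc"
  blocks <- anchor_blocks(a, b)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$strand, "-")
  expect_equal(c(blocks$s_start, blocks$s_end), c(0L, 4000L))
  expect_equal(blocks$identity_pct, 100)
})

test_that("divergence breakpoints are anchored at motif junctions within tolerance", {
  set.seed(55)
  sim <- generate_locus(synthetic_locus_spec(n_orphans = 2, seed = 61))
  a <- sim$sequence
  # b shares sequence up to the o1 motif junction, then diverges
  junction <- sim$truth$modules[[2]]$motif$start
  b <- genome_sequence("b", paste0(substr(a$seq, 1, junction), random_dna(2500)))
  map_a <- scan_locus(a); map_b <- scan_locus(b)
  blocks <- anchor_blocks(a, b)
  ev <- detect_divergence_breakpoint(blocks, map_a, map_b, tol_nt = 30L)
  expect_gte(length(ev), 1L)
  labs <- vapply(ev, function(e) e$module_labels[1], character(1))
  expect_true("o1" %in% labs)
  # a breakpoint far from any motif is not reported as an event
  c2 <- genome_sequence("c", paste0(substr(a$seq, 1, junction - 500),
                                    random_dna(2500)))
  blocks2 <- anchor_blocks(a, c2)
  ev2 <- detect_divergence_breakpoint(blocks2, map_a, scan_locus(c2), 30L)
  expect_length(ev2, 0L)
})

test_that("planted deletions are recovered at exact length", {
  set.seed(56)
  stub <- list(modules = list())
  for (i in 1:12) {
    g <- genome_sequence("a", random_dna(8000))
    len <- sample(50:5000, 1)
    p <- sample(500:(8000 - len - 500), 1)
    d <- plant_plain_deletion(g, p, len)
    ev <- detect_deletion_fusion(anchor_blocks(g, d), stub, stub)
    expect_length(ev, 1L)
    expect_equal(ev[[1]]$deletion_len_nt, len)
  }
})

test_that("an intergenic deletion carries no fused-module annotation", {
  sim <- generate_locus(synthetic_locus_spec(n_orphans = 2, seed = 71))
  a <- sim$sequence
  # delete 1000 nt starting just after the main immunity gene (intergenic)
  p <- sim$truth$modules[[1]]$immunity$end + 5L
  d <- plant_plain_deletion(a, p, 1000L)
  map_a <- scan_locus(a)
  ev <- detect_deletion_fusion(anchor_blocks(a, d), map_a, scan_locus(d))
  del <- Filter(function(e) e$kind == "deletion_fusion", ev)
  expect_length(del, 1L)
  expect_equal(del[[1]]$deletion_len_nt, 1000L)
  expect_true(is.na(del[[1]]$module_labels[1]))
})

test_that("copied modules are reported as interchange and the call is symmetric", {
  a <- generate_locus(synthetic_locus_spec(n_orphans = 2, seed = 81))
  b <- generate_locus(synthetic_locus_spec(n_orphans = 2, seed = 82))
  moved <- apply_rearrangement(a$sequence, a$truth, "module_copy",
                               list(orphan = 1, target = b))
  map_a <- scan_locus(a$sequence)
  map_b <- scan_locus(moved$sequence)
  ev <- match_modules(map_a, map_b)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$module_labels, c("o1", "main"))
  expect_gte(ev[[1]]$identity_pct, 99)
  back <- match_modules(map_b, map_a)
  expect_length(back, 1L)
  expect_equal(back[[1]]$module_labels, c("main", "o1"))
  # unrelated loci share no modules
  expect_length(match_modules(map_a, scan_locus(b$sequence)), 0L)
})
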