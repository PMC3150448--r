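# direct codon-walk oracle for CT delimitation
oracle_ct <- function(seq, motif_end_cs) {
  L <- nchar(seq)
  pos <- motif_end_cs
  while (pos + 3L <= L) {
    if (substr(seq, pos + 1L, pos + 3L) %in% c("TAA", "TAG", "TGA")) {
      return(list(end = pos, truncated = FALSE))
    }
    pos <- pos + 3L
  }
  list(end = pos, truncated = TRUE)
}

test_that("build_ct_region walks to the first in-frame stop", {
  # motif at [3,15), then 7 non-stop codons, then TAA
  seq <- paste0("AAA", "GTGGAAAATAAT", strrep("GCA", 7), "TAA", "CCCCC")
  g <- genome_sequence("t", seq)
  hit <- scan_six_frames(g, motif_venn())[[1]]
  ct <- build_ct_region(hit, g)
  want <- oracle_ct(seq, 15L)
  expect_equal(ct$location$start, 15L)
  expect_equal(ct$location$end, want$end)
  expect_false(ct$truncated)
  expect_equal(ct$upstream_coding_nt, 3L)   # one full codon upstream of GTG
})

test_that("a CT without a downstream stop is truncated at the sequence edge", {
  seq <- paste0("AAA", "GTGGAAAATAAT", strrep("GCA", 5), "GC")
  g <- genome_sequence("t", seq)
  ct <- build_ct_region(scan_six_frames(g, motif_venn())[[1]], g)
  expect_true(ct$truncated)
  expect_false(ct$stop_present)
  expect_equal(ct$location$end, 15L + 15L)  # last complete codon
})

test_that("minus-strand CT regions lie genomically left of the motif", {
  seq <- paste0("AAA", "GTGGAAAATAAT", strrep("GCA", 7), "TAA", "CCCCC")
  g <- revcomp(genome_sequence("t", seq))
  hit <- scan_six_frames(g, motif_venn())[[1]]
  expect_equal(hit$strand, "-")
  ct <- build_ct_region(hit, g)
  expect_lte(ct$location$end, hit$location$start)
  # mirror of the plus-strand oracle
  L <- g$length
  expect_equal(ct$location$start, L - oracle_ct(seq, 15L)$end)
  expect_equal(ct$location$end, L - 15L)
})

test_that("pair_immunity picks the nearest qualifying ORF with tie-break by length", {
  mk_orf <- function(start, len, strand = "+") {
    structure(list(location = interval(start, start + len, strand),
                   strand = strand, frame_offset = start %% 3L,
                   has_start_codon = TRUE, start_codon = "ATG",
                   stop_present = TRUE, length_nt = len), class = "orf_record")
  }
  ct <- structure(list(location = interval(100, 400, "+"), strand = "+",
                       stop_present = TRUE, truncated = FALSE),
                  class = "ct_region")
  near <- mk_orf(420, 300); far <- mk_orf(800, 300)
  expect_equal(pair_immunity(ct, list(far, near), 300L, c(150, 900), L = 2000L),
               near, ignore_attr = TRUE)
  # outside the window
  expect_null(pair_immunity(ct, list(far), 300L, c(150, 900), L = 2000L))
  # length filter rejects oversized ORFs
  expect_null(pair_immunity(ct, list(mk_orf(420, 1200)), 300L, c(150, 900),
                            L = 2000L))
  # equal gap: the longer ORF wins
  a <- mk_orf(420, 150); b <- mk_orf(420, 450)
  got <- pair_immunity(ct, list(a, b), 300L, c(150, 900), L = 2000L)
  expect_equal(got$length_nt, 450L)
  # antisense ORFs are never paired
  expect_null(pair_immunity(ct, list(mk_orf(420, 300, "-")), 300L, c(150, 900),
                            L = 2000L))
})

test_that("module classification separates full-length genes from orphans", {
  sim <- generate_locus(synthetic_locus_spec(n_orphans = 2, seed = 9))
  g <- sim$sequence
  orfs <- find_orfs(g, 90L)
  hits <- scan_six_frames(g, motif_venn())
  cts <- lapply(hits, build_ct_region, g = g)
  klass <- vapply(cts, classify_module, character(1), g = g, orfs = orfs)
  ups <- vapply(cts, `[[`, integer(1), "upstream_coding_nt")
  expect_equal(klass[which.max(ups)], "main")
  expect_equal(sum(klass == "main"), 1L)
  expect_equal(sum(klass == "orphan"), 2L)
  # the threshold boundary is inclusive
  main_ct <- cts[[which.max(ups)]]
  expect_equal(classify_module(main_ct, g, orfs,
                               main_min_upstream_nt = main_ct$upstream_coding_nt),
               "main")
  expect_equal(classify_module(main_ct, g, orfs,
                               main_min_upstream_nt = main_ct$upstream_coding_nt + 1L),
               "orphan")
})

test_that("o-labels are positional and removing an orphan shifts downstream labels", {
  sim <- generate_locus(synthetic_locus_spec(n_orphans = 3, seed = 15))
  map <- scan_locus(sim$sequence)
  expect_equal(vapply(map$modules, `[[`, character(1), "label"),
               c("main", "o1", "o2", "o3"))
  starts <- vapply(map$modules, function(m) m$ct$location$start, integer(1))
  expect_true(all(diff(starts) > 0))
  # excise o2 (motif through immunity) and rescan
  o2 <- sim$truth$modules[[3]]
  g2 <- genome_sequence("cut", paste0(
    substr(sim$sequence$seq, 1, o2$motif$start - 3),
    substr(sim$sequence$seq, o2$immunity$end + 1, sim$sequence$length)))
  map2 <- scan_locus(g2)
  expect_equal(vapply(map2$modules, `[[`, character(1), "label"),
               c("main", "o1", "o2"))
  # upstream modules unchanged
  expect_equal(map2$modules[[2]]$ct$location$start,
               map$modules[[2]]$ct$location$start)
})

test_that("two main modules are a structural error", {
  g <- genome_sequence("x", random_dna(600))
  fake_main <- function(s) {
    hit <- structure(list(motif = "VENN", location = interval(s, s + 12),
                          strand = "+", frame_offset = s %% 3L,
                          peptide = "VENN", ct_start = s + 12L),
                     class = "motif_hit")
    ct <- structure(list(motif_hit = hit, location = interval(s + 12, s + 60),
                         strand = "+", upstream_coding_nt = 5000L,
                         truncated = FALSE, stop_present = TRUE),
                    class = "ct_region")
    structure(list(ct = ct, immunity = NULL, immunity_expressible = FALSE,
                   klass = "main", label = NA_character_,
                   intergenic_gap_nt = NA_integer_), class = "toxin_module")
  }
  expect_error(assemble_locus_map(g, list(fake_main(10), fake_main(300))),
               "two main")
})

test_that("an insertion-interrupted orphan is reported unpaired with a note", {
  spec <- synthetic_locus_spec(n_orphans = 2, seed = 27,
                               noise = list(is_insertion = TRUE))
  sim <- generate_locus(spec)
  map <- scan_locus(sim$sequence)
  expect_equal(length(map$modules), 3L)
  o1 <- map$modules[[2]]
  expect_null(o1$immunity)   # the 1.2 kb cassette pushes it out of the window
  kinds <- vapply(map$notes, `[[`, character(1), "kind")
  expect_true("unpaired_or_interrupted" %in% kinds)
  # the cassette also shortens the recovered CT relative to the planted one
  expect_lt(orphanscan:::iv_len(o1$ct$location),
            orphanscan:::iv_len(sim$truth$modules[[2]]$ct))
})

test_that("motif-less fragments are noted but never labelled", {
  spec <- synthetic_locus_spec(n_orphans = 1, seed = 31,
                               noise = list(motifless_fragment = TRUE))
  sim <- generate_locus(spec)
  map <- scan_locus(sim$sequence)
  expect_equal(vapply(map$modules, `[[`, character(1), "label"),
               c("main", "o1"))
  frg <- Filter(function(n) n$kind == "motifless_fragment", map$notes)
  expect_gte(length(frg), 1L)
  tf <- sim$truth$motifless_fragment
  hit <- vapply(frg, function(n) n$start < tf$end && tf$start < n$end, logical(1))
  expect_true(any(hit))
})

test_that("a dropped immunity gene leaves the module unpaired, not mispaired", {
  spec <- synthetic_locus_spec(n_orphans = 3, seed = 37,
                               noise = list(drop_immunity_at = 2L))
  sim <- generate_locus(spec)
  map <- scan_locus(sim$sequence)
  labs <- vapply(map$modules, `[[`, character(1), "label")
  expect_equal(labs, c("main", "o1", "o2", "o3"))
  expect_null(map$modules[[3]]$immunity)
  expect_false(is.null(map$modules[[2]]$immunity))
  expect_false(is.null(map$modules[[4]]$immunity))
})
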