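BASES <- c("A", "C", "G", "T")

# per-base sampling weights at a target GC fraction
base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

codon_weights <- function(codons, gc) {
  p <- setNames(base_probs(gc), BASES)
  vapply(codons, function(cd) prod(p[strsplit(cd, "")[[1]]]), numeric(1))
}

ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
START_SET <- c("ATG", "GTG", "TTG")
NONSTART_SENSE <- setdiff(SENSE_CODONS, START_SET)

# one representative codon per residue that is neither a stop nor a start
# codon, so planted fragment frames cannot acquire initiation signals
SAFE_CODON <- local({
  tab <- GENETIC_CODE_11[!names(GENETIC_CODE_11) %in% STOP_CODONS]
  tab <- tab[!names(tab) %in% START_SET]
  vapply(split(names(tab), tab), `[`, character(1), 1L)
})

rint <- function(range) {
  if (range[1] >= range[2]) as.integer(range[1])
  else sample(seq.int(range[1], range[2]), 1L)
}

random_nt <- function(n, gc) {
  paste(sample(BASES, n, replace = TRUE, prob = base_probs(gc)), collapse = "")
}

random_codons <- function(n, gc, allow_starts = TRUE) {
  pool <- if (allow_starts) SENSE_CODONS else NONSTART_SENSE
  paste(sample(pool, n, replace = TRUE, prob = codon_weights(pool, gc)),
        collapse = "")
}

# motif-encoding nucleotides using only start-free codons; wildcards draw a
# random residue (never Met, whose sole codon is the initiator)
encode_motif <- function(motif, gc) {
  wild_pool <- setdiff(names(SAFE_CODON), "M")
  chars <- strsplit(motif$pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    if (ch == ".") SAFE_CODON[[sample(wild_pool, 1L)]] else SAFE_CODON[[ch]]
  }, character(1)), collapse = "")
}

# Stop-dense cassette built from 30 nt units, each carrying a stop codon in
# every forward frame (TAA at unit offsets 0, 4, 8) and every reverse frame
# (TTA at offsets 12, 16, 20), with random filler elsewhere.  No ORF of
# 150 nt or more can start inside it; emulates an insertion-element
# interruption or a decayed gene remnant.
stop_dense_cassette <- function(gc, len = 1200L) {
  n_units <- ceiling(len / 30L)
  units <- vapply(seq_len(n_units), function(i) {
    u <- strsplit(random_nt(30L, gc), "")[[1]]
    u[1:3] <- c("T", "A", "A"); u[5:7] <- c("T", "A", "A")
    u[9:11] <- c("T", "A", "A")
    u[13:15] <- c("T", "T", "A"); u[17:19] <- c("T", "T", "A")
    u[21:23] <- c("T", "T", "A")
    paste(u, collapse = "")
  }, character(1))
  substr(paste(units, collapse = ""), 1L, len)
}

#' Specification for a synthetic CDI/Rhs-like locus
#'
#' Defines the architecture the generator emits: a long expressible
#' full-length gene whose 3' region encodes motif + CT + stop, a downstream
#' expressible immunity ORF, then an ordered array of orphan units — each a
#' motif-encoding CT fragment with no start codon and no Shine-Dalgarno,
#' followed by a small expressible immunity ORF.  Optional noise features
#' add an insertion-element interruption, a motif-less fragment, or drop
#' one orphan's immunity gene.
#'
#' @param n_orphans number of orphan modules (>= 0).
#' @param motif a [compile_motif()] spec or built-in name.
#' @param main_gene_len_nt length of the full-length gene (start to stop).
#' @param ct_len_range,immunity_len_range,gap_range nt ranges for CT
#'   length, immunity ORF length (start through stop) and intergenic
#'   spacers.
#' @param gc_content background GC fraction (0-1 exclusive).
#' @param noise list of flags: `is_insertion`, `motifless_fragment`
#'   (logicals) and `drop_immunity_at` (orphan index or `NULL`).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A validated `synthetic_locus_spec`.
#' @export
synthetic_locus_spec <- function(n_orphans = 2L, motif = motif_venn(),
                                 main_gene_len_nt = 9000L,
                                 ct_len_range = c(250L, 600L),
                                 immunity_len_range = c(300L, 600L),
                                 gap_range = c(40L, 150L),
                                 gc_content = 0.5,
                                 noise = list(is_insertion = FALSE,
                                              motifless_fragment = FALSE,
                                              drop_immunity_at = NULL),
                                 seed = 1L) {
  motif <- resolve_motif(motif)
  noise <- modifyList(list(is_insertion = FALSE, motifless_fragment = FALSE,
                           drop_immunity_at = NULL), noise)
  stopifnot(n_orphans >= 0L, gc_content > 0, gc_content < 1,
            all(ct_len_range > 0), ct_len_range[1] <= ct_len_range[2],
            all(immunity_len_range > 0),
            immunity_len_range[1] <= immunity_len_range[2],
            all(gap_range > 0), gap_range[1] <= gap_range[2])
  if (immunity_len_range[1] < 150L) {
    stop("immunity ORFs below 150 nt fall outside the pairing length filter",
         call. = FALSE)
  }
  if (main_gene_len_nt < 3L + 3L * motif$length + ct_len_range[2] + 3L + 3000L) {
    stop("main_gene_len_nt too short to host motif, CT and a full-length ",
         "upstream region", call. = FALSE)
  }
  if (!is.null(noise$drop_immunity_at)) {
    noise$drop_immunity_at <- as.integer(noise$drop_immunity_at)
    if (noise$drop_immunity_at < 1L || noise$drop_immunity_at > n_orphans) {
      stop("drop_immunity_at must index an orphan", call. = FALSE)
    }
  }
  structure(list(n_orphans = as.integer(n_orphans), motif = motif,
                 main_gene_len_nt = as.integer(main_gene_len_nt),
                 ct_len_range = as.integer(ct_len_range),
                 immunity_len_range = as.integer(immunity_len_range),
                 gap_range = as.integer(gap_range),
                 gc_content = gc_content, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_locus_spec")
}

# count motif occurrences over the six frame translations (generation check)
count_motif_occurrences <- function(seq, motif) {
  g <- genome_sequence("chk", seq)
  rx <- paste0("(?=", motif$pattern, ")")
  total <- 0L
  for (strand in c("+", "-")) for (off in 0:2) {
    m <- gregexpr(rx, translate_frame(g, off, strand), perl = TRUE)[[1]]
    if (m[1] != -1L) total <- total + length(m)
  }
  total
}

build_locus_once <- function(spec) {
  gc <- spec$gc_content
  motif <- spec$motif
  mlen_nt <- 3L * motif$length
  parts <- character(0); pos <- 0L
  add <- function(x) {
    parts[[length(parts) + 1L]] <<- x
    p <- pos; pos <<- pos + nchar(x); p
  }
  ac6 <- function() paste(sample(c("A", "C"), 6L, replace = TRUE), collapse = "")
  # SD + start junction: in-frame stop, anti-SD consensus, 6 nt spacer free
  # of G/T (so no start codon can form across the junction), then ATG
  add_expressible_start <- function() {
    add("TAA"); add("AGGAGG"); add(ac6())
    add("ATG")
  }
  add_immunity <- function() {
    add("AGGAGG"); add(ac6())
    atg <- add("ATG")
    len <- rint(spec$immunity_len_range)
    n_body <- max(1L, (len - 6L) %/% 3L)
    add(random_codons(n_body, gc))
    stop_end <- add("TAA") + 3L
    interval(atg, stop_end, "+")
  }
  modules <- list(); motif_positions <- list(); notes <- list()

  # --- full-length gene ---
  add(random_nt(rint(spec$gap_range) + 60L, gc))
  atg_main <- add_expressible_start()
  ct_len_main <- 3L * (rint(spec$ct_len_range) %/% 3L)
  pre_n <- (spec$main_gene_len_nt - 3L - mlen_nt - ct_len_main - 3L) %/% 3L
  add(random_codons(pre_n, gc))
  m_main <- add(encode_motif(motif, gc))
  motif_positions[[1L]] <- interval(m_main, m_main + mlen_nt, "+")
  ct_main_start <- add(random_codons(ct_len_main %/% 3L, gc))
  main_stop <- add("TAA")
  gene_iv <- interval(atg_main, main_stop + 3L, "+")
  imm_main <- add_immunity()
  modules[[1L]] <- list(label = "main", klass = "main",
                        ct = interval(ct_main_start, main_stop, "+"),
                        immunity = imm_main,
                        motif = motif_positions[[1L]],
                        interrupted = FALSE)

  # --- orphan array ---
  for (j in seq_len(spec$n_orphans)) {
    add(random_nt(rint(spec$gap_range), gc))
    add("TAA")                               # frame anchor: no upstream coding
    m_pos <- add(encode_motif(motif, gc))
    motif_positions[[j + 1L]] <- interval(m_pos, m_pos + mlen_nt, "+")
    n_ct <- rint(spec$ct_len_range) %/% 3L
    interrupted <- isTRUE(spec$noise$is_insertion) && j == 1L
    if (interrupted) {
      add(random_codons(n_ct %/% 2L, gc, allow_starts = FALSE))
      add(stop_dense_cassette(gc))
      add(random_codons(n_ct - n_ct %/% 2L, gc, allow_starts = FALSE))
    } else {
      add(random_codons(n_ct, gc, allow_starts = FALSE))
    }
    ct_stop <- add("TAA")
    imm <- NULL
    if (!identical(spec$noise$drop_immunity_at, as.integer(j))) {
      imm <- add_immunity()
    } else {
      # decayed remnant downstream: stop-dense so nothing can be mistaken
      # for an immunity gene within the pairing window
      add(stop_dense_cassette(gc, 450L))
    }
    modules[[j + 1L]] <- list(label = paste0("o", j), klass = "orphan",
                              ct = interval(m_pos + mlen_nt, ct_stop, "+"),
                              immunity = imm,
                              motif = motif_positions[[j + 1L]],
                              interrupted = interrupted)
  }

  # --- motif-less fragment noise ---
  frag_iv <- NULL
  if (isTRUE(spec$noise$motifless_fragment)) {
    add(random_nt(rint(spec$gap_range), gc))
    add("TAA")
    f0 <- pos
    add(random_codons(150L, gc, allow_starts = FALSE))
    f1 <- add("TAA") + 3L
    frag_iv <- interval(f0, f1, "+")
  }
  add(random_nt(rint(spec$gap_range) + 60L, gc))

  seq <- paste(parts, collapse = "")
  truth <- structure(list(
    modules = modules, motif_positions = motif_positions,
    full_length_gene = gene_iv, motifless_fragment = frag_iv,
    events = list(), motif = motif$name, seed = spec$seed),
    class = "ground_truth")
  list(seq = seq, truth = truth)
}

#' Generate a synthetic locus with planted ground truth
#'
#' Emits a `cdiBAI`-like locus: full-length expressible gene carrying a
#' motif-demarcated CT at its 3' end, downstream immunity ORF, then the
#' requested number of orphan CT/immunity units, with optional noise
#' features.  Planted coding sequence is random (mutually non-homologous
#' CTs); orphan CT frames contain no start codon, so the fragments cannot
#' carry initiation signals.  Generation is deterministic for a fixed
#' seed; candidate sequences containing chance motif occurrences outside
#' the planted positions are rejected and regenerated from a derived seed.
#'
#' @param spec a [synthetic_locus_spec()].
#' @return list with `sequence` (a [genome_sequence()]) and `truth`
#'   (a `ground_truth` of planted modules, motif positions and events).
#' @export
generate_locus <- function(spec) {
  stopifnot(is(spec, "synthetic_locus_spec"))
  expected <- 1L + spec$n_orphans
  for (attempt in 0:49) {
    set.seed((spec$seed + 7919L * attempt) %% .Machine$integer.max)
    built <- build_locus_once(spec)
    n_occ <- count_motif_occurrences(built$seq, spec$motif)
    if (isTRUE(spec$noise$is_insertion)) {
      # the cassette truncates the interrupted CT but never its motif
      ok <- n_occ == expected
    } else ok <- n_occ == expected
    if (ok) {
      g <- genome_sequence(
        sprintf("synthetic_locus_seed%d", spec$seed), built$seq,
        sprintf("synthetic %s locus, %d orphan(s), seed=%d",
                spec$motif$name, spec$n_orphans, spec$seed))
      return(list(sequence = g, truth = built$truth))
    }
  }
  stop("could not generate a locus free of chance motif occurrences",
       call. = FALSE)
}

shift_iv <- function(iv, from, by) {
  if (is.null(iv)) return(NULL)
  if (iv$start >= from) interval(iv$start - by, iv$end - by, iv$strand) else iv
}

#' Plant a rearrangement into a synthetic locus
#'
#' `deletion_fusion` removes the span from a position inside the main CT
#' to the motif junction of orphan `k`, fusing that orphan's CT/immunity
#' module onto the full-length gene and recording the deleted length.
#' `module_copy` overwrites the main CT+immunity span of a second locus
#' with orphan `k`'s CT+immunity span, planting an interchange.
#'
#' @param g a generated [genome_sequence()].
#' @param truth its `ground_truth`.
#' @param kind `"deletion_fusion"` or `"module_copy"`.
#' @param params for `deletion_fusion`: `orphan` (index k) and either
#'   `deletion_len` or `from_pos`; for `module_copy`: `orphan` and
#'   `target` (a `list(sequence=, truth=)` from [generate_locus()]).
#' @return list with updated `sequence` and `truth` (for `module_copy`,
#'   the modified target locus).
#' @export
apply_rearrangement <- function(g, truth, kind, params = list()) {
  kind <- match.arg(kind, c("deletion_fusion", "module_copy"))
  k <- params$orphan
  if (is.null(k)) stop("params$orphan is required", call. = FALSE)
  orphan <- NULL
  for (m in truth$modules) if (identical(m$label, paste0("o", k))) orphan <- m
  if (is.null(orphan)) stop("no orphan o", k, " in truth", call. = FALSE)
  main <- truth$modules[[1L]]
  if (!identical(main$klass, "main")) stop("truth lacks a main module", call. = FALSE)

  if (kind == "deletion_fusion") {
    junction <- orphan$motif$start
    del <- params$deletion_len
    from_pos <- params$from_pos
    if (is.null(from_pos)) {
      if (is.null(del) || del <= 0L) {
        stop("deletion_fusion needs a positive deletion_len or from_pos",
             call. = FALSE)
      }
      from_pos <- junction - as.integer(del)
    }
    del <- junction - from_pos
    if (del <= 0L) stop("deletion span has non-positive length", call. = FALSE)
    if (from_pos <= main$ct$start || from_pos >= main$ct$end) {
      stop("deletion must start inside the main CT region (main CT spans [",
           main$ct$start, ",", main$ct$end, "))", call. = FALSE)
    }
    new_seq <- paste0(substr(g$seq, 1L, from_pos),
                      substr(g$seq, junction + 1L, g$length))
    new_modules <- list()
    for (m in truth$modules) {
      lab_num <- suppressWarnings(as.integer(sub("^o", "", m$label)))
      if (identical(m$label, "main")) next         # its CT is excised
      if (!is.na(lab_num) && lab_num < k) next     # removed by the deletion
      m$ct <- shift_iv(m$ct, junction, del)
      m$immunity <- shift_iv(m$immunity, junction, del)
      m$motif <- shift_iv(m$motif, junction, del)
      if (!is.na(lab_num) && lab_num == k) {
        m$label <- "main"; m$klass <- "main"
      } else if (!is.na(lab_num)) {
        m$label <- paste0("o", lab_num - k)
      }
      new_modules[[length(new_modules) + 1L]] <- m
    }
    fused <- new_modules[[1L]]
    truth$modules <- new_modules
    truth$motif_positions <- lapply(new_modules, `[[`, "motif")
    truth$full_length_gene <- interval(truth$full_length_gene$start,
                                       fused$ct$end + 3L, "+")
    truth$events <- c(truth$events, list(new_event(
      "deletion_fusion", a_coords = interval(from_pos, junction),
      deletion_len_nt = as.integer(del),
      module_labels = c(paste0("o", k), "main"))))
    gg <- genome_sequence(paste0(g$id, "_delfus"), new_seq,
                          sprintf("%s; %d nt deletion fusing o%d", g$description,
                                  del, k))
    return(list(sequence = gg, truth = truth))
  }

  # module_copy
  tgt <- params$target
  if (is.null(tgt)) stop("module_copy needs params$target", call. = FALSE)
  g2 <- tgt$sequence; truth2 <- tgt$truth
  main2 <- truth2$modules[[1L]]
  src0 <- orphan$motif$start
  src1 <- if (is.null(orphan$immunity)) orphan$ct$end + 3L else orphan$immunity$end
  t0 <- main2$motif$start
  t1 <- if (is.null(main2$immunity)) main2$ct$end + 3L else main2$immunity$end
  chunk <- substr(g$seq, src0 + 1L, src1)
  new_seq <- paste0(substr(g2$seq, 1L, t0), chunk,
                    substr(g2$seq, t1 + 1L, g2$length))
  delta <- (t1 - t0) - nchar(chunk)
  reloc <- function(iv) {
    if (is.null(iv)) return(NULL)
    interval(iv$start - src0 + t0, iv$end - src0 + t0, "+")
  }
  new_main <- list(label = "main", klass = "main",
                   ct = reloc(orphan$ct), immunity = reloc(orphan$immunity),
                   motif = reloc(orphan$motif), interrupted = FALSE)
  new_modules <- list(new_main)
  for (m in truth2$modules[-1L]) {
    m$ct <- shift_iv(m$ct, t1, delta)
    m$immunity <- shift_iv(m$immunity, t1, delta)
    m$motif <- shift_iv(m$motif, t1, delta)
    new_modules[[length(new_modules) + 1L]] <- m
  }
  truth2$modules <- new_modules
  truth2$motif_positions <- lapply(new_modules, `[[`, "motif")
  truth2$full_length_gene <- interval(truth2$full_length_gene$start,
                                      new_main$ct$end + 3L, "+")
  truth2$events <- c(truth2$events, list(new_event(
    "interchange", a_coords = interval(src0, src1),
    b_coords = interval(t0, t0 + nchar(chunk)),
    module_labels = c(paste0("o", k), "main"), identity_pct = 100)))
  gg2 <- genome_sequence(paste0(g2$id, "_copy"), new_seq,
                         sprintf("%s; main module replaced by donor o%d",
                                 g2$description, k))
  list(sequence = gg2, truth = truth2)
}

#' Express planted ground truth as a locus map
#'
#' Builds a `locus_map` directly from a generator's ground truth, so that
#' truth can be written as GFF3 and compared field-by-field against the
#' map recovered by [scan_locus()].
#'
#' @param g the generated [genome_sequence()].
#' @param truth its `ground_truth`.
#' @return A `locus_map`.
#' @export
truth_to_locus_map <- function(g, truth) {
  modules <- lapply(truth$modules, function(m) {
    hit <- structure(list(motif = truth$motif, location = m$motif,
                          strand = "+", frame_offset = m$motif$start %% 3L,
                          peptide = NA_character_, ct_start = m$motif$end),
                     class = "motif_hit")
    ct <- structure(list(motif_hit = hit, location = m$ct, strand = "+",
                         upstream_coding_nt = NA_integer_,
                         truncated = isTRUE(m$interrupted),
                         stop_present = TRUE), class = "ct_region")
    imm <- NULL
    if (!is.null(m$immunity)) {
      imm <- structure(list(location = m$immunity, strand = "+",
                            frame_offset = m$immunity$start %% 3L,
                            has_start_codon = TRUE, start_codon = "ATG",
                            stop_present = TRUE,
                            length_nt = iv_len(m$immunity)),
                       class = "orf_record")
    }
    structure(list(ct = ct, immunity = imm,
                   immunity_expressible = !is.null(imm), klass = m$klass,
                   label = m$label,
                   intergenic_gap_nt = if (is.null(imm)) NA_integer_ else
                     imm$location$start - m$ct$end),
              class = "toxin_module")
  })
  map <- structure(list(sequence_id = g$id, sequence_length = g$length,
                        full_length_gene = truth$full_length_gene,
                        modules = modules, notes = list(),
                        motif = truth$motif, sequence = g),
                   class = "locus_map")
  map
}

#' Write ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  iv_js <- function(iv) if (is.null(iv)) NULL else
    list(start = iv$start, end = iv$end, strand = iv$strand)
  out <- list(
    seed = truth$seed, motif = truth$motif,
    full_length_gene = iv_js(truth$full_length_gene),
    modules = lapply(truth$modules, function(m) list(
      label = m$label, klass = m$klass, ct = iv_js(m$ct),
      immunity = iv_js(m$immunity), motif = iv_js(m$motif),
      interrupted = isTRUE(m$interrupted))),
    events = lapply(truth$events, function(e) list(
      kind = e$kind, a_coords = iv_js(e$a_coords), b_coords = iv_js(e$b_coords),
      deletion_len_nt = e$deletion_len_nt,
      module_labels = as.list(e$module_labels),
      identity_pct = e$identity_pct)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
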