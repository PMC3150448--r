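#' Default module-assembly parameters
#'
#' Field-scale defaults: immunity ORFs are "small" genes of roughly
#' 150-900 nt found within 300 nt downstream of a toxin CT; a module counts
#' as the main (full-length) gene when at least 3,000 nt of uninterrupted
#' in-frame coding sequence lie upstream of the demarcation motif
#' (full-length CdiA/Rhs proteins exceed 1,400 residues) and that upstream
#' frame is expressible.  All are configurable.
#'
#' @return Named list of parameters.
#' @export
module_config <- function() {
  list(max_gap_nt = 300L,
       immunity_len_range = c(150L, 900L),
       main_min_upstream_nt = 3000L,
       fragment_min_len = 300L)
}

# coding-strand coordinates of a genome interval
iv_cs <- function(iv, L) {
  if (iv$strand == "+") c(iv$start, iv$end) else c(L - iv$end, L - iv$start)
}

#' Delimit the toxin C-terminal (CT) region downstream of a motif hit
#'
#' The CT begins at the first nucleotide after the motif-encoding span on
#' the coding strand and extends to the first in-frame stop codon
#' (exclusive of the stop).  If no stop occurs before the sequence edge the
#' region is truncated at the last complete codon and flagged.  The number
#' of nucleotides of uninterrupted in-frame coding sequence upstream of the
#' motif is also recorded; it is the quantity that separates full-length
#' genes from detached CT remnants.
#'
#' @param hit a `motif_hit` from [scan_six_frames()].
#' @param g the [genome_sequence()] the hit was produced from.
#' @return `ct_region` with fields `motif_hit`, `location`, `strand`,
#'   `upstream_coding_nt`, `truncated`, `stop_present`.
#' @export
build_ct_region <- function(hit, g) {
  L <- g$length
  cs <- if (hit$strand == "+") g$seq else revcomp(g$seq)
  mspan <- iv_cs(hit$location, L)          # motif span, coding-strand coords
  m_end <- mspan[2]
  n_down <- (L - m_end) %/% 3L
  stop_at <- NA_integer_
  if (n_down > 0L) {
    starts <- m_end + 1L + 3L * (seq_len(n_down) - 1L)
    codons <- substring(cs, starts, starts + 2L)
    hitstop <- which(codons %in% STOP_CODONS)
    if (length(hitstop)) stop_at <- m_end + 3L * (hitstop[1] - 1L)
  }
  truncated <- is.na(stop_at)
  ct_end <- if (truncated) m_end + 3L * n_down else stop_at
  # upstream codon walk from the motif start until a stop or the edge
  n_up <- mspan[1] %/% 3L
  up_nt <- 0L
  if (n_up > 0L) {
    ustarts <- mspan[1] - 3L * seq_len(n_up) + 1L
    ucodons <- substring(cs, ustarts, ustarts + 2L)
    ustop <- which(ucodons %in% STOP_CODONS)
    up_nt <- 3L * (if (length(ustop)) ustop[1] - 1L else n_up)
  }
  loc <- if (ct_end > m_end) {
    if (hit$strand == "+") interval(m_end, ct_end, "+")
    else interval(L - ct_end, L - m_end, "-")
  } else NULL
  if (is.null(loc)) {  # motif at the very edge: zero-length CT, keep a stub
    loc <- hit$location
    truncated <- TRUE
  }
  structure(list(motif_hit = hit, location = loc, strand = hit$strand,
                 upstream_coding_nt = up_nt, truncated = truncated,
                 stop_present = !is.na(stop_at)),
            class = "ct_region")
}

# coding-strand end of the CT (position of its stop codon, or edge)
ct_cs_end <- function(ct, L) iv_cs(ct$location, L)[2]

#' Pair a CT region with its downstream immunity ORF
#'
#' Returns the nearest same-strand ORF whose start lies within
#' `max_gap_nt` downstream of the CT end (coding-strand direction) and
#' whose length falls in `len_range`; ties on gap are broken toward the
#' longer ORF.  `NULL` when no candidate qualifies (unpaired module).
#'
#' @param ct a [build_ct_region()] result.
#' @param orfs candidate `orf_record` list from the same sequence
#'   (CT-bearing ORFs should not be offered as candidates).
#' @param max_gap_nt pairing window in nt.
#' @param len_range numeric `(min, max)` ORF length in nt.
#' @param L parent sequence length (nt).
#' @return An `orf_record` or `NULL`.
#' @export
pair_immunity <- function(ct, orfs, max_gap_nt = 300L,
                          len_range = c(150L, 900L),
                          L = attr(ct, "seqlen", exact = TRUE)) {
  if (is.null(L)) stop("pair_immunity needs the sequence length L", call. = FALSE)
  cend <- ct_cs_end(ct, L)
  best <- NULL; best_gap <- NA_integer_
  for (orf in orfs) {
    if (orf$strand != ct$strand) next
    if (orf$length_nt < len_range[1] || orf$length_nt > len_range[2]) next
    gap <- orf_cs_start(orf, L) - cend
    if (gap < 0L || gap > max_gap_nt) next
    if (is.null(best) || gap < best_gap ||
        (gap == best_gap && orf$length_nt > best$length_nt)) {
      best <- orf; best_gap <- gap
    }
  }
  if (!is.null(best)) attr(best, "gap_nt") <- best_gap
  best
}

# the stop-to-stop ORF whose frame and span contain the motif hit
containing_orf <- function(hit, orfs, L) {
  m0 <- iv_cs(hit$location, L)[1]
  for (orf in orfs) {
    if (orf$strand != hit$strand || orf$frame_offset != hit$frame_offset) next
    span <- iv_cs(orf$location, L)
    if (m0 >= span[1] && m0 < span[2]) return(orf)
  }
  NULL
}

orf_contains_any_motif <- function(orf, hits, L) {
  span <- iv_cs(orf$location, L)
  for (h in hits) {
    if (h$strand != orf$strand) next
    m0 <- iv_cs(h$location, L)[1]
    if (h$frame_offset == orf$frame_offset && m0 >= span[1] && m0 < span[2])
      return(TRUE)
  }
  FALSE
}

#' Classify a motif-anchored module as main or orphan
#'
#' A module belongs to the full-length (main) gene when the in-frame coding
#' sequence upstream of its motif is at least `main_min_upstream_nt` long
#' (inclusive boundary) and the upstream frame, traced to its annotated
#' start codon, is expressible; otherwise the module is a detached orphan
#' remnant.
#'
#' @param ct a [build_ct_region()] result.
#' @param g the parent [genome_sequence()].
#' @param orfs the [find_orfs()] output for `g`.
#' @param main_min_upstream_nt inclusive threshold in nt.
#' @param ocfg ORF/SD parameters, see [orf_config()].
#' @return `"main"` or `"orphan"`.
#' @export
classify_module <- function(ct, g, orfs,
                            main_min_upstream_nt = module_config()$main_min_upstream_nt,
                            ocfg = orf_config()) {
  if (ct$upstream_coding_nt < main_min_upstream_nt) return("orphan")
  host <- containing_orf(ct$motif_hit, orfs, g$length)
  if (is.null(host) || !isTRUE(host$has_start_codon)) return("orphan")
  sd <- score_sd(g, host, ocfg)
  if (classify_initiation(host, sd, ocfg$sd_min_score) == "expressible") "main"
  else "orphan"
}

iv_overlaps <- function(a, b) a$start < b$end && b$start < a$end

#' Genomic span of a module (CT plus immunity, if paired)
#' @param m a `toxin_module`.
#' @return An [interval()].
#' @export
module_span <- function(m) {
  s <- m$ct$location$start; e <- m$ct$location$end
  if (m$ct$stop_present) { if (m$ct$strand == "+") e <- e + 3L else s <- s - 3L }
  if (!is.null(m$immunity)) {
    s <- min(s, m$immunity$location$start)
    e <- max(e, m$immunity$location$end)
  }
  interval(s, e, m$ct$strand)
}

#' Assemble modules into an ordered, o-labelled locus map
#'
#' Modules are sorted 5' to 3' along the locus strand; the (at most one)
#' main module is labelled `"main"` and orphans are labelled `o1..oN` in
#' positional order — downstream of the main gene, or from the locus 5'
#' end when there is none.  Motif-less fragments are carried as notes,
#' never labelled.
#'
#' @param g the parent [genome_sequence()].
#' @param modules list of `toxin_module` records (unlabelled).
#' @param motifless_fragments list of fragment `orf_record`s to note.
#' @param full_length_gene optional [interval()] of the main gene.
#' @param notes additional structured annotations.
#' @param motif_name motif used for the scan (report metadata).
#' @return A `locus_map`.
#' @export
assemble_locus_map <- function(g, modules, motifless_fragments = list(),
                               full_length_gene = NULL, notes = list(),
                               motif_name = NA_character_) {
  n_main <- sum(vapply(modules, function(m) identical(m$klass, "main"), logical(1)))
  if (n_main > 1L) {
    stop("locus contains two main modules; split the input per locus",
         call. = FALSE)
  }
  if (length(modules)) {
    strands <- vapply(modules, function(m) m$ct$strand, character(1))
    locus_strand <- names(sort(table(strands), decreasing = TRUE))[1]
    key <- vapply(modules, function(m) m$ct$location$start, integer(1))
    ord <- order(if (locus_strand == "+") key else -key)
    modules <- modules[ord]
  }
  k <- 0L
  for (i in seq_along(modules)) {
    if (identical(modules[[i]]$klass, "main")) {
      modules[[i]]$label <- "main"
    } else {
      k <- k + 1L
      modules[[i]]$label <- paste0("o", k)
    }
    if (is.null(modules[[i]]$immunity)) {
      notes[[length(notes) + 1L]] <- list(
        kind = "unpaired_or_interrupted", label = modules[[i]]$label,
        detail = "motif-anchored CT with no immunity ORF in the pairing window")
    }
  }
  for (fr in motifless_fragments) {
    notes[[length(notes) + 1L]] <- list(
      kind = "motifless_fragment",
      start = fr$location$start, end = fr$location$end,
      strand = fr$strand,
      detail = "fragment ORF without demarcation motif or immunity gene")
  }
  structure(list(sequence_id = g$id, sequence_length = g$length,
                 full_length_gene = full_length_gene, modules = modules,
                 notes = notes, motif = motif_name, sequence = g),
            class = "locus_map")
}

#' Annotate one locus end to end
#'
#' Runs the full single-locus pipeline: six-frame motif scan, ORF calling,
#' CT delimitation, immunity pairing, main/orphan classification, and
#' positional o-labelling.  ORFs that themselves carry a demarcation motif
#' are CT fragments and are never offered as immunity candidates.
#'
#' @param g a [genome_sequence()] (or single-record FASTA path).
#' @param motif motif spec, built-in name or config path.
#' @param config pipeline parameters, see [pipeline_config()].
#' @return A `locus_map`.
#' @export
scan_locus <- function(g, motif = "VENN", config = pipeline_config()) {
  if (is.character(g)) g <- read_fasta(g)[[1]]
  motif <- resolve_motif(motif)
  hits <- scan_six_frames(g, motif)
  orfs <- find_orfs(g, config$orf$min_orf_len, config$orf)
  candidates <- Filter(function(o) !orf_contains_any_motif(o, hits, g$length), orfs)
  modules <- list()
  full_gene <- NULL
  for (h in hits) {
    ct <- build_ct_region(h, g)
    imm <- pair_immunity(ct, candidates, config$module$max_gap_nt,
                         config$module$immunity_len_range, L = g$length)
    klass <- classify_module(ct, g, orfs, config$module$main_min_upstream_nt,
                             config$orf)
    imm_expr <- FALSE
    if (!is.null(imm)) {
      sd <- if (isTRUE(imm$has_start_codon)) score_sd(g, imm, config$orf) else NULL
      imm_expr <- classify_initiation(imm, sd, config$orf$sd_min_score) == "expressible"
    }
    if (klass == "main" && is.null(full_gene)) {
      host <- containing_orf(h, orfs, g$length)
      if (!is.null(host)) full_gene <- host$location
    }
    modules[[length(modules) + 1L]] <- structure(list(
      ct = ct, immunity = imm, immunity_expressible = imm_expr,
      klass = klass, label = NA_character_,
      intergenic_gap_nt = if (is.null(imm)) NA_integer_
                          else attr(imm, "gap_nt", exact = TRUE)),
      class = "toxin_module")
  }
  frags <- motifless_fragment_candidates(g, orfs, hits, modules, full_gene,
                                         config)
  assemble_locus_map(g, modules, frags, full_length_gene = full_gene,
                     motif_name = motif$name)
}

# fragment ORFs (no initiation signals) of substantial length that carry no
# motif and overlap neither a module nor the full-length gene
motifless_fragment_candidates <- function(g, orfs, hits, modules, full_gene,
                                          config) {
  spans <- lapply(modules, module_span)
  if (!is.null(full_gene)) spans <- c(spans, list(full_gene))
  keep <- list()
  for (orf in orfs) {
    if (orf$length_nt < config$module$fragment_min_len) next
    if (orf_contains_any_motif(orf, hits, g$length)) next
    sd <- if (isTRUE(orf$has_start_codon)) score_sd(g, orf, config$orf) else NULL
    if (classify_initiation(orf, sd, config$orf$sd_min_score) == "expressible") next
    if (any(vapply(spans, function(s) iv_overlaps(s, orf$location), logical(1)))) next
    keep[[length(keep) + 1L]] <- orf
  }
  keep
}

#' @export
print.locus_map <- function(x, ...) {
  cat(sprintf("<locus_map> %s (%d nt), motif %s\n", x$sequence_id,
              x$sequence_length, x$motif))
  if (!is.null(x$full_length_gene)) {
    cat(sprintf("  full-length gene: [%d, %d) %s\n", x$full_length_gene$start,
                x$full_length_gene$end, x$full_length_gene$strand))
  }
  df <- as.data.frame(x)
  if (nrow(df)) print(df, row.names = FALSE) else cat("  no modules\n")
  if (length(x$notes)) {
    cat(sprintf("  %d note(s): %s\n", length(x$notes),
                paste(vapply(x$notes, `[[`, character(1), "kind"), collapse = ", ")))
  }
  invisible(x)
}

#' One-row-per-module report of a locus map
#' @param x a `locus_map`.
#' @param ... unused.
#' @return data.frame (label, class, strand, coordinates, gap, flags).
#' @export
as.data.frame.locus_map <- function(x, ...) {
  rows <- lapply(x$modules, function(m) data.frame(
    label = m$label, class = m$klass, strand = m$ct$strand,
    ct_start = m$ct$location$start, ct_end = m$ct$location$end,
    immunity_start = if (is.null(m$immunity)) NA_integer_ else m$immunity$location$start,
    immunity_end = if (is.null(m$immunity)) NA_integer_ else m$immunity$location$end,
    gap_nt = if (is.null(m$intergenic_gap_nt)) NA_integer_ else m$intergenic_gap_nt,
    immunity_expressible = m$immunity_expressible,
    ct_truncated = m$ct$truncated,
    upstream_coding_nt = m$ct$upstream_coding_nt,
    stringsAsFactors = FALSE))
  if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), class = character(0))
}

#' Write the locus-map module table as TSV
#' @param locus_map a `locus_map`.
#' @param path output path.
#' @export
write_locus_tsv <- function(locus_map, path) {
  write.table(as.data.frame(locus_map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
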