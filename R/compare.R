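#' Default locus-comparison parameters
#'
#' Anchored block comparison seeds on exact shared `k`-mers (default 21),
#' extends gap-free, and reports blocks of at least `min_block_len` nt at
#' `block_min_identity` percent or better.  Breakpoints and deletion gaps
#' are matched to motif junctions within `tol` nt; interchange calls
#' require `interchange_min_identity` percent over
#' `interchange_min_len` nt.
#'
#' @return Named list of parameters.
#' @export
compare_config <- function() {
  list(k = 21L,
       min_block_len = 100L,
       block_min_identity = 90,
       breakpoint_tol_nt = 30L,
       deletion_tol_nt = 30L,
       interchange_min_identity = 90,
       interchange_min_len = 500L)
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

is_nucleotide <- function(x) {
  grepl("^[ACGTUN]+$", toupper(x))
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment.  Nucleotide inputs score match +1 /
#' mismatch -1 with gap open 5 and gap extension 1 (a gap of length L costs
#' 5 + L); peptide inputs use BLOSUM62 with gap open 11 / extension 1.  The
#' alphabet is auto-detected.  Identity is identical columns over all
#' aligned columns, gap columns included in the denominator.
#'
#' @param a,b non-empty sequence strings (both nucleotide or both peptide).
#' @return list with `identity_pct` and `aligned_len` (alignment columns),
#'   plus the raw alignment `score`.
#' @export
global_percent_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  if (!nzchar(a) || !nzchar(b)) {
    stop("global_percent_identity requires non-empty sequences", call. = FALSE)
  }
  a <- toupper(a); b <- toupper(b)
  nt <- is_nucleotide(a) && is_nucleotide(b)
  aln <- if (nt) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 1)
  } else {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = blosum62, gapOpening = 11, gapExtension = 1)
  }
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(identity_pct = 100 * Biostrings::nmatch(aln) / cols,
       aligned_len = cols,
       score = Biostrings::score(aln))
}

# blocks on one orientation: match vector per seeded diagonal
blocks_one_strand <- function(aseq, bseq, k, min_len, min_ident) {
  La <- nchar(aseq); Lb <- nchar(bseq)
  if (La < k || Lb < k) return(NULL)
  achars <- strsplit(aseq, "")[[1]]
  bchars <- strsplit(bseq, "")[[1]]
  ak <- substring(aseq, 1:(La - k + 1L), k:La)
  bk <- substring(bseq, 1:(Lb - k + 1L), k:Lb)
  bidx <- split(seq_along(bk), bk)
  present <- which(ak %in% names(bidx))
  if (!length(present)) return(NULL)
  diags <- unique(unlist(lapply(present, function(i) i - bidx[[ak[i]]]),
                         use.names = FALSE))
  thr <- min_ident / 100
  out <- list()
  for (d in diags) {
    qlo <- max(1L, 1L + d); qhi <- min(La, Lb + d)
    if (qhi - qlo + 1L < min_len) next
    mvec <- achars[qlo:qhi] == bchars[(qlo:qhi) - d]
    r <- rle(mvec)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    core <- which(r$values & r$lengths >= k)
    if (!length(core)) next
    cm <- cumsum(mvec)
    nmatch_in <- function(s, e) cm[e] - if (s > 1L) cm[s - 1L] else 0L
    # chain cores when the bridged gap is itself near-identical (or tiny),
    # so a sustained divergent stretch always breaks the block
    merged <- list(); cur <- c(starts[core[1]], ends[core[1]])
    for (ci in core[-1]) {
      s2 <- starts[ci]; e2 <- ends[ci]
      gap_len <- s2 - cur[2] - 1L
      gap_ok <- gap_len <= 12L ||
        nmatch_in(cur[2] + 1L, s2 - 1L) / gap_len >= thr
      if (gap_ok && nmatch_in(cur[1], e2) / (e2 - cur[1] + 1L) >= thr) {
        cur[2] <- e2
      } else {
        merged[[length(merged) + 1L]] <- cur; cur <- c(s2, e2)
      }
    }
    merged[[length(merged) + 1L]] <- cur
    n <- length(mvec)
    ext <- lapply(merged, function(blk) {
      s <- blk[1]; e <- blk[2]
      i <- s - 1L; mm <- 0L
      while (i >= 1L && mm < 3L) {
        if (mvec[i]) { s <- i; mm <- 0L } else mm <- mm + 1L
        i <- i - 1L
      }
      i <- e + 1L; mm <- 0L
      while (i <= n && mm < 3L) {
        if (mvec[i]) { e <- i; mm <- 0L } else mm <- mm + 1L
        i <- i + 1L
      }
      c(s, e)
    })
    # extension can bridge neighbours; merge overlaps
    ext <- ext[order(vapply(ext, `[`, integer(1), 1))]
    final <- list(); cur <- ext[[1]]
    for (blk in ext[-1]) {
      if (blk[1] <= cur[2] + 1L) cur[2] <- max(cur[2], blk[2])
      else { final[[length(final) + 1L]] <- cur; cur <- blk }
    }
    final[[length(final) + 1L]] <- cur
    for (blk in final) {
      len <- blk[2] - blk[1] + 1L
      ident <- 100 * nmatch_in(blk[1], blk[2]) / len
      if (len < min_len || ident < min_ident) next
      q0 <- qlo + blk[1] - 2L              # 0-based half-open
      q1 <- qlo + blk[2] - 1L
      out[[length(out) + 1L]] <- data.frame(
        q_start = q0, q_end = q1, s_start = q0 - d, s_end = q1 - d,
        identity_pct = ident, length_nt = len)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Anchored identity blocks between two loci
#'
#' ACT-style gap-free block comparison: exact shared k-mers (both strands
#' of `b`) seed diagonals; co-diagonal seeds are chained while the running
#' identity stays at or above `block_min_identity`, extended outward until
#' sustained divergence, and trimmed to matching boundaries.  Indels
#' therefore appear as block boundaries.
#'
#' @param a,b [genome_sequence()] objects (query and subject).
#' @param k seed length (odd, 11-31).
#' @param config comparison parameters, see [compare_config()].
#' @return data.frame of blocks sorted by `q_start` (0-based half-open
#'   coordinates): q_start, q_end, s_start, s_end, strand, identity_pct,
#'   length_nt.
#' @export
anchor_blocks <- function(a, b, k = compare_config()$k,
                          config = compare_config()) {
  stopifnot(is(a, "genome_sequence"), is(b, "genome_sequence"))
  if (k %% 2L == 0L || k < 11L || k > 31L) {
    stop("k must be odd and within 11..31", call. = FALSE)
  }
  Lb <- b$length
  fwd <- blocks_one_strand(a$seq, b$seq, k, config$min_block_len,
                           config$block_min_identity)
  if (!is.null(fwd) && nrow(fwd)) fwd$strand <- "+"
  rev <- blocks_one_strand(a$seq, revcomp(b$seq), k, config$min_block_len,
                           config$block_min_identity)
  if (!is.null(rev) && nrow(rev)) {
    tmp <- Lb - rev$s_end
    rev$s_end <- Lb - rev$s_start
    rev$s_start <- tmp
    rev$strand <- "-"
  }
  blocks <- rbind(fwd, rev)
  if (is.null(blocks) || !nrow(blocks)) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), identity_pct = numeric(0),
                      length_nt = integer(0)))
  }
  blocks <- blocks[, c("q_start", "q_end", "s_start", "s_end", "strand",
                       "identity_pct", "length_nt")]
  blocks[order(blocks$q_start, blocks$s_start), , drop = FALSE]
}

new_event <- function(kind, a_coords = NULL, b_coords = NULL,
                      deletion_len_nt = NA_integer_,
                      module_labels = c(NA_character_, NA_character_),
                      identity_pct = NA_real_, removed_labels = character(0)) {
  structure(list(kind = kind, a_coords = a_coords, b_coords = b_coords,
                 deletion_len_nt = deletion_len_nt,
                 module_labels = module_labels, identity_pct = identity_pct,
                 removed_labels = removed_labels),
            class = "rearrangement_event")
}

point_iv_dist <- function(p, iv) max(iv$start - p, p - iv$end, 0L)

#' Divergence breakpoints at motif junctions
#'
#' Block boundaries lying within `tol_nt` of a motif-encoding span of
#' locus A are reported as divergence breakpoints anchored at that motif —
#' the signature of homology that "extends precisely to" a demarcation
#' motif and then falls off.
#'
#' @param blocks [anchor_blocks()] output.
#' @param map_a,map_b `locus_map`s of the compared sequences.
#' @param tol_nt matching tolerance in nt.
#' @return list of `rearrangement_event`s of kind `divergence_breakpoint`.
#' @export
detect_divergence_breakpoint <- function(blocks, map_a, map_b, tol_nt = 30L) {
  events <- list()
  if (!nrow(blocks)) return(events)
  seen <- character(0)
  for (m in map_a$modules) {
    miv <- m$ct$motif_hit$location
    for (i in seq_len(nrow(blocks))) {
      for (side in c("q_start", "q_end")) {
        p <- blocks[[side]][i]
        if (p <= 0L || p >= map_a$sequence_length) next  # sequence edges
        if (point_iv_dist(p, miv) <= tol_nt) {
          key <- paste(m$label, side)
          if (key %in% seen) next
          seen <- c(seen, key)
          events[[length(events) + 1L]] <- new_event(
            "divergence_breakpoint", a_coords = miv,
            module_labels = c(m$label, NA_character_))
        }
      }
    }
  }
  events
}

#' Deletion-fusion events between a reference and a derived locus
#'
#' With locus A as the reference (non-deleted) arrangement, a
#' deletion-fusion is called when consecutive plus-strand blocks are
#' contiguous on B (gap at most `tol_nt`) but separated on A; the deleted
#' length is the A-gap minus the B-gap and is exact by diagonal
#' arithmetic.  The event is annotated with the A modules removed by the
#' deletion and the A module whose motif junction abuts the deletion end —
#' the module now fused onto B's full-length gene.
#'
#' @param blocks [anchor_blocks()] output.
#' @param map_a,map_b `locus_map`s (A is the reference).
#' @param tol_nt contiguity/annotation tolerance in nt.
#' @return list of `rearrangement_event`s of kind `deletion_fusion`.
#' @export
detect_deletion_fusion <- function(blocks, map_a, map_b, tol_nt = 30L) {
  events <- list()
  fb <- blocks[blocks$strand == "+", , drop = FALSE]
  if (nrow(fb) < 2L) return(events)
  fb <- fb[order(fb$q_start), , drop = FALSE]
  for (i in seq_len(nrow(fb) - 1L)) {
    gapA <- fb$q_start[i + 1L] - fb$q_end[i]
    gapB <- fb$s_start[i + 1L] - fb$s_end[i]
    del <- gapA - gapB
    if (gapB > tol_nt || del <= tol_nt) next
    a_lo <- fb$q_end[i]; a_hi <- fb$q_start[i + 1L]
    removed <- character(0); fused <- NA_character_
    for (m in map_a$modules) {
      span <- module_span(m)
      if (span$start >= a_lo - tol_nt && span$end <= a_hi + tol_nt) {
        removed <- c(removed, m$label)
      }
      if (point_iv_dist(a_hi, m$ct$motif_hit$location) <= tol_nt) {
        fused <- m$label
      }
    }
    into <- NA_character_
    if (!is.na(fused) &&
        any(vapply(map_b$modules, function(m) identical(m$klass, "main"),
                   logical(1)))) {
      into <- "main"
    }
    events[[length(events) + 1L]] <- new_event(
      "deletion_fusion",
      a_coords = interval(a_lo, max(a_hi, a_lo + 1L)),
      b_coords = interval(fb$s_end[i], max(fb$s_start[i + 1L], fb$s_end[i] + 1L)),
      deletion_len_nt = as.integer(del),
      module_labels = c(fused, into),
      removed_labels = removed)
  }
  events
}

module_seq <- function(map, m) {
  span <- module_span(m)
  s <- substr(map$sequence$seq, span$start + 1L, span$end)
  if (span$strand == "-") revcomp(s) else s
}

#' Interchanged (near-identical) module pairs between two loci
#'
#' Aligns every module pair (one per locus) over its CT-plus-immunity
#' nucleotide span and reports pairs at `min_identity_pct` or better over
#' at least `min_len_nt` aligned columns as interchange events.  A module
#' may appear in several pairs; swapping A and B yields the same pairs
#' with the labels swapped.
#'
#' @param map_a,map_b `locus_map`s built with the same motif.
#' @param min_identity_pct identity threshold (percent).
#' @param min_len_nt minimum aligned length in nt.
#' @return list of `rearrangement_event`s of kind `interchange`.
#' @export
match_modules <- function(map_a, map_b, min_identity_pct = 90,
                          min_len_nt = 500L) {
  events <- list()
  for (ma in map_a$modules) {
    sa <- module_seq(map_a, ma)
    for (mb in map_b$modules) {
      sb <- module_seq(map_b, mb)
      if (min(nchar(sa), nchar(sb)) < min_len_nt) next
      res <- global_percent_identity(sa, sb)
      if (res$identity_pct >= min_identity_pct &&
          res$aligned_len >= min_len_nt) {
        events[[length(events) + 1L]] <- new_event(
          "interchange", a_coords = module_span(ma),
          b_coords = module_span(mb),
          module_labels = c(ma$label, mb$label),
          identity_pct = res$identity_pct)
      }
    }
  }
  events
}

#' Compare two annotated loci
#'
#' Scans both loci with the same motif, computes anchored identity blocks,
#' and calls divergence breakpoints at motif junctions, deletion-fusion
#' events (A as reference) and module interchange.
#'
#' @param a,b [genome_sequence()] objects or single-record FASTA paths.
#' @param motif motif spec, built-in name or config path.
#' @param config pipeline parameters, see [pipeline_config()].
#' @return A `locus_comparison` with `map_a`, `map_b`, `blocks`, `events`.
#' @export
compare_loci <- function(a, b, motif = "VENN", config = pipeline_config()) {
  if (is.character(a)) a <- read_fasta(a)[[1]]
  if (is.character(b)) b <- read_fasta(b)[[1]]
  map_a <- scan_locus(a, motif, config)
  map_b <- scan_locus(b, motif, config)
  cc <- config$compare
  blocks <- anchor_blocks(a, b, cc$k, cc)
  pairs <- match_modules(map_a, map_b, cc$interchange_min_identity,
                         cc$interchange_min_len)
  # interchange means near-identity at a *different* position: a module
  # conserved in place (same label both sides) is plain conservation
  pairs <- Filter(function(e) e$module_labels[1] != e$module_labels[2], pairs)
  events <- c(
    detect_divergence_breakpoint(blocks, map_a, map_b, cc$breakpoint_tol_nt),
    detect_deletion_fusion(blocks, map_a, map_b, cc$deletion_tol_nt),
    pairs)
  structure(list(a_id = a$id, b_id = b$id, map_a = map_a, map_b = map_b,
                 blocks = blocks, events = events, config = config),
            class = "locus_comparison")
}

#' Flatten rearrangement events to a data frame
#' @param events list of `rearrangement_event`s (or a `locus_comparison`).
#' @return data.frame, one row per event.
#' @export
events_table <- function(events) {
  if (is(events, "locus_comparison")) events <- events$events
  rows <- lapply(events, function(e) data.frame(
    kind = e$kind,
    a_start = if (is.null(e$a_coords)) NA_integer_ else e$a_coords$start,
    a_end = if (is.null(e$a_coords)) NA_integer_ else e$a_coords$end,
    b_start = if (is.null(e$b_coords)) NA_integer_ else e$b_coords$start,
    b_end = if (is.null(e$b_coords)) NA_integer_ else e$b_coords$end,
    deletion_len_nt = e$deletion_len_nt,
    label_a = e$module_labels[1], label_b = e$module_labels[2],
    identity_pct = e$identity_pct,
    removed_labels = paste(e$removed_labels, collapse = ","),
    stringsAsFactors = FALSE))
  if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), a_start = integer(0), a_end = integer(0),
               b_start = integer(0), b_end = integer(0),
               deletion_len_nt = integer(0), label_a = character(0),
               label_b = character(0), identity_pct = numeric(0),
               removed_labels = character(0))
}

#' @export
print.locus_comparison <- function(x, ...) {
  cat(sprintf("<locus_comparison> %s vs %s\n", x$a_id, x$b_id))
  cat(sprintf("  %d block(s), %d event(s)\n", nrow(x$blocks), length(x$events)))
  ev <- events_table(x)
  if (nrow(ev)) print(ev, row.names = FALSE)
  invisible(x)
}
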