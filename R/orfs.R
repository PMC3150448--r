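STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Default ORF-calling and initiation-signal parameters
#'
#' `start_codons`: the standard bacterial initiator set.  `sd_consensus`:
#' the anti-Shine-Dalgarno hexamer; an ORF is deemed expressible when at
#' least `sd_min_score` of its 6 positions match within a window whose 3'
#' end lies `sd_window_min`..`sd_window_max` nt upstream of the start codon.
#' The window bounds quantify "properly spaced" and are exposed because no
#' standard value exists.
#'
#' @return Named list of parameters.
#' @export
orf_config <- function() {
  list(start_codons = c("ATG", "GTG", "TTG"),
       sd_consensus = "AGGAGG",
       sd_min_score = 4L,
       sd_window_min = 4L,
       sd_window_max = 20L,
       min_orf_len = 90L)
}

# codon vector of the coding strand from a frame offset (0-based)
frame_codons <- function(cs, offset) {
  n <- (nchar(cs) - offset) %/% 3L
  if (n <= 0L) return(character(0))
  starts <- offset + 1L + 3L * (seq_len(n) - 1L)
  substring(cs, starts, starts + 2L)
}

#' Enumerate open reading frames on both strands
#'
#' Reports all maximal stop-to-stop frame segments of at least `min_len_nt`,
#' each annotated with the most upstream in-frame start codon (from
#' `start_codons`) if one exists.  The reported interval runs from that
#' start codon (or the frame segment start if none) to the stop codon
#' inclusive; segments ending at the sequence edge without a stop are
#' reported with `stop_present = FALSE` (fragments at contig edges).
#' Segments carrying neither a stop nor any start codon are not reported.
#'
#' @param g a [genome_sequence()].
#' @param min_len_nt minimum reported ORF length in nt (>= 30).
#' @param config parameter list, see [orf_config()].
#' @return List of `orf_record` objects with fields `location`, `strand`,
#'   `frame_offset`, `has_start_codon`, `start_codon`, `stop_present`,
#'   `length_nt`.
#' @export
find_orfs <- function(g, min_len_nt = 90L, config = orf_config()) {
  stopifnot(is(g, "genome_sequence"), min_len_nt >= 30L)
  L <- g$length
  out <- list()
  for (strand in c("+", "-")) {
    cs <- if (strand == "+") g$seq else revcomp(g$seq)
    for (offset in 0:2) {
      codons <- frame_codons(cs, offset)
      nc <- length(codons)
      if (nc == 0L) next
      stop_idx <- which(codons %in% STOP_CODONS)
      seg_start <- c(1L, stop_idx + 1L)            # codon index after each stop
      seg_stop  <- c(stop_idx, NA_integer_)        # terminal stop codon index
      for (si in seq_along(seg_start)) {
        a <- seg_start[si]; sc <- seg_stop[si]
        b <- if (is.na(sc)) nc else sc             # last codon incl. stop
        if (a > b) next
        body_end <- if (is.na(sc)) b else sc - 1L  # codons before the stop
        starts_here <- if (a <= body_end)
          which(codons[a:body_end] %in% config$start_codons) else integer(0)
        has_start <- length(starts_here) > 0L
        if (!has_start && is.na(sc)) next          # no signal at all
        first <- if (has_start) a + starts_here[1] - 1L else a
        cs0 <- offset + 3L * (first - 1L)          # 0-based coding-strand coords
        cs1 <- offset + 3L * b
        len <- cs1 - cs0
        if (len < min_len_nt) next
        loc <- if (strand == "+") interval(cs0, cs1, "+")
               else interval(L - cs1, L - cs0, "-")
        out[[length(out) + 1L]] <- structure(list(
          location = loc, strand = strand, frame_offset = offset,
          has_start_codon = has_start,
          start_codon = if (has_start) codons[first] else NA_character_,
          stop_present = !is.na(sc),
          length_nt = len), class = "orf_record")
      }
    }
  }
  ord <- order(vapply(out, function(o) o$location$start, integer(1)),
               vapply(out, function(o) o$strand, character(1)))
  out[ord]
}

# position of the ORF start on the coding strand (0-based)
orf_cs_start <- function(orf, L) {
  if (orf$strand == "+") orf$location$start else L - orf$location$end
}

#' Score the Shine-Dalgarno signal upstream of an ORF start
#'
#' Slides the 6-mer anti-SD consensus over the coding-strand window whose
#' spacing (distance from the consensus 3' end to the start codon) ranges
#' `sd_window_min`..`sd_window_max` nt, and returns the maximum number of
#' matching positions; ties are broken toward the smaller spacing.
#'
#' @param g a [genome_sequence()].
#' @param orf an `orf_record` with `has_start_codon = TRUE`.
#' @param config parameter list, see [orf_config()].
#' @return `sd_match` list with `best_score`, `spacing`, `window_searched`.
#' @export
score_sd <- function(g, orf, config = orf_config()) {
  if (!isTRUE(orf$has_start_codon)) {
    stop("score_sd requires an ORF with a start codon", call. = FALSE)
  }
  cs <- if (orf$strand == "+") g$seq else revcomp(g$seq)
  start0 <- orf_cs_start(orf, g$length)
  cons <- strsplit(config$sd_consensus, "")[[1]]
  klen <- length(cons)
  best_score <- 0L; best_spacing <- NA_integer_
  for (s in config$sd_window_min:config$sd_window_max) {
    a <- start0 - s - klen            # 0-based window start
    if (a < 0L) next
    win <- strsplit(substr(cs, a + 1L, a + klen), "")[[1]]
    sc <- sum(win == cons)
    if (sc > best_score) { best_score <- sc; best_spacing <- s }
  }
  structure(list(best_score = as.integer(best_score), spacing = best_spacing,
                 window_searched = c(config$sd_window_min, config$sd_window_max)),
            class = "sd_match")
}

#' Classify an ORF as expressible or fragment
#'
#' An ORF is expressible when it has a start codon and an SD match of at
#' least `sd_min_score`; otherwise it is a fragment — the criterion that
#' separates translatable genes from orphan toxin-fragment ORFs, which
#' generally lack translation-initiation signals.
#'
#' @param orf an `orf_record`.
#' @param sd the [score_sd()] result, or `NULL` when there is no start codon.
#' @param sd_min minimum SD score (matched positions out of 6).
#' @return `"expressible"` or `"fragment"`.
#' @export
classify_initiation <- function(orf, sd = NULL, sd_min = orf_config()$sd_min_score) {
  if (!isTRUE(orf$has_start_codon)) return("fragment")
  if (is.null(sd) || sd$best_score < sd_min) return("fragment")
  "expressible"
}
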