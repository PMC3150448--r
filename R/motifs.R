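AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Compile a demarcation-motif specification
#'
#' Patterns use uppercase amino-acid letters for exact residues and `.`
#' (equivalently `x`) for "any single residue".  The two motifs that
#' demarcate polymorphic toxin C-termini in the field are built in:
#' `"VENN"` for CdiA and `"P....DP.GL"` (PxxxxDPxGL) for Rhs.
#'
#' @param name short motif name used in reports (e.g. `"VENN"`).
#' @param pattern peptide pattern string.
#' @return A `motif_spec` with fields `name`, `pattern` and `length`.
#' @export
compile_motif <- function(name, pattern) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(pattern), length(pattern) == 1L)
  if (!nzchar(pattern)) stop("motif pattern must be non-empty", call. = FALSE)
  pattern <- gsub("x", ".", pattern, fixed = TRUE)
  chars <- strsplit(pattern, "")[[1]]
  ok <- chars %in% c(AA_LETTERS, ".")
  if (!all(ok)) {
    stop(sprintf("motif '%s': illegal pattern character '%s'",
                 name, chars[!ok][1]), call. = FALSE)
  }
  if (length(chars) < 2L) stop("motif pattern must have length >= 2", call. = FALSE)
  structure(list(name = name, pattern = pattern, length = length(chars)),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> %s: %s (%d residues)\n", x$name, x$pattern, x$length))
  invisible(x)
}

#' Built-in demarcation motifs
#'
#' @return `motif_venn()`: the CdiA VENN tetrapeptide; `motif_dpxgl()`: the
#'   Rhs PxxxxDPxGL motif.
#' @export
motif_venn <- function() compile_motif("VENN", "VENN")

#' @rdname motif_venn
#' @export
motif_dpxgl <- function() compile_motif("DPxGL", "P....DP.GL")

#' Resolve a motif argument
#'
#' Accepts a `motif_spec`, a built-in name (`"VENN"`, `"DPxGL"`), or the
#' path of a YAML motif config with `name:` and `pattern:` entries.
#'
#' @param motif motif specification, name, or config path.
#' @return A `motif_spec`.
#' @export
resolve_motif <- function(motif) {
  if (is(motif, "motif_spec")) return(motif)
  stopifnot(is.character(motif), length(motif) == 1L)
  if (toupper(motif) == "VENN") return(motif_venn())
  if (toupper(motif) == "DPXGL") return(motif_dpxgl())
  if (file.exists(motif)) {
    cfg <- yaml::read_yaml(motif)
    if (is.null(cfg$name) || is.null(cfg$pattern)) {
      stop("motif config must provide 'name' and 'pattern'", call. = FALSE)
    }
    return(compile_motif(cfg$name, cfg$pattern))
  }
  stop("unknown motif '", motif, "' (not a built-in, not a config file)",
       call. = FALSE)
}

# Map a 1-based residue index in frame (offset, strand) to the 0-based
# half-open nucleotide interval of its codons on the genome.
residue_to_nt <- function(res_index, n_res, offset, strand, L) {
  p0 <- offset + 3L * (res_index - 1L)        # coding-strand coords
  p1 <- p0 + 3L * n_res
  if (strand == "+") c(p0, p1) else c(L - p1, L - p0)
}

#' Scan all six reading frames for a peptide motif
#'
#' Translates the locus in all six frames (bacterial code, ambiguity codons
#' as X) and reports every occurrence of the motif pattern, including
#' overlapping ones, mapped back to exact nucleotide coordinates.  The field
#' `ct_start` of each hit is the first nucleotide after the motif-encoding
#' span on the coding strand — the point where the variable toxin C-terminal
#' region (CT) begins: on `+` hits it equals `location$end`, on `-` hits
#' `location$start` (the CT extends leftward in genome coordinates).
#'
#' @param g a [genome_sequence()].
#' @param motif a [compile_motif()] spec (or anything [resolve_motif()] takes).
#' @return A list of `motif_hit` records sorted by `location$start` then
#'   strand, each with fields `motif`, `location`, `strand`, `frame_offset`,
#'   `peptide`, `ct_start`.
#' @export
scan_six_frames <- function(g, motif) {
  motif <- resolve_motif(motif)
  stopifnot(is(g, "genome_sequence"))
  if (g$length < 3L * motif$length) {
    stop("sequence shorter than one motif-encoding span", call. = FALSE)
  }
  rx <- paste0("(?=", motif$pattern, ")")
  hits <- list()
  for (strand in c("+", "-")) {
    for (offset in 0:2) {
      pep <- translate_frame(g, offset, strand)
      if (nchar(pep) < motif$length) next
      m <- gregexpr(rx, pep, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (pos in as.integer(m)) {
        span <- residue_to_nt(pos, motif$length, offset, strand, g$length)
        loc <- interval(span[1], span[2], strand)
        hits[[length(hits) + 1L]] <- structure(list(
          motif = motif$name,
          location = loc,
          strand = strand,
          frame_offset = offset,
          peptide = substr(pep, pos, pos + motif$length - 1L),
          ct_start = if (strand == "+") loc$end else loc$start),
          class = "motif_hit")
      }
    }
  }
  if (length(hits) == 0L) return(list())
  ord <- order(vapply(hits, function(h) h$location$start, integer(1)),
               vapply(hits, function(h) h$strand, character(1)))
  hits[ord]
}
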