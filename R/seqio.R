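#' @importFrom methods is
#' @importFrom stats runif setNames
#' @importFrom utils modifyList read.csv write.csv write.table packageVersion
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")

#' Construct a genome sequence record
#'
#' The basic unit of annotation: a named, uppercase nucleotide sequence.
#' Characters must belong to the IUPAC DNA alphabet (ACGT, N and ambiguity
#' codes); whitespace and gap characters are rejected rather than stripped,
#' since downstream coordinates would silently shift otherwise.
#'
#' @param id identifier string.
#' @param seq nucleotide string; case is folded to upper.
#' @param description optional free-text description.
#' @return An object of class `genome_sequence` with fields `id`,
#'   `description`, `seq` and `length`.
#' @export
genome_sequence <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")), seq)
  if (bad > 0L) {
    stop(sprintf(
      "record '%s': non-IUPAC nucleotide character '%s' at position %d",
      id, substr(seq, bad, bad), bad), call. = FALSE)
  }
  structure(
    list(id = id, description = description, seq = seq, length = nchar(seq)),
    class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s (%d nt)\n", x$id, x$length))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  head <- substr(x$seq, 1L, 60L)
  cat(" ", head, if (x$length > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Half-open genomic interval
#'
#' Internal coordinates are 0-based half-open throughout the package;
#' emitted files (GFF3, TSV reports) are 1-based inclusive.
#'
#' @param start,end 0-based start (inclusive) and end (exclusive).
#' @param strand `"+"` or `"-"`.
#' @return A list of class `interval`.
#' @export
interval <- function(start, end, strand = "+") {
  stopifnot(is.numeric(start), is.numeric(end), start >= 0, end > start,
            strand %in% c("+", "-"))
  structure(list(start = as.integer(start), end = as.integer(end),
                 strand = strand), class = "interval")
}

iv_len <- function(iv) iv$end - iv$start

#' Read a FASTA file of nucleotide loci
#'
#' Records are uppercased (soft-masking case is folded) and validated
#' against the IUPAC DNA alphabet; the error for an illegal character names
#' the offending record and offset.
#'
#' @param path path to a FASTA file with one or more records.
#' @return A list of [genome_sequence()] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- genome_sequence(ids[i], as.character(set[[i]]), descs[i])
  }
  out
}

#' Write genome sequences to FASTA
#'
#' @param seqs a `genome_sequence` or list thereof.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is(seqs, "genome_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in seqs) {
    header <- if (nzchar(g$description)) paste(g$id, g$description) else g$id
    writeLines(paste0(">", header), con)
    starts <- seq(1L, g$length, by = width)
    writeLines(substring(g$seq, starts, pmin(starts + width - 1L, g$length)), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string or genome sequence
#'
#' @param x a character string or `genome_sequence`.
#' @return Object of the same type with the reverse-complemented sequence.
#' @export
revcomp <- function(x) {
  if (is(x, "genome_sequence")) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x$seq)))
    return(genome_sequence(x$id, rc, x$description))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Bacterial/plant-plastid code (NCBI table 11).  Alternative initiation is
# the ORF caller's business, so no.init.codon keeps GTG/TTG as Val/Leu here.
GENETIC_CODE_11 <- Biostrings::getGeneticCode("11")

#' Translate one reading frame
#'
#' Translates `g` from `offset` (0, 1 or 2) to the last complete codon using
#' the bacterial genetic code (NCBI table 11).  For the minus strand the
#' reverse complement is translated with the same offset rule.  Stop codons
#' render as `"*"`; codons containing N or an ambiguity code render as `"X"`
#' and can therefore never match a motif residue.
#'
#' @param g a [genome_sequence()] (or plain nucleotide string).
#' @param offset frame offset, 0, 1 or 2.
#' @param strand `"+"` or `"-"`.
#' @return Peptide string of `floor((length - offset)/3)` residues.
#' @export
translate_frame <- function(g, offset = 0L, strand = "+") {
  stopifnot(offset %in% 0:2, strand %in% c("+", "-"))
  seq <- if (is(g, "genome_sequence")) g$seq else toupper(g)
  if (strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  n_res <- (nchar(seq) - offset) %/% 3L
  if (n_res <= 0L) return("")
  starts <- offset + 1L + 3L * (seq_len(n_res) - 1L)
  aa <- unname(GENETIC_CODE_11[substring(seq, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"   # codons containing N or ambiguity codes
  paste(aa, collapse = "")
}

# 0-based half-open -> GRanges (1-based inclusive)
iv_to_granges <- function(seqid, ivs, seqlen) {
  GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(
      start = vapply(ivs, function(iv) iv$start + 1L, integer(1)),
      end   = vapply(ivs, function(iv) iv$end, integer(1))),
    strand = vapply(ivs, function(iv) iv$strand, character(1)),
    seqlengths = setNames(seqlen, seqid))
}

#' Write a locus map as GFF3
#'
#' Emits `gene` (the full-length toxin gene), `module` (one grouping feature
#' per toxin/immunity module, with the positional o-label in `Name`),
#' `ct_region` and `immunity_orf` children (via `Parent`), and a `CDS` child
#' for the full-length gene.  Coordinates are converted from the package's
#' 0-based half-open convention to the 1-based inclusive GFF3 standard.
#'
#' @param locus_map a `locus_map` as returned by [scan_locus()].
#' @param path output path.
#' @export
write_gff3 <- function(locus_map, path) {
  stopifnot(is(locus_map, "locus_map"))
  ivs <- list(); meta <- list()
  add <- function(iv, type, id, name = NA_character_, parent = NA_character_,
                  phase = NA_integer_) {
    ivs[[length(ivs) + 1L]] <<- iv
    meta[[length(meta) + 1L]] <<- list(type = type, ID = id, Name = name,
                                       Parent = parent, phase = phase)
  }
  if (!is.null(locus_map$full_length_gene)) {
    gid <- paste0(locus_map$sequence_id, ":gene")
    add(locus_map$full_length_gene, "gene", gid, name = "full_length_gene")
    add(locus_map$full_length_gene, "CDS", paste0(gid, ":cds"), parent = gid,
        phase = 0L)
  }
  for (m in locus_map$modules) {
    mid <- paste0(locus_map$sequence_id, ":module:", m$label)
    span <- module_span(m)
    add(span, "module", mid, name = m$label)
    add(m$ct$location, "ct_region", paste0(mid, ":ct"), parent = mid)
    if (!is.null(m$immunity)) {
      add(m$immunity$location, "immunity_orf", paste0(mid, ":immunity"),
          parent = mid)
    }
  }
  if (length(ivs) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- iv_to_granges(locus_map$sequence_id, ivs, locus_map$sequence_length)
  S4Vectors::mcols(gr)$source <- "orphanscan"
  S4Vectors::mcols(gr)$type <- vapply(meta, `[[`, character(1), "type")
  S4Vectors::mcols(gr)$ID <- vapply(meta, `[[`, character(1), "ID")
  S4Vectors::mcols(gr)$Name <- vapply(meta, `[[`, character(1), "Name")
  S4Vectors::mcols(gr)$Parent <- vapply(meta, `[[`, character(1), "Parent")
  S4Vectors::mcols(gr)$phase <- vapply(meta, `[[`, integer(1), "phase")
  rtracklayer::export(gr, path, format = "gff3")
  # drop run-dependent pragmas so identical inputs give identical bytes
  lines <- readLines(path)
  writeLines(lines[!grepl("^##(date|source-version)", lines)], path)
  invisible(path)
}

#' Read back a GFF3 file written by [write_gff3()]
#'
#' Returns a data frame in the package's internal 0-based half-open
#' coordinates, for round-tripping and downstream tooling.
#'
#' @param path GFF3 path.
#' @return data.frame with columns type, start, end, strand, ID, Name, Parent.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- S4Vectors::mcols(gr)$Parent
  parent_chr <- if (is.null(parent)) rep(NA_character_, length(gr)) else
    vapply(as.list(parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  grab <- function(col) {
    v <- S4Vectors::mcols(gr)[[col]]
    if (is.null(v)) rep(NA_character_, length(gr)) else as.character(v)
  }
  data.frame(
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = grab("ID"), Name = grab("Name"), Parent = parent_chr,
    stringsAsFactors = FALSE)
}
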