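# Independent oracles: hand-written codon table, naive six-frame scan with
# coordinate back-mapping, and an exhaustive affine-gap DP aligner.  None of
# them share code with the package internals they check.

ORACLE_CODON <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIIMTTTTNNKKSSRR",   # ATT..AGG
    "VVVVAAAADDEEGGGG"),  # GTT..GGG
    "")[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  setNames(aa, codons)
})

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_translate <- function(seq, offset = 0L, strand = "+") {
  if (strand == "-") seq <- oracle_revcomp(seq)
  n <- (nchar(seq) - offset) %/% 3L
  if (n <= 0L) return("")
  starts <- offset + 1L + 3L * (seq_len(n) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- ORACLE_CODON[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# naive six-frame scan: translate, regex with lookahead, back-map residues
oracle_scan <- function(seq, pattern) {
  L <- nchar(seq)
  plen <- nchar(pattern)   # pattern uses only residue letters and "."
  hits <- NULL
  for (strand in c("+", "-")) for (off in 0:2) {
    pep <- oracle_translate(seq, off, strand)
    m <- gregexpr(paste0("(?=", pattern, ")"), pep, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (i in as.integer(m)) {
      p0 <- off + 3L * (i - 1L); p1 <- p0 + 3L * plen
      if (strand == "-") { tmp <- p0; p0 <- L - p1; p1 <- L - tmp }
      hits <- rbind(hits, data.frame(start = p0, end = p1, strand = strand,
                                     frame = off))
    }
  }
  if (is.null(hits)) return(data.frame(start = integer(0), end = integer(0),
                                       strand = character(0), frame = integer(0)))
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

hits_to_df <- function(hits) {
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0),
                                       strand = character(0), frame = integer(0)))
  df <- data.frame(
    start = vapply(hits, function(h) h$location$start, integer(1)),
    end = vapply(hits, function(h) h$location$end, integer(1)),
    strand = vapply(hits, function(h) h$strand, character(1)),
    frame = vapply(hits, function(h) h$frame_offset, integer(1)))
  df[order(df$start, df$strand), , drop = FALSE]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Exhaustive affine-gap global aligner for tiny inputs.  A gap of length
# k costs open + k * ext.  Returns the optimal score plus the set of
# (matches, columns) pairs attainable by co-optimal alignments, so identity
# can be checked without fixing an arbitrary tie-break.
oracle_nw <- function(a, b, sub, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sub[av[i], bv[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # enumerate co-optimal paths (bounded) collecting identity outcomes
  outcomes <- new.env()
  count <- 0L
  walk <- function(i, j, state, matches, cols) {
    if (count > 20000L) return()
    if (i == 0L && j == 0L && state == "M") {
      count <<- count + 1L
      assign(paste(matches, cols), TRUE, envir = outcomes)
      return()
    }
    val <- switch(state, M = M[i + 1, j + 1], X = X[i + 1, j + 1],
                  Y = Y[i + 1, j + 1])
    if (state == "M" && i > 0L && j > 0L) {
      s <- sub[av[i], bv[j]]
      hit <- as.integer(av[i] == bv[j])
      for (prev in c("M", "X", "Y")) {
        pv <- switch(prev, M = M[i, j], X = X[i, j], Y = Y[i, j])
        if (pv + s == val) walk(i - 1L, j - 1L, prev, matches + hit, cols + 1L)
      }
    } else if (state == "X" && i > 0L) {
      if (M[i, j + 1] - open - ext == val) walk(i - 1L, j, "M", matches, cols + 1L)
      if (X[i, j + 1] - ext == val) walk(i - 1L, j, "X", matches, cols + 1L)
    } else if (state == "Y" && j > 0L) {
      if (M[i + 1, j] - open - ext == val) walk(i, j - 1L, "M", matches, cols + 1L)
      if (Y[i + 1, j] - ext == val) walk(i, j - 1L, "Y", matches, cols + 1L)
    }
  }
  for (st in c("M", "X", "Y")) {
    v <- switch(st, M = M[n + 1, m + 1], X = X[n + 1, m + 1], Y = Y[n + 1, m + 1])
    if (v == best) walk(n, m, st, 0L, 0L)
  }
  keys <- ls(outcomes)
  parts <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  list(score = best,
       identities = unique(100 * parts[, 1] / parts[, 2]),
       lengths = unique(parts[, 2]))
}

nt_submatrix <- function() {
  b <- c("A", "C", "G", "T")
  m <- matrix(-1, 4, 4, dimnames = list(b, b)); diag(m) <- 1
  m
}

aa_submatrix <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# plain single deletion of [p, p+len) for rearrangement-recovery checks
plant_plain_deletion <- function(g, p, len) {
  genome_sequence(paste0(g$id, "_del"),
                  paste0(substr(g$seq, 1, p), substr(g$seq, p + len + 1, g$length)))
}

write_temp_fasta <- function(seqs, dir = tempdir()) {
  f <- tempfile(tmpdir = dir, fileext = ".fasta")
  write_fasta(seqs, f)
  f
}
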