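#' Pipeline configuration
#'
#' Bundles the parameters of every stage ([orf_config()],
#' [module_config()], [compare_config()]) with override validation:
#' unknown keys are rejected rather than silently ignored.
#'
#' @param ... named overrides, e.g. `orf = list(sd_min_score = 5)`.
#' @return Nested parameter list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(orf = orf_config(), module = module_config(),
                   compare = compare_config())
  overrides <- list(...)
  for (section in names(overrides)) {
    if (!section %in% names(defaults)) {
      stop("unknown config section '", section, "'", call. = FALSE)
    }
    bad <- setdiff(names(overrides[[section]]), names(defaults[[section]]))
    if (length(bad)) {
      stop("unknown config key(s) in '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[[section]] <- modifyList(defaults[[section]], overrides[[section]])
  }
  structure(defaults, class = c("pipeline_config", "list"))
}

# tiny FNV-1a hash for provenance lines (config and input fingerprints)
fnv1a <- function(x) {
  bytes <- if (is.raw(x)) as.integer(x) else utf8ToInt(paste(x, collapse = "\n"))
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

config_hash <- function(config) {
  flat <- unlist(config)
  fnv1a(paste(names(flat), flat, sep = "=", collapse = ";"))
}

file_checksum <- function(path) {
  fnv1a(readBin(path, "raw", n = file.size(path)))
}

provenance_lines <- function(config, inputs = character(0)) {
  c(sprintf("# orphanscan %s", as.character(packageVersion("orphanscan"))),
    sprintf("# config_hash %s", config_hash(config)),
    vapply(names(inputs), function(nm)
      sprintf("# input %s %s", nm, inputs[[nm]]), character(1)))
}

log_stage <- function(stage, detail, t0) {
  message(sprintf("[orphanscan] %-10s %s (%.2fs)", stage, detail,
                  as.numeric(Sys.time()) - t0))
}

#' Scan one or more loci from FASTA and write reports
#'
#' Runs [scan_locus()] on every record and writes, per record, a GFF3
#' feature file and a TSV module table into `out_dir`.  Progress is logged
#' to stderr; outputs are deterministic for identical inputs and config.
#'
#' @param fasta_path input FASTA (one locus per record).
#' @param out_dir output directory (created if needed).
#' @param motif motif spec, built-in name or config path.
#' @param config a [pipeline_config()].
#' @return (invisibly) the list of `locus_map`s.
#' @export
run_scan <- function(fasta_path, out_dir, motif = "VENN",
                     config = pipeline_config()) {
  t0 <- as.numeric(Sys.time())
  seqs <- read_fasta(fasta_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance_lines(config, c(fasta = file_checksum(fasta_path)))
  maps <- list()
  for (g in seqs) {
    map <- scan_locus(g, motif, config)
    stem <- file.path(out_dir, gsub("[^A-Za-z0-9._-]", "_", g$id))
    write_gff3(map, paste0(stem, ".gff3"))
    tsv <- paste0(stem, ".modules.tsv")
    writeLines(prov, tsv)
    suppressWarnings(
      write.table(as.data.frame(map), tsv, sep = "\t", quote = FALSE,
                  row.names = FALSE, append = TRUE))
    log_stage("scan", sprintf("%s: %d module(s), %d note(s)", g$id,
                              length(map$modules), length(map$notes)), t0)
    maps[[g$id]] <- map
  }
  invisible(maps)
}

#' Compare two loci from FASTA and write reports
#'
#' Scans both inputs (single-record FASTA each), computes anchored blocks
#' and rearrangement events, and writes `blocks.tsv`, `events.tsv` and a
#' human-readable `summary.txt` (with a provenance header: tool version,
#' config hash, input checksums) into `out_dir`.  Coordinates in the TSVs
#' are 1-based inclusive.
#'
#' @param fasta_a,fasta_b single-record FASTA paths (A is the reference
#'   arrangement for deletion calls).
#' @param out_dir output directory.
#' @param motif motif spec, built-in name or config path.
#' @param config a [pipeline_config()].
#' @return (invisibly) the `locus_comparison`.
#' @export
run_compare <- function(fasta_a, fasta_b, out_dir, motif = "VENN",
                        config = pipeline_config()) {
  t0 <- as.numeric(Sys.time())
  sa <- read_fasta(fasta_a); sb <- read_fasta(fasta_b)
  if (length(sa) != 1L || length(sb) != 1L) {
    stop("compare requires single-record FASTA inputs; extract one locus ",
         "per file first", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- compare_loci(sa[[1]], sb[[1]], motif, config)
  prov <- provenance_lines(config, c(a = file_checksum(fasta_a),
                                     b = file_checksum(fasta_b)))
  blocks <- cmp$blocks
  if (nrow(blocks)) {  # 0-based half-open -> 1-based inclusive
    blocks$q_start <- blocks$q_start + 1L
    blocks$s_start <- blocks$s_start + 1L
  }
  bl_path <- file.path(out_dir, "blocks.tsv")
  writeLines(prov, bl_path)
  suppressWarnings(write.table(blocks, bl_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  ev <- events_table(cmp)
  if (nrow(ev)) {
    ev$a_start <- ev$a_start + 1L
    ev$b_start <- ev$b_start + 1L
  }
  ev_path <- file.path(out_dir, "events.tsv")
  writeLines(prov, ev_path)
  suppressWarnings(write.table(ev, ev_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  writeLines(prov, con)
  writeLines(sprintf("comparison: %s (A, reference) vs %s (B)",
                     cmp$a_id, cmp$b_id), con)
  writeLines(sprintf("blocks: %d  events: %d", nrow(cmp$blocks),
                     length(cmp$events)), con)
  for (e in cmp$events) {
    writeLines(sprintf(
      "  %s  A[%s]  B[%s]  len=%s  modules=%s/%s  identity=%s",
      e$kind,
      if (is.null(e$a_coords)) "-" else
        paste0(e$a_coords$start + 1L, "..", e$a_coords$end),
      if (is.null(e$b_coords)) "-" else
        paste0(e$b_coords$start + 1L, "..", e$b_coords$end),
      if (is.na(e$deletion_len_nt)) "-" else e$deletion_len_nt,
      e$module_labels[1], e$module_labels[2],
      if (is.na(e$identity_pct)) "-" else sprintf("%.1f%%", e$identity_pct)), con)
  }
  close(con)
  log_stage("compare", sprintf("%d block(s), %d event(s)", nrow(cmp$blocks),
                               length(cmp$events)), t0)
  invisible(cmp)
}

#' Generate a synthetic locus and write FASTA, GFF3 and JSON truth
#'
#' @param spec a [synthetic_locus_spec()] (or YAML path with its fields).
#' @param out_dir output directory.
#' @return (invisibly) the `list(sequence, truth)` pair.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) {
    cfg <- yaml::read_yaml(spec)
    if (!is.null(cfg$motif) && is.character(cfg$motif)) {
      cfg$motif <- resolve_motif(cfg$motif)
    }
    spec <- do.call(synthetic_locus_spec, cfg)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_locus(spec)
  write_fasta(sim$sequence, file.path(out_dir, "locus.fasta"))
  write_gff3(truth_to_locus_map(sim$sequence, sim$truth),
             file.path(out_dir, "truth.gff3"))
  write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
  message(sprintf("[orphanscan] simulate   %s: %d nt, %d module(s)",
                  sim$sequence$id, sim$sequence$length,
                  length(sim$truth$modules)))
  invisible(sim)
}

#' Summarize a qPCR CSV and write the result
#'
#' @param csv_in input CSV (target, E_target, Ct_target, E_ref, Ct_ref,
#'   replicate).
#' @param csv_out output CSV (target, mean, sem, n).
#' @return (invisibly) the summary data.frame.
#' @export
run_qpcr <- function(csv_in, csv_out) {
  out <- qpcr_summary(csv_in)
  write.csv(out, csv_out, row.names = FALSE)
  invisible(out)
}
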