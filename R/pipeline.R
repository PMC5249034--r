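# One-command finishing pipeline: scaffold (reference or optical-map axis),
# merge dovetail neighbours, close gaps from a read consensus, set the
# replication start, and write reports. Deterministic: no randomness is
# used anywhere in the pipeline proper.

#' Configuration for the finishing pipeline
#'
#' All tunables of the underlying modules with their documented defaults.
#' Unknown names are rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated list of class `finish_config`.
#' @export
finish_config <- function(...) {
  cfg <- list(
    word_size = 11L,          # seed word length (blastn-like default)
    min_identity = 0.8,       # placement / anchoring identity
    merge_min_identity = 0.95,
    min_overlap = 20L,        # dovetail merge minimum overlap (bp)
    flank_len = 3000L,        # flank window for merging and gap closing (bp)
    min_depth = 3L,           # depth required for a closed gap base
    pad = 500L,               # reference context around gap anchors (bp)
    end_slack = 10L,          # dovetail / anchor end tolerance (bp)
    ambiguity_margin = 0.05,  # relative score margin for anchor ambiguity
    min_coverage_frac = 0.4,  # contig placement coverage rule
    min_contig_len = 200L,    # contigs shorter than this stay unplaced
    gap_policy = "axis_distance",
    fixed_gap = 100L,         # unknown-gap convention (N)
    min_gap = 1L,
    probe_len = 2000L,        # replication-start probe (bp)
    circular = TRUE,
    set_origin = TRUE,
    enzyme_name = "KpnI",
    enzyme_site = "GGTACC",
    enzyme_cut_offset = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$word_size >= 4L, cfg$min_identity > 0, cfg$min_identity <= 1,
            cfg$merge_min_identity > 0, cfg$merge_min_identity <= 1,
            cfg$min_overlap >= 1L, cfg$flank_len >= 100L, cfg$min_depth >= 1L,
            cfg$pad >= 0L, cfg$min_coverage_frac > 0, cfg$min_coverage_frac <= 1,
            cfg$gap_policy %in% c("axis_distance", "fixed"),
            cfg$fixed_gap >= 1L, cfg$min_gap >= 1L, cfg$probe_len >= 100L)
  structure(cfg, class = "finish_config")
}

#' Read a YAML-like `key: value` config file
#'
#' One `key: value` pair per line; `#` comments ignored. Values are coerced
#' to numeric or logical where possible.
#'
#' @param path Path to the config file.
#' @param ... Overrides applied after the file (flags win over the file).
#' @return A [finish_config()].
#' @export
read_finish_config <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = ":"))
    if (v %in% c("true", "TRUE", "yes")) return(TRUE)
    if (v %in% c("false", "FALSE", "no")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(if (num == round(num)) as.integer(num) else num)
    v
  })
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  over <- list(...)
  vals[names(over)] <- over
  do.call(finish_config, vals)
}

usage_error <- function(msg) {
  stop(structure(class = c("finishr_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Run the full finishing pipeline
#'
#' Executes the finishing flow: (i) order and orient contigs along exactly
#' one axis (reference genome or optical-map placement report) and build an
#' N-gapped scaffold; (ii) merge neighbours with dovetail overlaps into
#' supercontigs; (iii) when reads and a reference are supplied, close each
#' remaining gap by flank anchoring and consensus extraction; (iv) rotate
#' the curated circular genome to the reference replication start; (v) write
#' statistics. Per-gap failures become report rows, not errors.
#'
#' @param contigs_fasta Path to the draft contigs FASTA.
#' @param out_dir Output directory (created if needed).
#' @param reference_fasta Path to a reference genome FASTA (reference axis).
#' @param map_report Path to a placement-report TSV (optical-map axis).
#'   Exactly one of `reference_fasta`/`map_report` must be given.
#' @param reads_fastq Optional path to single-end FASTQ reads (enables gap
#'   closing; requires the reference axis).
#' @param config A [finish_config()].
#' @return Invisibly, a list with the scaffold, placements, merges, gap
#'   resolutions, curated genome string and metrics. Files written to
#'   `out_dir`: `scaffolds.fasta`, `scaffolds.agp`, `placements.tsv`,
#'   `gaps.tsv`, `metrics.json`, `n_report.tsv`, `curated_genome.fasta`.
#' @export
run_finish <- function(contigs_fasta, out_dir, reference_fasta = NULL,
                       map_report = NULL, reads_fastq = NULL,
                       config = finish_config()) {
  if (is.null(reference_fasta) == is.null(map_report)) {
    usage_error("exactly one of reference_fasta or map_report must be supplied")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- read_fasta(contigs_fasta)
  message("[finishr] loaded ", nrow(contigs), " contig(s)")

  reference <- NULL
  if (!is.null(reference_fasta)) {
    ref_set <- read_fasta(reference_fasta)
    reference <- ref_set$seq[1]
    ord <- order_contigs_by_reference(
      contigs, reference,
      min_coverage_frac = config$min_coverage_frac,
      min_contig_len = config$min_contig_len,
      word_size = config$word_size, min_identity = config$min_identity,
      ambiguity_margin = config$ambiguity_margin)
    evidence <- "align_genus"
  } else {
    report <- read_placement_report(map_report)
    ord <- order_contigs_by_map_report(report, contigs)
    evidence <- "map"
  }
  message("[finishr] placed ", nrow(ord$placements), " contig(s), ",
          length(ord$unplaced), " unplaced")
  sc <- build_scaffold(ord$placements, contigs,
                       gap_policy = config$gap_policy,
                       fixed_gap = config$fixed_gap, min_gap = config$min_gap,
                       circular = config$circular)

  mg <- merge_neighbor_contigs(sc, contigs,
                               min_overlap = config$min_overlap,
                               min_identity = config$merge_min_identity,
                               flank_len = config$flank_len,
                               word_size = config$word_size,
                               end_slack = config$end_slack)
  message("[finishr] ", nrow(mg$merges), " dovetail merge(s)")
  sc <- mg$scaffold
  work <- mg$contigs

  # gap closing
  comp <- sc$components
  gaps <- data.frame(left_id = character(0), right_id = character(0),
                     status = character(0), method = character(0),
                     fill_len = integer(0), min_depth = integer(0),
                     reason = character(0))
  resolutions <- list()
  reads <- if (!is.null(reads_fastq)) read_fastq(reads_fastq) else NULL
  parts <- contig_seq(work, comp$contig_id[1])
  if (nrow(comp) > 1L) {
    for (i in seq_len(nrow(comp) - 1L)) {
      left <- contig_seq(work, comp$contig_id[i])
      right <- contig_seq(work, comp$contig_id[i + 1L])
      if (!is.null(reads) && !is.null(reference)) {
        res <- close_gap(left, right, reference, reads,
                         flank_len = config$flank_len, pad = config$pad,
                         min_depth = config$min_depth,
                         min_identity = config$min_identity,
                         end_slack = config$end_slack)
      } else {
        res <- structure(list(status = "unresolved", fill_seq = "",
                              support = 0L, method = "none",
                              reason = "no reads/reference supplied"),
                         class = "gap_resolution")
      }
      resolutions[[i]] <- res
      gaps <- rbind(gaps, data.frame(
        left_id = comp$contig_id[i], right_id = comp$contig_id[i + 1L],
        status = res$status, method = res$method,
        fill_len = nchar(res$fill_seq), min_depth = res$support,
        reason = res$reason))
      joint <- if (res$status %in% c("closed", "partial")) {
        res$fill_seq
      } else {
        strrep("N", max(comp$gap_after[i], 1L, na.rm = TRUE))
      }
      parts <- paste0(parts, joint, right)
    }
  }
  message("[finishr] gaps: ", sum(gaps$status == "closed"), " closed, ",
          sum(gaps$status == "partial"), " partial, ",
          sum(gaps$status == "unresolved"), " unresolved")
  curated <- parts

  if (!is.null(reference) && isTRUE(config$set_origin) &&
      isTRUE(config$circular)) {
    curated <- tryCatch(
      set_origin(curated, reference, probe_len = config$probe_len,
                 min_identity = config$min_identity),
      error = function(e) {
        message("[finishr] origin not set: ", conditionMessage(e))
        curated
      })
  }

  # outputs
  write_fasta(data.frame(id = sc$id, seq = sc$sequence),
              file.path(out_dir, "scaffolds.fasta"))
  write_agp(sc, file.path(out_dir, "scaffolds.agp"), evidence = evidence)
  write_placement_report(ord$placements, file.path(out_dir, "placements.tsv"))
  write.table(gaps, file.path(out_dir, "gaps.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  curated_set <- data.frame(id = "curated_genome", seq = curated)
  metrics <- assembly_metrics(curated_set)
  write_metrics_json(metrics, file.path(out_dir, "metrics.json"))
  nrep <- unknown_nucleotide_report(curated_set)
  write.table(nrep$summary, file.path(out_dir, "n_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(curated_set, file.path(out_dir, "curated_genome.fasta"))

  invisible(list(scaffold = sc, placements = ord$placements,
                 unplaced = ord$unplaced, merges = mg$merges, gaps = gaps,
                 resolutions = resolutions, curated_genome = curated,
                 metrics = metrics))
}

#' Identity between two assemblies via syntenic blocks
#'
#' Total matched bases over syntenic blocks divided by the longer sequence
#' length: 1.0 for identical sequences, and a conservative lower bound on
#' per-base identity otherwise.
#'
#' @param a,b DNA strings.
#' @param min_block Minimum syntenic block (default 1000).
#' @return A fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b, min_block = 1000L) {
  blocks <- syntenic_blocks(a, b, min_block = min_block)
  if (nrow(blocks) == 0L) return(0)
  sum(blocks$identity * blocks$length) / max(nchar(a), nchar(b))
}
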