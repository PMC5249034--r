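# Assembly metrics, unknown-nucleotide reporting, and assembly-vs-assembly
# comparison export.

#' Standard assembly metrics
#'
#' N50 is the largest length L such that contigs of length >= L sum to at
#' least half of the total assembly length; N90 likewise with 90%.
#'
#' @param contigs Contig table (`id`, `seq`).
#' @return A list of class `assembly_metrics`: `n_contigs`, `total_len`,
#'   `largest`, `n50`, `n90`, `gc_frac`, `n_count` and `gap_intervals`
#'   (a `data.frame` of N runs: `seq_id`, `start`, `end`, 0-based
#'   half-open).
#' @export
assembly_metrics <- function(contigs) {
  contigs <- as_contig_set(contigs)
  if (nrow(contigs) == 0L) stop("no contigs")
  lens <- nchar(contigs$seq)
  gaps <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i) {
    r <- n_runs(contigs$seq[i])
    if (nrow(r) == 0L) return(NULL)
    cbind(seq_id = contigs$id[i], r)
  }))
  if (is.null(gaps)) {
    gaps <- data.frame(seq_id = character(0), start = integer(0),
                       end = integer(0))
  }
  structure(list(
    n_contigs = nrow(contigs),
    total_len = sum(lens),
    largest = max(lens),
    n50 = nx_length(lens, 0.5),
    n90 = nx_length(lens, 0.9),
    gc_frac = gc_fraction(contigs$seq),
    n_count = sum(nchar(gsub("[^N]", "", contigs$seq))),
    gap_intervals = gaps
  ), class = "assembly_metrics")
}

# Nx: largest L with sum(lengths >= L) >= frac * total.
nx_length <- function(lens, frac) {
  lens <- sort(lens, decreasing = TRUE)
  idx <- which(cumsum(as.numeric(lens)) >= frac * sum(as.numeric(lens)))[1]
  lens[idx]
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(paste0("<assembly_metrics> %d contig(s), total %d bp, ",
                     "largest %d, N50 %d, N90 %d, GC %.3f, %d N\n"),
              x$n_contigs, x$total_len, x$largest, x$n50, x$n90,
              x$gc_frac, x$n_count))
  invisible(x)
}

#' Write assembly metrics as JSON
#'
#' @param metrics An [assembly_metrics()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics)[c("n_contigs", "total_len", "largest",
                                          "n50", "n90", "gc_frac", "n_count")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-scaffold report of undetermined (N) nucleotides
#'
#' @param scaffolds Contig table of scaffold sequences (`id`, `seq`).
#' @return A list: `summary` with one row per scaffold (`id`, `length`,
#'   `n_count`, `n_frac`, `n_run_count`) plus a `TOTAL` row; `runs` listing
#'   every N run (`id`, `start`, `end`, `length`, 0-based half-open);
#'   `run_length_hist` a table of run lengths.
#' @export
unknown_nucleotide_report <- function(scaffolds) {
  scaffolds <- as_contig_set(scaffolds)
  runs <- do.call(rbind, lapply(seq_len(nrow(scaffolds)), function(i) {
    r <- n_runs(scaffolds$seq[i])
    if (nrow(r) == 0L) return(NULL)
    data.frame(id = scaffolds$id[i], start = r$start, end = r$end,
               length = r$end - r$start)
  }))
  if (is.null(runs)) {
    runs <- data.frame(id = character(0), start = integer(0),
                       end = integer(0), length = integer(0))
  }
  per <- data.frame(
    id = scaffolds$id,
    length = nchar(scaffolds$seq),
    n_count = nchar(gsub("[^N]", "", scaffolds$seq))
  )
  per$n_frac <- per$n_count / per$length
  per$n_run_count <- vapply(per$id, function(i) sum(runs$id == i), integer(1))
  total <- data.frame(id = "TOTAL", length = sum(per$length),
                      n_count = sum(per$n_count),
                      n_frac = sum(per$n_count) / sum(per$length),
                      n_run_count = nrow(runs))
  list(summary = rbind(per, total), runs = runs,
       run_length_hist = table(runs$length))
}

#' Compare two single-sequence assemblies via syntenic blocks
#'
#' Reports the syntenic blocks between the old (`a`) and new (`b`) assembly,
#' the length difference (new minus old), the intervals of the new assembly
#' not covered by any block ("undetected" regions), and blocks that are
#' inverted or out of order (candidate mis-assemblies; reported, not
#' adjudicated).
#'
#' @param asm_old,asm_new Single DNA strings.
#' @param min_block Minimum syntenic block length (default 1000).
#' @return A list: `blocks` (see [syntenic_blocks()]; `a` = old, `b` = new),
#'   `length_diff`, `uncovered_new` (`data.frame` of 0-based half-open
#'   intervals), `candidate_misassemblies` (block rows flagged `inversion`
#'   and/or `out_of_order`).
#' @export
compare_assemblies <- function(asm_old, asm_new, min_block = 1000L) {
  blocks <- syntenic_blocks(asm_old, asm_new, min_block = min_block)
  len_new <- nchar(asm_new)
  covered <- IRanges::reduce(IRanges::IRanges(blocks$b_start + 1L, blocks$b_end))
  uncovered <- IRanges::setdiff(IRanges::IRanges(1L, len_new), covered)
  uncovered_df <- data.frame(start = BiocGenerics::start(uncovered) - 1L,
                             end = BiocGenerics::end(uncovered))
  flags <- blocks
  flags$inversion <- flags$strand == "-"
  flags$out_of_order <- FALSE
  if (nrow(flags) > 1L) {
    b_rank <- rank(flags$b_start)
    flags$out_of_order <- b_rank != seq_len(nrow(flags))
  }
  list(blocks = blocks,
       length_diff = len_new - nchar(asm_old),
       uncovered_new = uncovered_df,
       candidate_misassemblies = flags[flags$inversion | flags$out_of_order, ])
}
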