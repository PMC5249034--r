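# External representations: FASTA, FASTQ (Phred+33), AGP v2.1, the
# placement-report TSV and the restriction-map TSV.

#' Read a multi-record FASTA file into a contig table
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}` is
#' replaced by `N` (a warning reports how many bases were squashed).
#'
#' @param path Path to a FASTA file.
#' @param source Provenance tag stored with each record (default: the file
#'   name).
#' @return A `data.frame` with columns `id`, `seq`, `source`.
#' @export
read_fasta <- function(path, source = basename(path)) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  ids <- sub("[[:space:]].*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[1])
  norm <- normalize_dna(as.character(set))
  if (norm$n_replaced > 0L) {
    warning(norm$n_replaced, " non-ACGTN base(s) replaced by N in ", path)
  }
  as_contig_set(data.frame(id = ids, seq = unname(norm$seq), source = source))
}

#' Write a contig table as FASTA
#'
#' @param records A `data.frame` with columns `id` and `seq`.
#' @param path Output path.
#' @param line_width Sequence line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  stopifnot(line_width >= 1L)
  if (nrow(records) == 0L) stop("nothing to write")
  records <- as_contig_set(records)
  set <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

#' Read single-end FASTQ (4-line records, Phred+33)
#'
#' @param path Path to a FASTQ file.
#' @return A list of class `read_set` with elements `id` (character), `seq`
#'   (character) and `qual` (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) && lines[length(lines)] == "") lines <- lines[-length(lines)]
  if (length(lines) == 0L) {
    return(structure(list(id = character(0), seq = character(0), qual = list()),
                     class = "read_set"))
  }
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (!all(startsWith(ids, "@"))) stop("malformed FASTQ header in ", path)
  ids <- sub("[[:space:]].*$", "", substring(ids, 2L))
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) stop("length mismatch ", ids[bad[1]])
  qual <- lapply(quals, function(q) as.integer(charToRaw(q)) - 33L)
  rng <- range(unlist(qual, use.names = FALSE), na.rm = TRUE)
  if (length(unlist(qual)) && (rng[1] < 0L || rng[2] > 60L)) {
    stop("quality out of range [0,60] (is this Phred+33?)")
  }
  norm <- normalize_dna(seqs)
  structure(list(id = ids, seq = unname(norm$seq), qual = qual),
            class = "read_set")
}

#' Write a read set as FASTQ (Phred+33)
#'
#' @param reads A `read_set` (see [read_fastq()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  qs <- vapply(reads$qual, function(q) rawToChar(as.raw(q + 33L)), character(1))
  out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qs))
  writeLines(out, path)
  invisible(path)
}

#' Read an optical-map placement report
#'
#' Tab-separated with header
#' `contig_id  map_start  map_end  strand  rank`; lines starting with `#` are
#' ignored. Coordinates are 0-based half-open on the map axis. Rows are
#' returned sorted by rank; ranks must form a permutation of `1..n`.
#'
#' @param path Path to the TSV report.
#' @return A `data.frame` with the five columns above.
#' @export
read_placement_report <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("contig_id", "map_start", "map_end", "strand", "rank")
  if (!all(need %in% names(df))) {
    stop("placement report must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (any(!df$strand %in% c("+", "-"))) stop("invalid strand")
  if (anyDuplicated(df$contig_id)) {
    stop("duplicate contig_id ", df$contig_id[duplicated(df$contig_id)][1])
  }
  if (any(df$map_start >= df$map_end)) stop("map_start must be < map_end")
  if (anyDuplicated(df$rank)) stop("rank collision")
  if (!setequal(df$rank, seq_len(nrow(df)))) {
    stop("ranks must form a permutation of 1..", nrow(df))
  }
  df <- df[order(df$rank), ]
  rownames(df) <- NULL
  df
}

#' Write a placement table in the placement-report TSV dialect
#'
#' @param placements A `data.frame` with at least `contig_id`, `start`/`end`
#'   (or `map_start`/`map_end`), `strand`, `rank`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placement_report <- function(placements, path) {
  df <- placements
  if ("start" %in% names(df) && !"map_start" %in% names(df)) {
    df$map_start <- df$start
    df$map_end <- df$end
  }
  keep <- c("contig_id", "map_start", "map_end", "strand", "rank",
            intersect("coverage_frac", names(df)))
  write.table(df[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a restriction map
#'
#' @param enzyme_name Enzyme name.
#' @param fragment_sizes Ordered positive integer fragment sizes (bp).
#' @param circular Is the molecule circular?
#' @return An object of class `restriction_map`.
#' @export
restriction_map <- function(enzyme_name, fragment_sizes, circular = FALSE) {
  fragment_sizes <- as.integer(fragment_sizes)
  if (length(fragment_sizes) == 0L) stop("empty map")
  if (any(fragment_sizes < 1L)) stop("fragment sizes must be >= 1")
  structure(list(enzyme = enzyme_name, sizes = fragment_sizes,
                 circular = isTRUE(circular)),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat(sprintf("<restriction_map> enzyme=%s %s, %d fragments, total %d bp\n",
              x$enzyme, if (x$circular) "circular" else "linear",
              length(x$sizes), sum(x$sizes)))
  invisible(x)
}

#' Read a restriction-map TSV
#'
#' Header lines `enzyme=<name>` and `circular=<true|false>`, then one
#' fragment size per line. `#` comment lines are ignored.
#'
#' @param path Path to the file.
#' @return A [restriction_map()].
#' @export
read_restriction_map <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  enz <- sub("^enzyme=", "", grep("^enzyme=", lines, value = TRUE))
  circ <- sub("^circular=", "", grep("^circular=", lines, value = TRUE))
  if (length(enz) != 1L || length(circ) != 1L) {
    stop("restriction-map file needs one enzyme= and one circular= header")
  }
  sizes <- suppressWarnings(as.numeric(lines[!grepl("=", lines)]))
  if (length(sizes) == 0L) stop("empty map")
  if (anyNA(sizes) || any(sizes <= 0)) stop("fragment sizes must be positive integers")
  restriction_map(enz, sizes, circular = tolower(circ) %in% c("true", "t", "1"))
}

#' Write a restriction map in the restriction-map TSV dialect
#'
#' @param map A [restriction_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restriction_map <- function(map, path) {
  stopifnot(inherits(map, "restriction_map"))
  writeLines(c(paste0("enzyme=", map$enzyme),
               paste0("circular=", tolower(map$circular)),
               as.character(map$sizes)), path)
  invisible(path)
}

#' Write a scaffold layout as AGP v2.1
#'
#' Component lines are type `W`; gap lines are type `N` with gap type
#' `scaffold`, linkage `yes` and linkage evidence `align_genus` (reference
#' axis) or `map` (optical-map axis). AGP coordinates are 1-based inclusive.
#'
#' @param scaffold A `scaffold` object (see [build_scaffold()]).
#' @param path Output path.
#' @param contigs Contig table supplying component lengths (defaults to the
#'   lengths recorded in the scaffold).
#' @param evidence Linkage evidence tag, `"align_genus"` or `"map"`.
#' @return `path`, invisibly.
#' @export
write_agp <- function(scaffold, path, contigs = NULL, evidence = "align_genus") {
  stopifnot(inherits(scaffold, "scaffold"))
  comp <- scaffold$components
  lens <- comp$length
  if (!is.null(contigs)) lens <- nchar(contig_seq(contigs, comp$contig_id))
  lines <- character(0)
  pos <- 0L  # 0-based cursor on the object
  part <- 0L
  for (i in seq_len(nrow(comp))) {
    part <- part + 1L
    beg <- pos + 1L
    end <- pos + lens[i]
    if (end < beg) stop("overlapping component spans in scaffold ", scaffold$id)
    lines <- c(lines, paste(scaffold$id, beg, end, part, "W", comp$contig_id[i],
                            1L, lens[i], comp$strand[i], sep = "\t"))
    pos <- end
    gap <- comp$gap_after[i]
    if (i < nrow(comp) && !is.na(gap) && gap > 0L) {
      part <- part + 1L
      lines <- c(lines, paste(scaffold$id, pos + 1L, pos + gap, part, "N", gap,
                              "scaffold", "yes", evidence, sep = "\t"))
      pos <- pos + gap
    }
  }
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' Read an AGP file and rebuild the scaffold it describes
#'
#' @param path Path to an AGP v2.1 file describing one object.
#' @param contigs Contig table providing the component sequences.
#' @return A `scaffold` object whose `sequence` is regenerated from the
#'   components and gap lengths.
#' @export
read_agp <- function(path, contigs) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  obj <- unique(vapply(f, `[`, character(1), 1L))
  if (length(obj) != 1L) stop("read_agp handles a single object, found ", length(obj))
  comp <- data.frame(contig_id = character(0), strand = character(0),
                     gap_after = integer(0), length = integer(0))
  for (x in f) {
    if (x[5] == "W") {
      comp <- rbind(comp, data.frame(
        contig_id = x[6], strand = x[9], gap_after = NA_integer_,
        length = as.integer(x[8]) - as.integer(x[7]) + 1L))
    } else if (x[5] %in% c("N", "U")) {
      if (nrow(comp) == 0L) stop("AGP gap line before any component")
      comp$gap_after[nrow(comp)] <- as.integer(x[6])
    } else {
      stop("unsupported AGP component type ", x[5])
    }
  }
  comp$gap_after[is.na(comp$gap_after) & seq_len(nrow(comp)) < nrow(comp)] <- 0L
  new_scaffold(obj, comp, contigs, circular = FALSE)
}
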