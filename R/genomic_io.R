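#' Read a catalog of robust TSS clusters (RTSSs) from a BED6-like file
#'
#' Each line holds `chrom start end id score strand` (whitespace separated,
#' 0-based half-open coordinates, strand `+` or `-`). The profile anchor is the
#' interval midpoint, `floor((start + end) / 2)`.
#'
#' @param path path to a BED6-like file.
#' @return an `rtss_catalog`: a data.frame with columns `id`, `chrom`, `start`,
#'   `end`, `strand`, `anchor`, in file order.
#' @export
read_rtss_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    warning("empty RTSS catalog: ", path)
    return(rtss_catalog(data.frame(
      id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character()
    )))
  }
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  lineno <- which(keep)
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) {
    stop("malformed RTSS line ", lineno[bad[1L]], ": fewer than 6 fields")
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed RTSS line ", lineno[which(is.na(start) | is.na(end))[1L]],
         ": non-integer coordinates")
  }
  rtss_catalog(data.frame(
    id = m[, 4L], chrom = m[, 1L], start = start, end = end,
    strand = m[, 6L], stringsAsFactors = FALSE
  ))
}

#' Construct and validate an RTSS catalog
#'
#' @param df data.frame with columns `id`, `chrom`, `start`, `end`, `strand`.
#' @return validated catalog with `anchor` column added.
#' @export
rtss_catalog <- function(df) {
  required <- c("id", "chrom", "start", "end", "strand")
  if (!all(required %in% names(df))) {
    stop("catalog requires columns: ", paste(required, collapse = ", "))
  }
  if (nrow(df)) {
    if (any(df$start < 0L)) stop("negative start coordinate")
    if (any(df$start >= df$end)) stop("start must be < end (0-based half-open)")
    if (!all(df$strand %in% c("+", "-"))) stop("RTSS strand must be '+' or '-'")
    if (anyDuplicated(df$id)) {
      stop("duplicate RTSS id: ", df$id[duplicated(df$id)][1L])
    }
  }
  df$anchor <- as.integer((df$start + df$end) %/% 2L)
  rownames(df) <- NULL
  class(df) <- c("rtss_catalog", "data.frame")
  df
}

#' Write an RTSS catalog as BED6
#'
#' @param catalog an `rtss_catalog`.
#' @param path output path.
#' @export
write_rtss_catalog <- function(catalog, path) {
  df <- data.frame(catalog$chrom, catalog$start, catalog$end, catalog$id,
                   0L, catalog$strand)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read enrichment peaks (broadPeak / narrowPeak / BED)
#'
#' Only the first three columns are interpreted; score, signal and summit
#' columns are ignored. Peaks are never merged on read. Intervals are returned
#' sorted by start within each chromosome.
#'
#' @param path path to a peak file with >= 3 tab/space-separated columns.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 3L)) {
    stop("malformed peak line ", which(lengths(fields) < 3L)[1L],
         ": fewer than 3 fields")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:3))
  df <- data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
                   end = as.integer(m[, 3L]), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("peak with start >= end")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intervals as BED3
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_peaks <- function(intervals, path) {
  data.table::fwrite(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read generic BED intervals (CpG islands, excludable regions, ...)
#'
#' @param path BED file with >= 3 columns; strand taken from column 6 if present.
#' @return data.frame `chrom`, `start`, `end` and `strand` when available.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- min(lengths(fields))
  if (n < 3L) stop("BED line with fewer than 3 fields")
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (n >= 6L) df$strand <- vapply(fields, `[`, "", 6L)
  if (any(df$start >= df$end)) stop("BED interval with start >= end")
  df
}

#' Read a gene annotation table
#'
#' refFlat-like TSV with columns `gene_id`, `chrom`, `strand`, `txStart`,
#' `txEnd` (0-based half-open). The TSS is `txStart` for `+` genes and
#' `txEnd - 1` for `-` genes.
#'
#' @param path path to the TSV (with header).
#' @return data.frame with the five columns plus a computed `tss` column.
#' @export
read_gene_annotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  required <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
  if (!all(required %in% names(df))) {
    stop("gene annotation requires columns: ", paste(required, collapse = ", "))
  }
  gene_annotation(df[, required])
}

#' Validate a gene annotation table and compute TSS positions
#'
#' @param df data.frame with `gene_id`, `chrom`, `strand`, `txStart`, `txEnd`.
#' @return the validated data.frame with a `tss` column.
#' @export
gene_annotation <- function(df) {
  if (nrow(df)) {
    if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
    if (any(df$txStart >= df$txEnd)) stop("txStart must be < txEnd")
  }
  df$tss <- ifelse(df$strand == "+", df$txStart, df$txEnd - 1L)
  df
}

#' Write a gene annotation table
#' @param genes gene annotation data.frame.
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  data.table::fwrite(
    genes[, c("gene_id", "chrom", "strand", "txStart", "txEnd")],
    path, sep = "\t"
  )
  invisible(path)
}

#' Read a CAGE expression matrix
#'
#' TSV whose first column (`rtss_id`) names RTSSs and whose remaining header
#' names are sample ids; entries are non-negative tag counts.
#'
#' @param path path to the TSV.
#' @return integer matrix with RTSS ids as rownames, sample ids as colnames.
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(m < 0L)) stop("negative tag count in expression matrix")
  rownames(m) <- ids
  m
}

#' Write a CAGE expression matrix
#' @param counts matrix with RTSS rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(counts, path) {
  df <- data.frame(rtss_id = rownames(counts), counts, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read mapped-read 5' start positions from a BED6 tag file
#'
#' Tag files store one mapped read per line with the 5' start position in the
#' start column (`end = start + 1`). Column 6 gives the mapped strand.
#'
#' @param path path to the tag BED file.
#' @param mark mark name to attach (defaults to the file name).
#' @return a `read_starts` data.frame with columns `chrom`, `pos`, `strand`.
#' @export
read_tag_file <- function(path, mark = basename(path)) {
  df <- read_bed(path)
  if (!"strand" %in% names(df)) stop("tag file requires a strand column (BED6)")
  read_starts(df$chrom, df$start, df$strand, mark = mark)
}

#' Construct a read-start set
#'
#' @param chrom,pos,strand parallel vectors of chromosome, 5' position (bp, >=0)
#'   and mapped strand (`+`/`-`).
#' @param mark mark name.
#' @return a `read_starts` data.frame.
#' @export
read_starts <- function(chrom, pos, strand, mark = "mark") {
  if (length(pos) && any(pos < 0L)) stop("read positions must be >= 0")
  if (length(strand) && !all(strand %in% c("+", "-"))) {
    stop("read strand must be '+' or '-'")
  }
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  attr(df, "mark") <- mark
  class(df) <- c("read_starts", "data.frame")
  df
}

#' Write a read-start set as a BED6 tag file
#' @param reads a `read_starts` data.frame.
#' @param path output path.
#' @export
write_tag_file <- function(reads, path) {
  df <- data.frame(reads$chrom, reads$pos, reads$pos + 1L, ".", 0L, reads$strand)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read mapped reads from a BAM file as 5' start positions
#'
#' Convenience ingestion that reduces alignments to `(chrom, 5' position,
#' strand)` tag records; the 5' end of a minus-strand alignment is its last
#' aligned base. Downstream operations consume only the resulting
#' `read_starts`.
#'
#' @param path path to a BAM file (index not required).
#' @param mark mark name to attach.
#' @return a `read_starts` data.frame.
#' @export
read_tags_bam <- function(path, mark = basename(path)) {
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "qwidth"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  keep <- !is.na(b$pos) & b$strand %in% c("+", "-")
  strand <- as.character(b$strand[keep])
  start1 <- b$pos[keep]              # 1-based leftmost
  width <- b$qwidth[keep]
  pos0 <- ifelse(strand == "+", start1 - 1L, start1 - 1L + width - 1L)
  read_starts(as.character(b$rname[keep]), pos0, strand, mark = mark)
}

#' Read a base-resolution signal track (bedGraph or wiggle)
#'
#' bedGraph lines are `chrom start end value` (0-based half-open); wiggle
#' `fixedStep`/`variableStep` blocks use 1-based starts and are converted on
#' read. Intervals must not overlap within a chromosome. Queries outside
#' covered regions return 0.
#'
#' @param path path to a bedGraph or wiggle file.
#' @return a `signal_track`: data.frame `chrom`, `start`, `end`, `value`.
#' @export
read_signal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  chrom <- character(0); start <- integer(0); end <- integer(0); value <- numeric(0)
  mode <- "bedgraph"
  cur_chrom <- NA_character_; cur_pos <- NA_integer_
  step <- 1L; span <- 1L
  for (ln in lines) {
    if (grepl("^fixedStep", ln) || grepl("^variableStep", ln)) {
      kv <- regmatches(ln, gregexpr("[A-Za-z]+=[^ \t]+", ln))[[1L]]
      opts <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
      mode <- if (grepl("^fixedStep", ln)) "fixed" else "variable"
      cur_chrom <- opts[["chrom"]]
      span <- if ("span" %in% names(opts)) as.integer(opts[["span"]]) else 1L
      if (mode == "fixed") {
        cur_pos <- as.integer(opts[["start"]]) - 1L  # wiggle is 1-based
        step <- if ("step" %in% names(opts)) as.integer(opts[["step"]]) else 1L
      }
      next
    }
    f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (mode == "bedgraph") {
      if (length(f) < 4L) stop("malformed bedGraph line: ", ln)
      chrom <- c(chrom, f[1L]); start <- c(start, as.integer(f[2L]))
      end <- c(end, as.integer(f[3L])); value <- c(value, as.numeric(f[4L]))
    } else if (mode == "fixed") {
      chrom <- c(chrom, cur_chrom); start <- c(start, cur_pos)
      end <- c(end, cur_pos + span); value <- c(value, as.numeric(f[1L]))
      cur_pos <- cur_pos + step
    } else {
      if (length(f) < 2L) stop("malformed variableStep line: ", ln)
      s <- as.integer(f[1L]) - 1L
      chrom <- c(chrom, cur_chrom); start <- c(start, s); end <- c(end, s + span)
      value <- c(value, as.numeric(f[2L]))
    }
  }
  signal_track(data.frame(chrom = chrom, start = start, end = end,
                          value = value, stringsAsFactors = FALSE))
}

#' Construct and validate a signal track
#'
#' @param df data.frame with `chrom`, `start`, `end`, `value` (0-based
#'   half-open, non-overlapping within chromosome, finite values).
#' @return a `signal_track` sorted by chromosome and start.
#' @export
signal_track <- function(df) {
  if (nrow(df)) {
    if (any(!is.finite(df$value))) stop("signal values must be finite")
    if (any(df$start >= df$end)) stop("signal interval with start >= end")
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    same <- df$chrom[-1L] == df$chrom[-nrow(df)]
    if (any(same & df$start[-1L] < df$end[-nrow(df)])) {
      stop("overlapping signal intervals within a chromosome")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Write a signal track as bedGraph
#' @param track a `signal_track`.
#' @param path output path.
#' @export
write_signal <- function(track, path) {
  data.table::fwrite(as.data.frame(track)[, c("chrom", "start", "end", "value")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
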