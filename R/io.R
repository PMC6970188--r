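#' Read a BED3-BED6 file into a FeatureSet
#'
#' Lines starting with `#`, `track` or `browser` and blank lines are skipped.
#' A name of `.` is read as the empty string; a missing strand column yields
#' strand `"."`. Malformed lines raise an error naming the offending line
#' number; intervals beyond the chromosome end fail validation.
#'
#' @param path BED file path.
#' @param genome a [genome_model()] used to validate coordinates.
#' @param label label for the returned set (default: file base name).
#' @return A [feature_set()].
#' @export
read_bed <- function(path, genome, label = NULL) {
  if (!file.exists(path)) stop_("read_bed: no such file: %s", path)
  label <- label %||% sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*$|^#|^track|^browser", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(feature_set(genome, data.frame(), label = label))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L | nf > 12L))
    stop_("read_bed: line %d has %d fields (need >= 3)",
          idx[which(nf < 3L | nf > 12L)[1]], nf[which(nf < 3L | nf > 12L)[1]])
  f <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else NA_character_, "")
  start <- suppressWarnings(as.numeric(f(2)))
  end <- suppressWarnings(as.numeric(f(3)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) stop_("read_bed: non-integer coordinates at line %d", idx[which(bad)[1]])
  bad <- start >= end
  if (any(bad)) stop_("read_bed: start >= end at line %d", idx[which(bad)[1]])
  nm <- f(4); nm[is.na(nm) | nm == "."] <- ""
  sc <- suppressWarnings(as.numeric(f(5))); sc[is.na(sc)] <- 0
  st <- f(6); st[is.na(st) | !(st %in% c("+", "-"))] <- "."
  feature_set(genome,
              data.frame(chrom = f(1), start = start, end = end, strand = st,
                         name = nm, score = sc, stringsAsFactors = FALSE),
              label = label)
}

#' Write a FeatureSet as BED6
#'
#' Output order is deterministic (genome chromosome order, then start); empty
#' names are written as `.`. `read_bed(write_bed(x))` reproduces `x` on all
#' written fields.
#'
#' @param fs a [feature_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(fs, path) {
  stopifnot(inherits(fs, "FeatureSet"))
  df <- fs$intervals
  lines <- if (nrow(df) == 0L) character(0) else
    sprintf("%s\t%d\t%d\t%s\t%s\t%s",
            df$chrom, as.integer(df$start), as.integer(df$end),
            ifelse(df$name == "", ".", df$name),
            num_chr(df$score), df$strand)
  writeLines(lines, path)
  invisible(path)
}

# deterministic, locale-independent numeric formatting that round-trips
num_chr <- function(x) {
  out <- vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE), "")
  out
}

#' Read a bedGraph file onto a fixed bin grid
#'
#' Every record must align to the bin grid: `start` a multiple of
#' `bin_width` and `end` either a multiple of `bin_width` or the chromosome
#' end (no silent re-binning). Records spanning several bins fill each
#' covered bin with the record value. A value of `nan` marks a masked bin.
#' Bins not covered by any record are set to 0 and the count is reported in
#' a message.
#'
#' @param path bedGraph path.
#' @param genome a [genome_model()].
#' @param bin_width grid width in bp.
#' @param units track units of the result.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, genome, bin_width,
                          units = c("linear", "log2_ratio")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop_("read_bedgraph: no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$|^#|^track|^browser", lines)
  idx <- which(keep)
  track <- signal_track(genome, bin_width, units = units)
  nb <- vapply(track$values, length, 1L)
  covered <- lapply(nb, function(n) logical(n))
  vals <- lapply(nb, function(n) numeric(n))
  names(covered) <- names(vals) <- genome$chrom
  if (length(idx) == 0L) {
    warning("read_bedgraph: empty file; returning all-zero track")
    return(track)
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L))
    stop_("read_bedgraph: line %d has %d fields (need 4)",
          idx[which(nf != 4L)[1]], nf[which(nf != 4L)[1]])
  chrom <- vapply(parts, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  vstr <- vapply(parts, `[`, "", 4)
  value <- suppressWarnings(as.numeric(vstr))
  value[tolower(vstr) %in% c("nan", "na")] <- NA_real_
  bad <- is.na(start) | is.na(end) | (is.na(value) & !(tolower(vstr) %in% c("nan", "na")))
  if (any(bad)) stop_("read_bedgraph: malformed record at line %d", idx[which(bad)[1]])
  if (any(!(chrom %in% genome$chrom)))
    stop_("read_bedgraph: unknown chromosome at line %d", idx[which(!(chrom %in% genome$chrom))[1]])
  clen <- chrom_length(genome, chrom)
  bad <- start < 0 | end > clen | start >= end
  if (any(bad)) stop_("read_bedgraph: bad interval at line %d", idx[which(bad)[1]])
  bad <- (start %% bin_width != 0) | (end %% bin_width != 0 & end != clen)
  if (any(bad))
    stop_("read_bedgraph: record not on the %d bp bin grid at line %d",
          as.integer(bin_width), idx[which(bad)[1]])
  for (k in seq_along(idx)) {
    bins <- seq.int(start[k] / bin_width + 1, ceiling(end[k] / bin_width))
    vals[[chrom[k]]][bins] <- value[k]
    covered[[chrom[k]]][bins] <- TRUE
  }
  n_uncov <- sum(vapply(covered, function(x) sum(!x), 1L))
  if (n_uncov > 0)
    message(sprintf("read_bedgraph: %d uncovered bin(s) set to 0", n_uncov))
  signal_track(genome, bin_width, vals, units = units)
}

#' Write a SignalTrack as bedGraph
#'
#' Consecutive bins with identical values are merged into one record; masked
#' bins are written with the value `nan`. Output is deterministic.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "SignalTrack"))
  bw <- track$bin_width
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in track$genome$chrom) {
    v <- track$values[[chrom]]
    clen <- chrom_length(track$genome, chrom)
    if (length(v) == 0L) next
    key <- ifelse(is.na(v), "nan", num_chr(v))
    r <- rle(key)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    lines <- sprintf("%s\t%d\t%d\t%s", chrom,
                     as.integer(starts_bin * bw),
                     as.integer(pmin(ends_bin * bw, clen)),
                     r$values)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Parses with `rtracklayer::import` and keeps records of the requested type
#' (default `gene`). GFF3 1-based closed coordinates are converted to the
#' package's 0-based half-open convention; strand is preserved. Gene
#' identifiers are taken from `ID` (falling back to `Name`).
#'
#' @param path GFF3 path.
#' @param genome a [genome_model()].
#' @param type feature type to keep.
#' @return A [feature_set()].
#' @export
read_gff3_genes <- function(path, genome, type = "gene") {
  if (!file.exists(path)) stop_("read_gff3_genes: no such file: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_("read_gff3_genes: parse error: %s",
                                           conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% type]
  if (length(gr) == 0L) return(feature_set(genome, data.frame(), label = "genes"))
  nm <- as.character(gr$ID %||% rep("", length(gr)))
  if (all(nm == "") && !is.null(gr$Name)) nm <- as.character(gr$Name)
  nm[is.na(nm)] <- ""
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  feature_set(genome,
              data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr) - 1,
                         end = GenomicRanges::end(gr),
                         strand = st, name = nm, score = 0,
                         stringsAsFactors = FALSE),
              label = "genes")
}

#' Write gene features as GFF3
#'
#' @param fs a [feature_set()] of genes.
#' @param path output path.
#' @param source source column value.
#' @param type type column value.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(fs, path, source = "meiochip", type = "gene") {
  df <- fs$intervals
  header <- "##gff-version 3"
  body <- if (nrow(df) == 0L) character(0) else
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s", df$chrom, source, type,
            as.integer(df$start + 1), as.integer(df$end),
            ifelse(df$strand == ".", "+", df$strand),
            ifelse(df$name == "", sprintf("gene%05d", seq_len(nrow(df))), df$name))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a two-column chromosome sizes table
#'
#' @param path TSV path with columns `chrom`, `length` (no header).
#' @return A [genome_model()].
#' @export
read_genome_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  genome_model(df$chrom, df$length)
}

#' @rdname read_genome_tsv
#' @param genome a [genome_model()].
#' @export
write_genome_tsv <- function(genome, path) {
  writeLines(sprintf("%s\t%d", genome$chrom, as.integer(genome$length)), path)
  invisible(path)
}
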