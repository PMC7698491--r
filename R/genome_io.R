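# Reading and writing the standard formats the pipeline touches.
#
# Every coordinate inside the package is 0-based half-open on the plus
# strand of the genome; GFF3 (1-based inclusive) is converted at the I/O
# boundary and bedGraph is natively 0-based half-open.

#' Construct a genome record
#'
#' @param id Sequence identifier.
#' @param sequence DNA string over `A,C,G,T,N` (uppercased on construction).
#' @return An object of class `genome_record` with fields `id`, `sequence`
#'   and `length`.
#' @export
genome_record <- function(id, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) > 0 && grepl("[^ACGTN]", sequence)) {
    stop("genome sequence contains non-nucleotide characters")
  }
  structure(
    list(id = as.character(id), sequence = sequence, length = nchar(sequence)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$id, "-", x$length, "bp\n")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param multiple What to do when the file holds more than one record:
#'   `"error"` (default, single-record mode) or `"first"`.
#' @return A [genome_record()].
#' @export
read_fasta <- function(path, multiple = c("error", "first")) {
  multiple <- match.arg(multiple)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) > 1L && multiple == "error") {
    stop("FASTA file holds ", length(set), " records; single-record mode")
  }
  id <- strsplit(names(set)[1], "[ \t]")[[1]][1]
  genome_record(id, as.character(set[[1]]))
}

#' Write a genome to a FASTA file
#'
#' @param genome A [genome_record()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read ORF features from a GFF3 file
#'
#' GFF3 1-based inclusive coordinates are converted to the package's
#' 0-based half-open convention. Features are returned ordered by start,
#' overlapping rows kept.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature types to keep (default `CDS` and `gene`;
#'   rows of other types are dropped).
#' @return A data.frame with columns `id`, `start`, `end`, `strand`,
#'   `product` (0-based half-open intervals).
#' @export
read_gff <- function(path, feature_type = c("CDS", "gene")) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3: ", conditionMessage(e))
  )
  if (length(gr) > 0L) gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0L) {
    return(data.frame(
      id = character(), start = integer(), end = integer(),
      strand = character(), product = character(),
      stringsAsFactors = FALSE
    ))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("ORF rows must carry an explicit +/- strand")
  }
  meta <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else rep(NA_character_, length(gr))
  if ("Name" %in% names(meta)) {
    ids <- ifelse(is.na(ids), as.character(meta$Name), ids)
  }
  ids[is.na(ids)] <- paste0("orf_", seq_along(gr))[is.na(ids)]
  product <- if ("product" %in% names(meta)) as.character(meta$product) else NA_character_
  out <- data.frame(
    id = ids,
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    product = product,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write features to a GFF3 file
#'
#' Converts the package's 0-based half-open intervals back to GFF3
#' coordinates. Extra columns of `features` become GFF3 attributes.
#'
#' @param features data.frame with `id`, `start`, `end`, `strand` and
#'   optionally further attribute columns.
#' @param path Output path.
#' @param seqname Sequence name for column 1.
#' @param type GFF3 feature type (either one value or one per row).
#' @param source Value for the source column.
#' @export
write_gff <- function(features, path, seqname = "genome", type = "CDS",
                      source = "phagetu") {
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  meta <- features[, setdiff(names(features), c("start", "end", "strand")), drop = FALSE]
  names(meta)[names(meta) == "id"] <- "ID"
  gr$source <- source
  gr$type <- rep_len(type, nrow(features))
  gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  for (nm in names(meta)) S4Vectors::mcols(gr)[[nm]] <- meta[[nm]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Construct a coverage track
#'
#' @param depth Numeric vector of per-base depth (one entry per genomic
#'   base, all entries >= 0). Real-valued so normalized tracks are
#'   admissible.
#' @param strand `"+"` or `"-"`.
#' @param timepoint Timepoint label, e.g. `"t5"`.
#' @param seqname Sequence name used when the track is written out.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(depth, strand, timepoint, seqname = "genome") {
  strand <- match.arg(strand, c("+", "-"))
  depth <- as.numeric(depth)
  if (any(is.na(depth)) || any(depth < 0)) {
    stop("coverage depth must be non-negative and complete")
  }
  structure(
    list(depth = depth, strand = strand, timepoint = as.character(timepoint),
         seqname = seqname),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track>", x$strand, "strand,", x$timepoint, "-",
      length(x$depth), "bp, mean depth", signif(mean(x$depth), 4), "\n")
  invisible(x)
}

#' Read a bedGraph file into a dense coverage track
#'
#' bedGraph intervals are 0-based half-open; gaps mean depth 0.
#' Overlapping intervals are rejected rather than summed, since silent
#' summation hides malformed exports.
#'
#' @param path Path to a bedGraph file.
#' @param genome_length Genome length in bp (track length).
#' @param strand,timepoint Labels attached to the returned track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, genome_length, strand, timepoint) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(data_lines) == 0L) {
    return(coverage_track(numeric(genome_length), strand, timepoint))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 0L && max(BiocGenerics::end(gr)) > genome_length) {
    stop("bedGraph interval extends beyond genome length ", genome_length)
  }
  red <- IRanges::reduce(IRanges::ranges(gr))
  if (sum(IRanges::width(red)) < sum(IRanges::width(gr))) {
    stop("bedGraph has overlapping intervals; refusing to sum them")
  }
  GenomeInfoDb::seqlengths(gr) <- genome_length
  depth <- as.numeric(GenomicRanges::coverage(gr, weight = gr$score)[[1]])
  track <- coverage_track(depth, strand, timepoint)
  track$seqname <- as.character(GenomeInfoDb::seqnames(gr))[1]
  track
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted (gaps mean depth 0 on re-reading).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$depth)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = track$seqname, start = start[keep],
                   end = end[keep], value = r$values[keep])
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                       format(df$value, trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over `A,C,G,T,N` (case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return(seq)
  if (grepl("[^ACGTN]", seq)) stop("reverse_complement: non-ACGTN character")
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}
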