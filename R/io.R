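#' Read a FASTA file of DNA sequences
#'
#' Sequences are upper-cased on ingest (lower-case input is accepted and
#' flagged with a message); `U` and any non-nucleotide character raise a
#' format error naming the record; duplicate identifiers and empty files are
#' errors. Record order and description lines are preserved.
#'
#' @param path FASTA path.
#' @return named character vector of sequences; full description lines in
#'   `attr(, "descriptions")`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("format error: empty FASTA file '", path, "'")
  desc <- names(x)
  ids <- sub("\\s.*$", "", desc)
  if (anyDuplicated(ids))
    stop("format error: duplicate identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(x)
  lower <- grepl("[a-z]", seqs)
  if (any(lower)) {
    message("read_fasta: upper-casing lower-case sequence in record(s): ",
            paste(ids[lower], collapse = ", "))
    seqs <- toupper(seqs)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("format error: non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  attr(seqs, "descriptions") <- desc
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(unlist(lapply(seqs, as.character)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

regions_granges <- function(regions, locus_name) {
  GenomicRanges::GRanges(
    seqnames = locus_name,
    ranges = IRanges::IRanges(start = regions$start + 1L,
                              end = regions$end),
    name = sprintf("region_%03d", seq_len(nrow(regions))),
    score = regions$level
  )
}

#' Write candidate regions as 6-column BED
#'
#' 0-based half-open coordinates; column 5 (score) carries the ladder level,
#' column 4 a generated region id. Input regions must be sorted and disjoint.
#'
#' @param scan a `crm_scan` object or its `regions` data.frame.
#' @param path output path.
#' @param locus_name chromosome/locus name for column 1.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(scan, path, locus_name = NULL) {
  regions <- if (inherits(scan, "crm_scan")) scan$regions else scan
  if (is.null(locus_name))
    locus_name <- if (inherits(scan, "crm_scan")) scan$name else "locus"
  if (nrow(regions) == 0L) {
    writeLines("# no candidate regions", path)
    return(invisible(path))
  }
  if (is.unsorted(regions$start) ||
      any(regions$start[-1] < regions$end[-nrow(regions)]))
    stop("internal contract error: regions must be sorted and disjoint")
  gr <- regions_granges(regions, locus_name)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a 6-column BED of candidate regions
#'
#' @param path BED path.
#' @return data.frame with 0-based half-open `start`, `end`, `level`, `name`,
#'   `locus`.
#' @export
read_regions_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || startsWith(first, "#"))
    return(data.frame(start = integer(0), end = integer(0),
                      level = integer(0), name = character(0),
                      locus = character(0)))
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             level = as.integer(gr$score),
             name = as.character(gr$name),
             locus = as.character(GenomicRanges::seqnames(gr)),
             stringsAsFactors = FALSE)
}

#' Write annotated binding sites as GFF3
#'
#' The sole 1-based-inclusive surface of the package: internal 0-based
#' half-open hit intervals are converted on serialization. Attributes carry
#' the motif name, class and factor.
#'
#' @param hits a `site_hits` data.frame (e.g. `annotate_region()$sites`).
#' @param path output path.
#' @param region_name sequence name for GFF3 column 1.
#' @return `path`, invisibly.
#' @export
write_sites_gff3 <- function(hits, path, region_name = "region") {
  gr <- GenomicRanges::GRanges(
    seqnames = rep(region_name, nrow(hits)),
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand
  )
  gr$type <- rep("TF_binding_site", nrow(hits))
  gr$ID <- sprintf("site_%03d", seq_len(max(1L, nrow(hits)))[seq_len(nrow(hits))])
  gr$Name <- hits$motif_name
  gr$motif_class <- hits$klass
  gr$tf_factor <- hits$factor
  gr$matched <- hits$matched
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read binding sites back from GFF3
#'
#' @param path GFF3 path.
#' @return a `site_hits` data.frame (0-based half-open).
#' @export
read_sites_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  hits <- data.frame(
    motif_name = as.character(gr$Name),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    matched = as.character(gr$matched),
    klass = as.character(gr$motif_class),
    factor = as.character(gr$tf_factor),
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$start, hits$strand, hits$motif_name), ]
  rownames(hits) <- NULL
  class(hits) <- c("site_hits", "data.frame")
  hits
}

#' Write per-region or per-class counts as TSV
#'
#' @param df a data.frame (e.g. `annotate_region()$counts` or
#'   `crm_scan()$regions`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap report between candidate regions and external intervals
#'
#' Simple intersection of scan regions with externally provided intervals
#' (e.g. in-vivo bound regions from a ChIP experiment) supplied as a BED
#' file or data.frame with 0-based `start`/`end`.
#'
#' @param scan a `crm_scan` object.
#' @param intervals BED path or data.frame with `start`, `end`.
#' @return the scan's regions data.frame with an added logical
#'   `overlaps_external` column.
#' @export
overlap_report <- function(scan, intervals) {
  stopifnot(inherits(scan, "crm_scan"))
  if (is.character(intervals)) intervals <- read_regions_bed(intervals)
  r <- scan$regions
  r$overlaps_external <- vapply(seq_len(nrow(r)), function(i)
    any(intervals$start < r$end[i] & intervals$end > r$start[i]),
    logical(1))
  r
}
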