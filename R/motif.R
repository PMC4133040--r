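#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "W", "S", "K", "M",
                   "B", "D", "H", "V", "N")

# expansion of one IUPAC code to the concrete bases it stands for
IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", W = "W", S = "S", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

MOTIF_KLASSES <- c("strict", "canonical", "non-canonical")
MOTIF_FACTORS <- c("Otx", "Fox", "Smad")

#' Compile an IUPAC consensus motif
#'
#' A motif is a short literal consensus over the IUPAC nucleotide alphabet,
#' tagged with the transcription factor it stands for (Otx, Fox or Smad) and a
#' specificity class. The class ladder `strict > canonical > non-canonical`
#' drives de-duplication when per-class counts are reported: a genomic site is
#' counted once, at its most specific class.
#'
#' @param name unique short label for the motif.
#' @param core IUPAC consensus string (length >= 3), e.g. `"GATTA"` for the
#'   canonical Otx homeodomain word or `"AGAC"` for the Smad Binding Element.
#' @param klass one of `"strict"`, `"canonical"`, `"non-canonical"`.
#' @param factor one of `"Otx"`, `"Fox"`, `"Smad"`.
#' @return an object of class `"motif"`.
#' @examples
#' motif("Otx-can", "GATTA", "canonical", "Otx")
#' motif("Otx-non", "GHATTA", "non-canonical", "Otx")
#' @export
motif <- function(name, core, klass = "canonical", factor = "Otx") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(core) || length(core) != 1L || !nzchar(core))
    stop("invalid motif '", name, "': core must be a non-empty string")
  core <- toupper(core)
  letters <- strsplit(core, "", fixed = TRUE)[[1]]
  bad <- which(!(letters %in% IUPAC_LETTERS))
  if (length(bad))
    stop("invalid motif '", name, "': non-IUPAC character '",
         letters[bad[1]], "' at position ", bad[1])
  if (nchar(core) < 3L)
    stop("invalid motif '", name, "': core length must be >= 3")
  klass <- match.arg(klass, MOTIF_KLASSES)
  factor <- match.arg(factor, MOTIF_FACTORS)
  structure(list(name = name, core = core, klass = klass, factor = factor),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s: %s (%s %s)\n", x$name, x$core, x$factor, x$klass))
  invisible(x)
}

#' Bundle motifs into a named set
#'
#' @param ... `motif` objects (or a single list of them).
#' @return an object of class `"motif_set"` (a named list of motifs).
#' @export
motif_set <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "motif"))
    ms <- ms[[1]]
  stopifnot(all(vapply(ms, inherits, logical(1), "motif")))
  nm <- vapply(ms, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate motif name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(ms) <- nm
  structure(ms, class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat("<motif_set> with", length(x), "motifs\n")
  for (m in x)
    cat(sprintf("  %-16s %-10s %-13s %s\n", m$name, m$core, m$klass, m$factor))
  invisible(x)
}

#' Default annotation motif set
#'
#' The shipped consensus words used throughout the b6.5-lineage enhancer
#' analysis: canonical Otx (GATTA), non-canonical Otx (GHATTA, covering the
#' GAATTA variant), canonical Fox (AAACA, reverse complement TGTTT),
#' non-canonical Fox (AACA) and the Smad Binding Element (AGAC). The strict
#' Otx word GGATTA used by the locus scanner's base requirement is included
#' when `strict = TRUE`.
#'
#' @param strict include the strict Otx motif GGATTA.
#' @return a [motif_set()].
#' @export
default_motif_set <- function(strict = FALSE) {
  ms <- list(
    motif("Otx-canonical", "GATTA", "canonical", "Otx"),
    motif("Otx-non-canonical", "GHATTA", "non-canonical", "Otx"),
    motif("Fox-canonical", "AAACA", "canonical", "Fox"),
    motif("Fox-non-canonical", "AACA", "non-canonical", "Fox"),
    motif("SBE", "AGAC", "canonical", "Smad")
  )
  if (strict)
    ms <- c(list(motif("Otx-strict", "GGATTA", "strict", "Otx")), ms)
  motif_set(ms)
}

#' Read / write a motif set as TSV
#'
#' Plain-text configuration with columns `name`, `core`, `klass`, `factor`.
#'
#' @param path file path.
#' @return `read_motif_set` returns a [motif_set()]; `write_motif_set`
#'   returns `path` invisibly.
#' @export
read_motif_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "core", "klass", "factor")
  if (!all(need %in% names(df)))
    stop("motif set file must have columns: ", paste(need, collapse = ", "))
  motif_set(lapply(seq_len(nrow(df)), function(i)
    motif(df$name[i], df$core[i], df$klass[i], df$factor[i])))
}

#' @rdname read_motif_set
#' @param motifs a [motif_set()].
#' @export
write_motif_set <- function(motifs, path) {
  df <- data.frame(
    name = vapply(motifs, `[[`, character(1), "name"),
    core = vapply(motifs, `[[`, character(1), "core"),
    klass = vapply(motifs, `[[`, character(1), "klass"),
    factor = vapply(motifs, `[[`, character(1), "factor")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement of a DNA (or IUPAC) string
#'
#' Plain-character reverse complementation; an involution that preserves
#' length. Ambiguity codes are complemented according to the IUPAC table, so
#' `revcomp("AAACA")` is `"TGTTT"` and `revcomp("GHATTA")` is `"TAATDC"`.
#'
#' @param seq a single character string over the IUPAC alphabet.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return("")
  letters <- rev(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  out <- IUPAC_COMPLEMENT[letters]
  if (anyNA(out))
    stop("invalid sequence: non-IUPAC character '",
         letters[which(is.na(out))[1]], "'")
  paste(out, collapse = "")
}

check_dna <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(unname(seq))
  if (nzchar(seq) && grepl("[^ACGTN]", seq))
    stop("invalid ", what, ": characters outside A/C/G/T/N")
  seq
}

# match an IUPAC pattern on the forward strand of a literal A/C/G/T/N subject;
# returns 0-based start offsets. Hits whose matched bases include N are
# dropped: an unknown base is evidence for nothing.
match_iupac <- function(seq, core) {
  w <- nchar(core)
  if (nchar(seq) < w) return(integer(0))
  m <- Biostrings::matchPattern(core, Biostrings::DNAString(seq),
                                fixed = "subject")
  if (length(m) == 0L) return(integer(0))
  starts <- Biostrings::start(m) - 1L
  hasN <- grepl("N", as.character(m), fixed = TRUE)
  starts[!hasN]
}

#' Enumerate motif occurrences on a sequence
#'
#' All occurrences of the motif's consensus on the forward strand and (by
#' default) of its reverse complement, with exact overlapping-hit semantics:
#' every matching offset is reported, overlaps included. `N` in the sequence
#' never matches any motif letter. A palindromic hit occupying the same
#' interval on both strands is reported once, on `"+"`.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param m a [motif()].
#' @param strands `"both"` (default) or `"plus"`.
#' @return a `data.frame` of class `"site_hits"` with columns `motif_name`,
#'   `start`, `end` (0-based half-open), `strand`, `matched` (forward-strand
#'   bases), `klass`, `factor`, sorted by `(start, strand)`.
#' @examples
#' find_sites("AAACAAACA", motif("Fox", "AAACA", "canonical", "Fox"))
#' @export
find_sites <- function(seq, m, strands = c("both", "plus")) {
  stopifnot(inherits(m, "motif"))
  strands <- match.arg(strands)
  seq <- check_dna(seq)
  w <- nchar(m$core)
  plus <- match_iupac(seq, m$core)
  if (strands == "both") {
    minus <- match_iupac(seq, revcomp(m$core))
    minus <- setdiff(minus, plus)  # palindromic double-count guard
  } else {
    minus <- integer(0)
  }
  start <- c(plus, minus)
  strand <- c(rep("+", length(plus)), rep("-", length(minus)))
  o <- order(start, strand)
  start <- start[o]; strand <- strand[o]
  hits <- data.frame(
    motif_name = rep(m$name, length(start)),
    start = as.integer(start),
    end = as.integer(start + w),
    strand = strand,
    matched = if (length(start)) substring(seq, start + 1L, start + w)
              else character(0),
    klass = rep(m$klass, length(start)),
    factor = rep(m$factor, length(start)),
    stringsAsFactors = FALSE
  )
  class(hits) <- c("site_hits", "data.frame")
  hits
}

#' Enumerate occurrences of every motif in a set
#'
#' @inheritParams find_sites
#' @param motifs a [motif_set()].
#' @return a `site_hits` data.frame sorted by `(start, strand, motif_name)`.
#' @export
find_all_sites <- function(seq, motifs, strands = c("both", "plus")) {
  strands <- match.arg(strands)
  stopifnot(inherits(motifs, "motif_set"))
  hits <- do.call(rbind, lapply(motifs, find_sites, seq = seq,
                                strands = strands))
  if (is.null(hits)) hits <- find_sites(seq, motif("x", "NNN"))[0, ]
  hits <- hits[order(hits$start, hits$strand, hits$motif_name), ]
  rownames(hits) <- NULL
  class(hits) <- c("site_hits", "data.frame")
  hits
}

# de-duplication across specificity classes: a hit overlapping a same-factor
# hit of a more specific class is suppressed (each genomic site counted once,
# at its most specific class). Rank: strict > canonical > non-canonical.
dedup_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  rank <- match(hits$klass, MOTIF_KLASSES)  # 1 most specific
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    over <- hits$start < hits$end[i] & hits$end > hits$start[i] &
      hits$factor == hits$factor[i] & rank < rank[i]
    if (any(over)) keep[i] <- FALSE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_hits", "data.frame")
  out
}

#' Per-class motif counts on a sequence
#'
#' Counts occurrences of every motif in the set after cross-class
#' de-duplication: a hit of a less specific same-factor motif that overlaps a
#' more specific hit is suppressed, so that e.g. the AACA words inside an
#' AAACA site are not counted as extra degenerate Fox sites, and a GATTA
#' nested in a strict GGATTA counts once.
#'
#' @inheritParams find_all_sites
#' @return a `data.frame` with columns `motif_name`, `factor`, `klass`,
#'   `count`, one row per motif in the set.
#' @examples
#' count_by_class("AAACAAACA", default_motif_set())
#' @export
count_by_class <- function(seq, motifs = default_motif_set(),
                           strands = c("both", "plus")) {
  strands <- match.arg(strands)
  hits <- dedup_hits(find_all_sites(seq, motifs, strands))
  data.frame(
    motif_name = vapply(motifs, `[[`, character(1), "name"),
    factor = vapply(motifs, `[[`, character(1), "factor"),
    klass = vapply(motifs, `[[`, character(1), "klass"),
    count = vapply(motifs, function(m)
      sum(hits$motif_name == m$name), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
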