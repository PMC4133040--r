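#' Synthetic stand-in enhancer sequences
#'
#' Deterministic, fully synthetic surrogates for the b6.5-lineage enhancers
#' whose published sequences live in PDF supplementary material and are not
#' redistributed here. Each stand-in is built by planting binding-site words
#' into scrubbed AT-rich background so that its per-class site composition
#' matches the published characterization exactly:
#'
#' \describe{
#'   \item{msxb_B}{273 bp; 3 canonical Otx (GATTA), 1 non-canonical Otx
#'     (GAATTA), 2 overlapping canonical Fox (AAACAAACA), 3 stand-alone
#'     degenerate Fox (AACA), 4 Smad Binding Elements.}
#'   \item{ci_msxb_line}{600 bp; 6 Otx (one as strict GGATTA), 5 Fox
#'     (including the overlapping pair), 6 SBEs, clustered within one 300 bp
#'     window.}
#'   \item{ci_delta2_line}{392 bp; 5 Otx (one strict), 3 Fox, 3 SBEs.}
#'   \item{pm_msxb_line}{587 bp; 6 Otx (one strict), 7 Fox (including the
#'     overlapping pair), 7 SBEs.}
#' }
#'
#' Some words are planted in reverse-complement orientation (TGTTT, TAATC,
#' GTCT), as site arrows in enhancer maps point both ways. Background
#' composition is 65\% AT. These sequences exercise the counting, scanning
#' and mutagenesis machinery against the published compositions; they are
#' not the genomic sequences.
#'
#' @param which one of `"msxb_B"`, `"ci_msxb_line"`, `"ci_delta2_line"`,
#'   `"pm_msxb_line"`.
#' @return a single named character string (the sequence).
#' @examples
#' annotate_region(synthetic_enhancer("msxb_B"))
#' @export
synthetic_enhancer <- function(which = c("msxb_B", "ci_msxb_line",
                                         "ci_delta2_line", "pm_msxb_line")) {
  which <- match.arg(which)
  spec <- switch(which,
    msxb_B = list(
      length = 273L, position = 8L, seed = 102L,
      words = c("GATTA", "AGAC", "AAACAAACA", "GAATTA", "GTCT", "GATTA",
                "AACA", "AGAC", "AACA", "TAATC", "AGAC", "AACA"),
      spacer = 18L),
    ci_msxb_line = list(
      length = 600L, position = 150L, seed = 102L,
      words = c("GGATTA", "AGAC", "GATTA", "AAACA", "AGAC", "AAACAAACA",
                "GATTA", "GTCT", "TAATC", "TGTTT", "AGAC", "GATTA",
                "AGAC", "TGTTT", "GATTA", "AGAC"),
      spacer = 13L),
    ci_delta2_line = list(
      length = 392L, position = 100L, seed = 103L,
      words = c("GGATTA", "AGAC", "AAACA", "GATTA", "GTCT", "TAATC",
                "TGTTT", "GATTA", "AGAC", "AAACA", "GATTA"),
      spacer = 15L),
    pm_msxb_line = list(
      length = 587L, position = 150L, seed = 104L,
      words = c("GGATTA", "AGAC", "AAACAAACA", "GATTA", "AGAC", "TGTTT",
                "GATTA", "GTCT", "AAACA", "TAATC", "AGAC", "TGTTT",
                "GATTA", "AGAC", "AAACA", "GATTA", "AGAC", "GTCT",
                "AAACA"),
      spacer = 11L)
  )
  plant <- list(position = spec$position, words = spec$words,
                spacers = rep(spec$spacer, length(spec$words) - 1L))
  ls <- locus_spec(spec$length, at_fraction = 0.65, plants = list(plant),
                   exclusion = TRUE)
  loc <- generate_locus(ls, seed = spec$seed)
  # construction contract: the stand-in must reproduce the published
  # per-class composition exactly
  expected <- switch(which,
    msxb_B = c(3L, 1L, 2L, 3L, 4L),
    ci_msxb_line = c(6L, 0L, 5L, 0L, 6L),
    ci_delta2_line = c(5L, 0L, 3L, 0L, 3L),
    pm_msxb_line = c(6L, 0L, 7L, 0L, 7L))
  stopifnot(identical(count_by_class(loc$seq)$count, expected))
  stats::setNames(loc$seq, which)
}

#' All four synthetic stand-in enhancers
#'
#' @return named character vector of the four sequences of
#'   [synthetic_enhancer()].
#' @export
synthetic_enhancer_set <- function() {
  nms <- c("msxb_B", "ci_msxb_line", "ci_delta2_line", "pm_msxb_line")
  out <- vapply(nms, function(w) unname(synthetic_enhancer(w)), character(1))
  out
}
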