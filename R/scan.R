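#' Scan configuration for the co-occurrence ladder
#'
#' The scanner slides a window (default 300 bp, the choice used to delimit
#' candidate regions at the Msxb and Delta2 loci) along a locus and keeps
#' windows satisfying the base requirement -- at least one strict Otx word
#' (GGATTA), one Fox word (AAACA/TGTTT, both strands) and one Smad Binding
#' Element (AGAC) -- plus, at ladder level L, at least L additional degenerate
#' Otx words (GATTA). GATTA hits nested inside a strict GGATTA hit are by
#' default not counted as "additional" (switch `count_nested_gatta`).
#'
#' @param window_bp window width in bp (default 300).
#' @param step_bp offset increment between tested windows (default 1,
#'   exhaustive).
#' @param ladder_level integer L >= 0: number of additional degenerate GATTA
#'   words required on top of the base requirement.
#' @param base_requirement named integer vector of minimum counts for the
#'   strict Otx, Fox and SBE motifs.
#' @param count_nested_gatta count GATTA hits lying inside a GGATTA hit
#'   towards the ladder requirement (default `FALSE`).
#' @param strands strand policy passed to the motif engine.
#' @return an object of class `"scan_config"`.
#' @export
scan_config <- function(window_bp = 300L, step_bp = 1L, ladder_level = 0L,
                        base_requirement = c(`Otx-strict` = 1L,
                                             `Fox-canonical` = 1L,
                                             SBE = 1L),
                        count_nested_gatta = FALSE,
                        strands = c("both", "plus")) {
  strands <- match.arg(strands)
  stopifnot(window_bp >= 6L, step_bp >= 1L, ladder_level >= 0L,
            all(base_requirement >= 0L))
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 ladder_level = as.integer(ladder_level),
                 base_requirement = base_requirement,
                 count_nested_gatta = isTRUE(count_nested_gatta),
                 strands = strands),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    "<scan_config> %d bp window, step %d, ladder level %d (%s strand%s)\n",
    x$window_bp, x$step_bp, x$ladder_level, x$strands,
    if (x$strands == "both") "s" else ""))
  cat("  base requirement:",
      paste(names(x$base_requirement), ">=", x$base_requirement,
            collapse = ", "), "\n")
  invisible(x)
}

scan_motifs <- function() {
  motif_set(
    motif("Otx-strict", "GGATTA", "strict", "Otx"),
    motif("Otx-degenerate", "GATTA", "canonical", "Otx"),
    motif("Fox-canonical", "AAACA", "canonical", "Fox"),
    motif("SBE", "AGAC", "canonical", "Smad")
  )
}

# hit starts per scanner motif, with the degenerate-GATTA nesting filter
# already applied when requested
scan_hit_table <- function(seq, config) {
  ms <- scan_motifs()
  hits <- lapply(ms, find_sites, seq = seq, strands = config$strands)
  if (!config$count_nested_gatta && nrow(hits$`Otx-strict`)) {
    g <- hits$`Otx-degenerate`
    s <- hits$`Otx-strict`
    nested <- vapply(seq_len(nrow(g)), function(i)
      any(s$start <= g$start[i] & g$end[i] <= s$end), logical(1))
    hits$`Otx-degenerate` <- g[!nested, , drop = FALSE]
  }
  hits
}

count_in_window <- function(hits, win_start, win_end) {
  # hits fully inside [win_start, win_end)
  sum(hits$start >= win_start & hits$end <= win_end)
}

window_counts <- function(hit_table, win_start, win_end) {
  vapply(hit_table, count_in_window, integer(1),
         win_start = win_start, win_end = win_end)
}

qualifies_from_counts <- function(counts, config) {
  base_ok <- all(counts[names(config$base_requirement)] >=
                   config$base_requirement)
  base_ok && counts[["Otx-degenerate"]] >= config$ladder_level
}

#' Does a single window satisfy the co-occurrence requirement?
#'
#' @param window_seq DNA string; normally exactly `window_bp` long (shorter
#'   windows are allowed only for a locus tail and are flagged by [crm_scan()]).
#' @param config a [scan_config()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' cfg <- scan_config()
#' window_qualifies(strrep("A", 300), cfg)
#' @export
window_qualifies <- function(window_seq, config = scan_config()) {
  window_seq <- check_dna(window_seq)
  if (nchar(window_seq) < 6L)
    stop("degenerate input: window shorter than the longest motif")
  ht <- scan_hit_table(window_seq, config)
  qualifies_from_counts(window_counts(ht, 0L, nchar(window_seq)), config)
}

#' Scan a locus for candidate cis-regulatory regions
#'
#' Slides a `window_bp` window at `step_bp` increments along the locus,
#' tests each window with [window_qualifies()] semantics, and merges
#' overlapping or bookended qualifying windows into maximal candidate
#' regions. Per-motif counts are recomputed on the merged interval, and each
#' region is assigned the highest ladder level at which at least one of its
#' windows still qualifies.
#'
#' A locus tail shorter than `window_bp` is scanned as one truncated window
#' and flagged in the result (`truncated_tail`), not silently dropped.
#'
#' @param seq locus DNA string.
#' @param config a [scan_config()].
#' @param name locus name carried into the result.
#' @return an object of class `"crm_scan"`: a list with `regions` (a
#'   data.frame with `start`, `end`, `level`, `n_windows` and per-motif count
#'   columns), `config`, `name`, `locus_length`, `truncated_tail`.
#' @export
crm_scan <- function(seq, config = scan_config(), name = "locus") {
  seq <- check_dna(seq)
  n <- nchar(seq)
  w <- config$window_bp
  empty <- data.frame(start = integer(0), end = integer(0),
                      level = integer(0), n_windows = integer(0))
  res <- structure(list(regions = empty, config = config, name = name,
                        locus_length = n, truncated_tail = FALSE),
                   class = "crm_scan")
  if (n == 0L) return(res)

  ht <- scan_hit_table(seq, config)
  starts <- if (n >= w) seq.int(0L, n - w, by = config$step_bp) else integer(0)
  truncated <- FALSE
  if (n < w || max(starts) + w < n) {
    # cover the tail with one truncated (or short-locus) window
    tail_start <- if (n >= w) max(starts) + config$step_bp else 0L
    if (n - tail_start >= 6L) {
      starts <- c(starts, tail_start)
      truncated <- TRUE
    }
  }
  if (length(starts) == 0L) return(res)
  ends <- pmin(starts + w, n)

  ok <- vapply(seq_along(starts), function(i) {
    qualifies_from_counts(window_counts(ht, starts[i], ends[i]), config)
  }, logical(1))
  res$truncated_tail <- truncated && ok[length(ok)]
  if (!any(ok)) return(res)

  qs <- starts[ok]; qe <- ends[ok]
  # merge overlapping or abutting qualifying windows
  breaks <- c(TRUE, qs[-1] > qe[-length(qe)])
  grp <- cumsum(breaks)
  reg_start <- as.integer(tapply(qs, grp, min))
  reg_end <- as.integer(tapply(qe, grp, max))
  n_windows <- as.integer(tapply(qs, grp, length))

  # per-region recomputed counts and maximal satisfied ladder level
  counts <- t(vapply(seq_along(reg_start), function(i)
    window_counts(ht, reg_start[i], reg_end[i]),
    integer(length(scan_motifs()))))
  level <- vapply(seq_along(reg_start), function(i) {
    win_idx <- which(qs >= reg_start[i] & qe <= reg_end[i])
    best <- config$ladder_level
    repeat {
      cfg2 <- config; cfg2$ladder_level <- best + 1L
      any_ok <- any(vapply(win_idx, function(j)
        qualifies_from_counts(window_counts(ht, qs[j], qe[j]), cfg2),
        logical(1)))
      if (!any_ok) break
      best <- best + 1L
    }
    best
  }, integer(1))

  res$regions <- data.frame(start = reg_start, end = reg_end, level = level,
                            n_windows = n_windows, counts)
  res
}

#' @export
print.crm_scan <- function(x, ...) {
  cat(sprintf("<crm_scan> %s (%d bp), ladder level %d: %d candidate region%s\n",
              x$name, x$locus_length, x$config$ladder_level,
              nrow(x$regions), if (nrow(x$regions) == 1) "" else "s"))
  if (nrow(x$regions)) print(x$regions, ...)
  if (x$truncated_tail)
    cat("  note: a truncated tail window qualifies\n")
  invisible(x)
}

#' Annotate a region with its binding-site content
#'
#' Per-class counts (via [count_by_class()], i.e. after cross-class
#' de-duplication) plus the full de-duplicated site list, ready for GFF3
#' serialization.
#'
#' @param seq region DNA string.
#' @param motifs a [motif_set()] (default [default_motif_set()]).
#' @param name region name carried into the report.
#' @param strands strand policy.
#' @return an object of class `"region_report"`: list with `name`, `length`,
#'   `counts` (data.frame) and `sites` (`site_hits` data.frame).
#' @examples
#' annotate_region("GATTAAGAC")
#' @export
annotate_region <- function(seq, motifs = default_motif_set(),
                            name = "region", strands = c("both", "plus")) {
  strands <- match.arg(strands)
  seq <- check_dna(seq)
  structure(list(name = name,
                 length = nchar(seq),
                 counts = count_by_class(seq, motifs, strands),
                 sites = dedup_hits(find_all_sites(seq, motifs, strands))),
            class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf("<region_report> %s (%d bp)\n", x$name, x$length))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
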