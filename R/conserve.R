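#' Is the site combination conserved in an orthologous sequence?
#'
#' Phylogenetic footprinting in its weakest reading: the orthologous sequence
#' passes when at least one window of `window_bp` within it satisfies the same
#' base requirement and ladder level as the focal scan. No alignment is
#' computed and no per-class count, spacing or order matching is required;
#' stricter per-class count matching can be enabled with
#' `match_counts = TRUE` (every scanner-motif count of the best ortholog
#' window must then reach the focal region's count).
#'
#' @param focal_seq the focal candidate region sequence.
#' @param ortholog_seq the user-supplied orthologous sequence.
#' @param config a [scan_config()] carrying the focal requirement.
#' @param match_counts require per-motif counts >= the focal region's counts.
#' @return a list of class `"conservation_report"`: `conserved` (logical),
#'   `best_window` (start/end in the ortholog, 0-based half-open),
#'   `best_counts`, `focal_counts`.
#' @export
combination_conserved <- function(focal_seq, ortholog_seq,
                                  config = scan_config(),
                                  match_counts = FALSE) {
  focal_seq <- check_dna(focal_seq, "focal sequence")
  ortholog_seq <- check_dna(ortholog_seq, "ortholog sequence")
  if (nchar(ortholog_seq) < 6L)
    stop("degenerate input: ortholog shorter than the longest motif")
  focal_counts <- window_counts(scan_hit_table(focal_seq, config),
                                0L, nchar(focal_seq))
  scan <- crm_scan(ortholog_seq, config, name = "ortholog")

  ht <- scan_hit_table(ortholog_seq, config)
  n <- nchar(ortholog_seq); w <- config$window_bp
  starts <- if (n >= w) seq.int(0L, n - w, by = config$step_bp) else 0L
  ends <- pmin(starts + w, n)
  ok <- vapply(seq_along(starts), function(i) {
    cnt <- window_counts(ht, starts[i], ends[i])
    if (!qualifies_from_counts(cnt, config)) return(FALSE)
    !match_counts || all(cnt >= focal_counts)
  }, logical(1))

  conserved <- any(ok)
  best <- if (conserved) {
    # best = qualifying window with the most total sites
    tot <- vapply(which(ok), function(i)
      sum(window_counts(ht, starts[i], ends[i])), integer(1))
    which(ok)[which.max(tot)]
  } else {
    tot <- vapply(seq_along(starts), function(i)
      sum(window_counts(ht, starts[i], ends[i])), integer(1))
    which.max(tot)
  }
  structure(list(
    conserved = conserved,
    best_window = c(start = starts[best], end = ends[best]),
    best_counts = window_counts(ht, starts[best], ends[best]),
    focal_counts = focal_counts
  ), class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("<conservation_report>", if (x$conserved) "conserved" else
    "not conserved", "\n")
  cat(sprintf("  best ortholog window [%d, %d): %s\n",
              x$best_window[["start"]], x$best_window[["end"]],
              paste(names(x$best_counts), x$best_counts, sep = "=",
                    collapse = " ")))
  invisible(x)
}

#' Filter candidate regions by conservation of the site combination
#'
#' A region survives when every supplied ortholog passes
#' [combination_conserved()] (conjunction: when two related genomes are
#' examined, the combination must be present in both). Regions with no
#' supplied ortholog are dropped and listed in `no_ortholog`.
#'
#' @param region_seqs named list/character vector of focal region sequences.
#' @param orthologs named list mapping region name to a character vector of
#'   ortholog sequences (possibly empty).
#' @param config a [scan_config()].
#' @param match_counts passed to [combination_conserved()].
#' @return list with `survivors` (names), `reports` (per region, per
#'   ortholog), `no_ortholog` (names dropped for lack of an ortholog).
#' @export
filter_candidates <- function(region_seqs, orthologs,
                              config = scan_config(),
                              match_counts = FALSE) {
  region_seqs <- as.list(region_seqs)
  nm <- names(region_seqs)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("region sequences must be named")
  no_ortholog <- nm[vapply(nm, function(r)
    is.null(orthologs[[r]]) || length(orthologs[[r]]) == 0L, logical(1))]
  tested <- setdiff(nm, no_ortholog)
  reports <- lapply(tested, function(r)
    lapply(orthologs[[r]], function(o)
      combination_conserved(region_seqs[[r]], o, config, match_counts)))
  names(reports) <- tested
  pass <- vapply(reports, function(rr)
    all(vapply(rr, `[[`, logical(1), "conserved")), logical(1))
  list(survivors = tested[pass], reports = reports,
       no_ortholog = no_ortholog)
}

#' Read an ortholog manifest
#'
#' Two-column tab-separated manifest mapping a region id to the path of a
#' FASTA file with its orthologous sequence(s). A region may appear on
#' several lines.
#'
#' @param path manifest path.
#' @param relative_to directory against which relative FASTA paths are
#'   resolved (default: the manifest's directory).
#' @return named list of character vectors of sequences, as expected by
#'   [filter_candidates()].
#' @export
read_ortholog_manifest <- function(path, relative_to = dirname(path)) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("region", "fasta"))
  out <- list()
  for (i in seq_len(nrow(df))) {
    p <- df$fasta[i]
    if (!file.exists(p)) p <- file.path(relative_to, df$fasta[i])
    seqs <- read_fasta(p)
    out[[df$region[i]]] <- c(out[[df$region[i]]], unname(seqs))
  }
  out
}
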