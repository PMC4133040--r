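#' Specification of a synthetic AT-rich locus with planted site clusters
#'
#' Emulates ascidian non-coding sequence: an independent-letter background at
#' `at_fraction` A+T (default 0.65), with cis-regulatory modules planted as
#' ordered motif words separated by background spacers. With
#' `exclusion = TRUE`, accidental background occurrences of the tracked
#' motifs are scrubbed by rejection-resampling, so the planted sites are the
#' only hits.
#'
#' @param length locus length in bp.
#' @param at_fraction background A+T proportion, in (0, 1).
#' @param plants list of plants; each plant is a list with `position`
#'   (0-based start), `words` (character vector of site words, in order) and
#'   optional `spacers` (integer vector, one fewer than `words`; default 10).
#' @param exclusion scrub accidental background hits of the tracked motifs.
#' @param tracked_motifs motif set whose accidental hits are scrubbed
#'   (default: [default_motif_set()] plus strict Otx).
#' @return object of class `"locus_spec"`.
#' @export
locus_spec <- function(length, at_fraction = 0.65, plants = list(),
                       exclusion = TRUE,
                       tracked_motifs = default_motif_set(strict = TRUE)) {
  stopifnot(length >= 1, at_fraction > 0, at_fraction < 1)
  plants <- lapply(plants, function(p) {
    stopifnot(!is.null(p$position), !is.null(p$words))
    if (is.null(p$spacers)) p$spacers <- rep(10L, max(0L,
                                                     length(p$words) - 1L))
    stopifnot(length(p$spacers) == max(0L, length(p$words) - 1L))
    p$width <- sum(nchar(p$words)) + sum(p$spacers)
    p
  })
  # plants must fit without overlap
  if (length(plants)) {
    s <- vapply(plants, `[[`, numeric(1), "position")
    e <- s + vapply(plants, `[[`, numeric(1), "width")
    o <- order(s); s <- s[o]; e <- e[o]
    if (any(s < 0) || any(e > length))
      stop("specification error: plant outside locus bounds")
    if (length(s) > 1L && any(s[-1] < e[-length(e)]))
      stop("specification error: plants overlap")
  }
  structure(list(length = as.integer(length), at_fraction = at_fraction,
                 plants = plants, exclusion = isTRUE(exclusion),
                 tracked_motifs = tracked_motifs),
            class = "locus_spec")
}

# rejection-resampling of non-planted positions until no tracked-motif hit
# touches them (hits fully inside planted intervals are the intended ones)
scrub_accidental <- function(chars, planted_mask, motifs, at_fraction,
                             max_iter = 200L) {
  for (iter in seq_len(max_iter)) {
    seqstr <- paste(chars, collapse = "")
    hits <- find_all_sites(seqstr, motifs)
    acc <- which(vapply(seq_len(nrow(hits)), function(i)
      any(!planted_mask[(hits$start[i] + 1L):hits$end[i]]), logical(1)))
    if (!length(acc)) return(chars)
    pos <- unique(unlist(lapply(acc, function(i)
      (hits$start[i] + 1L):hits$end[i])))
    pos <- pos[!planted_mask[pos]]
    chars[pos] <- draw_bases(length(pos), at_fraction)
  }
  stop("exclusion scrubbing did not converge")
}

base_probs <- function(at_fraction) {
  c(A = at_fraction / 2, T = at_fraction / 2,
    G = (1 - at_fraction) / 2, C = (1 - at_fraction) / 2)
}

draw_bases <- function(n, at_fraction) {
  p <- base_probs(at_fraction)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate a synthetic locus with ground truth
#'
#' Deterministic for a fixed seed (one master seed drives background
#' sampling, spacer sampling and scrubbing, in that order). When the spec has
#' `exclusion = TRUE`, accidental hits of the tracked motifs (both strands)
#' are removed by resampling the offending non-planted positions until none
#' remain; planted bases are never touched.
#'
#' @param spec a [locus_spec()].
#' @param seed integer seed.
#' @param max_scrub_iter safety cap on scrubbing rounds.
#' @return list of class `"synthetic_locus"`: `seq`, `truth` (data.frame of
#'   planted site intervals: `start`, `end`, `word`, `crm` index), `crms`
#'   (data.frame of planted CRM intervals), `spec`, `seed`.
#' @export
generate_locus <- function(spec, seed = 1L, max_scrub_iter = 200L) {
  stopifnot(inherits(spec, "locus_spec"))
  set.seed(as.integer(seed))
  chars <- draw_bases(spec$length, spec$at_fraction)

  truth <- data.frame(start = integer(0), end = integer(0),
                      word = character(0), crm = integer(0))
  crms <- data.frame(start = integer(0), end = integer(0))
  planted_mask <- rep(FALSE, spec$length)
  for (k in seq_along(spec$plants)) {
    p <- spec$plants[[k]]
    pos <- as.integer(p$position)
    for (i in seq_along(p$words)) {
      w <- toupper(p$words[i])
      wl <- nchar(w)
      chars[(pos + 1L):(pos + wl)] <- strsplit(w, "", fixed = TRUE)[[1]]
      planted_mask[(pos + 1L):(pos + wl)] <- TRUE
      truth <- rbind(truth, data.frame(start = pos, end = pos + wl,
                                       word = w, crm = k))
      pos <- pos + wl + if (i <= length(p$spacers)) p$spacers[i] else 0L
    }
    crms <- rbind(crms, data.frame(start = as.integer(p$position),
                                   end = pos))
  }

  if (spec$exclusion)
    chars <- scrub_accidental(chars, planted_mask, spec$tracked_motifs,
                              spec$at_fraction, max_scrub_iter)
  seqstr <- paste(chars, collapse = "")
  structure(list(seq = seqstr, truth = truth, crms = crms, spec = spec,
                 seed = as.integer(seed)),
            class = "synthetic_locus")
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf("<synthetic_locus> %d bp at %.0f%% AT, %d planted CRM(s), %d planted site(s)\n",
              x$spec$length, 100 * x$spec$at_fraction, nrow(x$crms),
              nrow(x$truth)))
  invisible(x)
}

#' Diverge a synthetic locus into a site-preserving "ortholog"
#'
#' Emulates enhancer evolution in which the flanking sequence diverges beyond
#' alignability while the binding-site combination is retained: point
#' substitutions (at `sub_rate` per base) and single-base indels (at
#' `indel_rate` per base) are applied only outside the planted site
#' intervals; planted words are preserved verbatim unless
#' `preserve_sites = FALSE`.
#'
#' @param locus a `synthetic_locus` from [generate_locus()].
#' @param sub_rate substitution probability per non-planted base, in [0, 1).
#' @param indel_rate single-base insertion/deletion probability per
#'   non-planted base, in [0, 1).
#' @param seed integer seed.
#' @param preserve_sites keep planted words immutable (default `TRUE`).
#' @return list of class `"synthetic_ortholog"`: `seq`, `truth` (planted site
#'   intervals remapped to ortholog coordinates; only when sites are
#'   preserved), `n_sub`, `n_indel`.
#' @export
diverge_ortholog <- function(locus, sub_rate = 0.3, indel_rate = 0,
                             seed = 1L, preserve_sites = TRUE) {
  stopifnot(inherits(locus, "synthetic_locus"),
            sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  set.seed(as.integer(seed))
  chars <- strsplit(locus$seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  planted <- rep(FALSE, n)
  for (i in seq_len(nrow(locus$truth)))
    planted[(locus$truth$start[i] + 1L):locus$truth$end[i]] <- TRUE
  mutable <- if (preserve_sites) which(!planted) else seq_len(n)

  # substitutions: draw a different base for selected positions
  sub_at <- mutable[stats::runif(length(mutable)) < sub_rate]
  for (i in sub_at) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- sample(alt, 1L)
  }
  # indels: per selected position, delete it or insert one base before it
  indel_at <- mutable[stats::runif(length(mutable)) < indel_rate]
  op_del <- stats::runif(length(indel_at)) < 0.5
  keep <- rep(TRUE, n)
  insert_before <- vector("list", n)
  for (j in seq_along(indel_at)) {
    i <- indel_at[j]
    if (op_del[j]) keep[i] <- FALSE
    else insert_before[[i]] <- draw_bases(1L, locus$spec$at_fraction)
  }
  out <- character(0)
  # coordinate map old (0-based) -> new (0-based start of surviving base)
  newpos <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    ins <- insert_before[[i]]
    if (!is.null(ins)) { out <- c(out, ins); cur <- cur + length(ins) }
    newpos[i] <- cur
    if (keep[i]) { out <- c(out, chars[i]); cur <- cur + 1L }
  }
  truth <- locus$truth
  if (preserve_sites && nrow(truth)) {
    truth$start <- newpos[truth$start + 1L]
    truth$end <- truth$start + nchar(truth$word)
  } else {
    truth <- truth[0, ]
  }
  # divergence must not manufacture accidental tracked-motif hits around the
  # preserved sites (e.g. a substitution upgrading a planted GATTA to
  # GGATTA): honor the source spec's exclusion contract on the ortholog too
  if (preserve_sites && locus$spec$exclusion) {
    mask2 <- rep(FALSE, length(out))
    for (i in seq_len(nrow(truth)))
      mask2[(truth$start[i] + 1L):truth$end[i]] <- TRUE
    out <- scrub_accidental(out, mask2, locus$spec$tracked_motifs,
                            locus$spec$at_fraction)
  }
  seqstr <- paste(out, collapse = "")
  structure(list(seq = seqstr, truth = truth,
                 n_sub = length(sub_at), n_indel = length(indel_at)),
            class = "synthetic_ortholog")
}

#' Planted-CRM recovery benchmark
#'
#' Generates `n_loci` independent loci from a spec template (the template's
#' seed stream is advanced per locus from the master seed), scans each with
#' [crm_scan()], and scores recovery against the planted ground truth: a
#' reported region is a true positive when it overlaps a planted CRM, a
#' planted CRM is recovered when some reported region overlaps it.
#'
#' @param n_loci number of loci (>= 1).
#' @param spec a [locus_spec()] template.
#' @param config a [scan_config()].
#' @param seed master seed.
#' @return list of class `"recovery_result"`: `sensitivity` (recovered CRMs /
#'   planted CRMs; `NA` when nothing is planted), `precision` (true-positive
#'   regions / reported regions; `NA` when nothing is reported), `n_crms`,
#'   `n_regions`, `n_true_positive`, `per_locus` data.frame.
#' @export
recovery_experiment <- function(n_loci, spec, config = scan_config(),
                                seed = 1L) {
  stopifnot(n_loci >= 1, inherits(spec, "locus_spec"))
  seeds <- as.integer(seed) + seq_len(n_loci) - 1L
  per <- lapply(seq_len(n_loci), function(i) {
    loc <- generate_locus(spec, seed = seeds[i])
    sc <- crm_scan(loc$seq, config, name = paste0("locus", i))
    r <- sc$regions
    overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2
    tp_region <- if (nrow(r)) vapply(seq_len(nrow(r)), function(j)
      any(overlaps(r$start[j], r$end[j], loc$crms$start, loc$crms$end)),
      logical(1)) else logical(0)
    hit_crm <- if (nrow(loc$crms)) vapply(seq_len(nrow(loc$crms)), function(j)
      any(overlaps(loc$crms$start[j], loc$crms$end[j], r$start, r$end)),
      logical(1)) else logical(0)
    data.frame(locus = i, n_crms = nrow(loc$crms), n_regions = nrow(r),
               n_tp = sum(tp_region), n_recovered = sum(hit_crm))
  })
  per <- do.call(rbind, per)
  n_crms <- sum(per$n_crms); n_regions <- sum(per$n_regions)
  structure(list(
    sensitivity = if (n_crms) sum(per$n_recovered) / n_crms else NA_real_,
    precision = if (n_regions) sum(per$n_tp) / n_regions else NA_real_,
    n_crms = n_crms, n_regions = n_regions,
    n_true_positive = sum(per$n_tp), per_locus = per, seed = seed
  ), class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "<recovery_result> %d locus/loci: sensitivity %s, precision %s (%d planted CRMs, %d regions)\n",
    nrow(x$per_locus),
    format(x$sensitivity, digits = 3), format(x$precision, digits = 3),
    x$n_crms, x$n_regions))
  invisible(x)
}

#' A standard qualifying plant: the base combination plus L extra GATTAs
#'
#' Convenience builder of a plant (see [locus_spec()]) holding one strict Otx
#' word, `extra_gatta` degenerate Otx words, one Fox word and one Smad
#' Binding Element, with the given spacer length, so that the plant fits one
#' scan window and qualifies at ladder level `extra_gatta`.
#'
#' @param position 0-based plant start.
#' @param extra_gatta number of additional degenerate GATTA words.
#' @param spacer spacer length between consecutive words.
#' @return a plant list.
#' @export
crm_plant <- function(position, extra_gatta = 2L, spacer = 12L) {
  words <- c("GGATTA", rep("GATTA", extra_gatta), "AAACA", "AGAC")
  list(position = position, words = words,
       spacers = rep(as.integer(spacer), length(words) - 1L))
}
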