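#' Define a site-destroying mutation recipe
#'
#' A recipe pairs an IUPAC `target` pattern (located on both strands) with a
#' `template` of the same length in which lower-case letters are concrete
#' replacement bases and upper-case positions are copied unchanged from the
#' original sequence. This is the notation used to report enhancer mutants,
#' e.g. `GATTA -> GcTTA` destroys the canonical Otx word with a single core
#' substitution, and `AGAC -> ctAC` destroys a Smad Binding Element.
#'
#' @param target IUPAC pattern to locate.
#' @param template equal-length replacement template; at least one lower-case
#'   concrete base.
#' @param name optional recipe label.
#' @return an object of class `"mutation_recipe"`.
#' @examples
#' mutation_recipe("GATTA", "GcTTA")
#' @export
mutation_recipe <- function(target, template, name = NULL) {
  stopifnot(is.character(target), length(target) == 1L,
            is.character(template), length(template) == 1L)
  if (nchar(target) != nchar(template))
    stop("target and template must have equal length")
  tl <- strsplit(template, "", fixed = TRUE)[[1]]
  lower <- tl %in% c("a", "c", "g", "t")
  if (!any(lower))
    stop("template must mark at least one changed position in lower case")
  if (any(!lower & !(tl %in% IUPAC_LETTERS)))
    stop("upper-case template positions must be IUPAC letters")
  # validate target through the motif machinery (alphabet check); length >= 3
  tu <- strsplit(toupper(target), "", fixed = TRUE)[[1]]
  bad <- which(!(tu %in% IUPAC_LETTERS))
  if (length(bad))
    stop("invalid target: non-IUPAC character at position ", bad[1])
  if (is.null(name)) name <- paste0(target, ">", template)
  structure(list(name = name, target = toupper(target), template = template,
                 changed = which(lower),
                 replacement = toupper(tl)[lower]),
            class = "mutation_recipe")
}

#' @export
print.mutation_recipe <- function(x, ...) {
  cat(sprintf("<mutation_recipe> %s: %s -> %s\n", x$name, x$target,
              x$template))
  invisible(x)
}

# forward-strand edits for one hit of the recipe's target:
# returns data.frame(pos (0-based), to)
recipe_edits <- function(recipe, start, strand) {
  w <- nchar(recipe$target)
  if (strand == "+") {
    data.frame(pos = start + recipe$changed - 1L, to = recipe$replacement,
               stringsAsFactors = FALSE)
  } else {
    # apply the template in reverse-complement space, fold back: template
    # position j (1-based) maps to forward position start + w - j, base
    # complemented
    data.frame(pos = start + w - recipe$changed,
               to = unname(IUPAC_COMPLEMENT[recipe$replacement]),
               stringsAsFactors = FALSE)
  }
}

#' Apply a mutation recipe to a sequence
#'
#' Locates every occurrence of the recipe target on both strands, rewrites
#' the selected occurrences through the template (strand `-` hits are
#' rewritten in reverse-complement space so the destroyed word is the motif
#' itself), and returns the variant together with a change log and per-class
#' motif counts before and after. Length is always preserved.
#'
#' Overlapping selected hits whose rewrites disagree at a shared position
#' raise a conflict error listing the positions; the caller resolves the
#' conflict via `which`.
#'
#' @param seq DNA string.
#' @param recipe a [mutation_recipe()], or a list of recipes applied jointly.
#' @param which `"all"` (default) or an integer vector selecting hits (in
#'   order of the combined hit list, by start).
#' @param motifs motif set used for the before/after counts.
#' @return an object of class `"variant_report"`: list with `variant_seq`,
#'   `changes` (data.frame: `pos` 0-based, `from`, `to`, `recipe`, `strand`),
#'   `counts_before`, `counts_after`, `n_sites_rewritten`.
#' @examples
#' apply_recipe("GATTA", mutation_recipe("GATTA", "GcTTA"))$variant_seq
#' @export
apply_recipe <- function(seq, recipe, which = "all",
                         motifs = default_motif_set()) {
  seq <- check_dna(seq)
  recipes <- if (inherits(recipe, "mutation_recipe")) list(recipe) else recipe
  stopifnot(all(vapply(recipes, inherits, logical(1), "mutation_recipe")))

  hits <- do.call(rbind, lapply(recipes, function(r) {
    h <- find_sites(seq, motif(paste0("t:", r$name), r$target, "canonical",
                               "Otx"))
    if (nrow(h)) h$recipe <- r$name
    h
  }))
  if (is.null(hits) || nrow(hits) == 0L) {
    rep0 <- structure(list(
      variant_seq = seq,
      changes = data.frame(pos = integer(0), from = character(0),
                           to = character(0), recipe = character(0),
                           strand = character(0)),
      counts_before = count_by_class(seq, motifs),
      counts_after = count_by_class(seq, motifs),
      n_sites_rewritten = 0L), class = "variant_report")
    return(rep0)
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  if (!identical(which, "all")) {
    stopifnot(is.numeric(which), all(which >= 1), all(which <= nrow(hits)))
    hits <- hits[as.integer(which), , drop = FALSE]
  }

  rmap <- lapply(recipes, identity)
  names(rmap) <- vapply(recipes, `[[`, character(1), "name")
  edits <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    e <- recipe_edits(rmap[[hits$recipe[i]]], hits$start[i], hits$strand[i])
    e$recipe <- hits$recipe[i]
    e$strand <- hits$strand[i]
    e
  }))
  # conflict detection: same forward position written with different bases
  edits <- edits[order(edits$pos), , drop = FALSE]
  n_to <- tapply(edits$to, edits$pos, function(v) length(unique(v)))
  conflicting <- names(n_to)[n_to > 1L]
  if (length(conflicting))
    stop("conflicting overlapping rewrites at position(s) ",
         paste(conflicting, collapse = ", "),
         "; select non-conflicting hits via `which`")
  edits <- edits[!duplicated(edits$pos), , drop = FALSE]

  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  from <- chars[edits$pos + 1L]
  changed <- from != edits$to
  chars[edits$pos + 1L] <- edits$to
  variant <- paste(chars, collapse = "")

  changes <- data.frame(pos = edits$pos[changed], from = from[changed],
                        to = edits$to[changed], recipe = edits$recipe[changed],
                        strand = edits$strand[changed],
                        stringsAsFactors = FALSE)
  changes <- changes[order(changes$pos), , drop = FALSE]
  rownames(changes) <- NULL
  structure(list(variant_seq = variant,
                 changes = changes,
                 counts_before = count_by_class(seq, motifs),
                 counts_after = count_by_class(variant, motifs),
                 n_sites_rewritten = nrow(hits)),
            class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat(sprintf("<variant_report> %d site(s) rewritten, %d base(s) changed\n",
              x$n_sites_rewritten, nrow(x$changes)))
  ba <- merge(x$counts_before, x$counts_after,
              by = c("motif_name", "factor", "klass"),
              suffixes = c("_before", "_after"))
  print(ba, row.names = FALSE)
  invisible(x)
}

#' The shipped enhancer mutation construct table
#'
#' The named recipe combinations of the msxb-B mutation series. Each
#' construct is a list of [mutation_recipe()]s applied jointly:
#' \describe{
#'   \item{Msxb-D}{canonical Otx sites, single core change (GATTA -> GcTTA).}
#'   \item{Msxb-I}{all Otx sites, canonical and non-canonical, two core
#'     changes (GNATTA -> GNcgTA; applied as GHATTA -> GHcgTA plus
#'     GATTA -> GcgTA so that canonical sites not preceded by G are also
#'     destroyed).}
#'   \item{Msxb-L}{Smad Binding Elements (AGAC -> ctAC).}
#'   \item{Msxb-E}{the overlapping canonical Fox pair, one change shared by
#'     both cores (AAACAAACA -> AAACgAACA).}
#'   \item{Msxb-H}{the overlapping canonical Fox pair, one change in each
#'     core (AAACAAACA -> AAgCAAgCA).}
#'   \item{Msxb-G}{degenerate Fox sites (AACA -> AgCA); [build_series()]
#'     restricts it to AACA hits not overlapping a canonical AAACA site.}
#'   \item{Msxb-F}{Msxb-D plus Msxb-H (Otx and overlapping Fox mutated).}
#' }
#' @return named list of recipe lists.
#' @export
msxb_construct_table <- function() {
  otx_can <- mutation_recipe("GATTA", "GcTTA", "Otx-canonical-kill")
  otx_all_non <- mutation_recipe("GHATTA", "GHcgTA", "Otx-non-canonical-kill")
  otx_all_can <- mutation_recipe("GATTA", "GcgTA", "Otx-core-kill")
  sbe <- mutation_recipe("AGAC", "ctAC", "SBE-kill")
  fox_shared <- mutation_recipe("AAACAAACA", "AAACgAACA", "Fox-overlap-shared")
  fox_each <- mutation_recipe("AAACAAACA", "AAgCAAgCA", "Fox-overlap-each")
  fox_degen <- mutation_recipe("AACA", "AgCA", "Fox-degenerate-kill")
  list(
    `Msxb-D` = list(otx_can),
    `Msxb-I` = list(otx_all_non, otx_all_can),
    `Msxb-L` = list(sbe),
    `Msxb-E` = list(fox_shared),
    `Msxb-H` = list(fox_each),
    `Msxb-G` = list(fox_degen),
    `Msxb-F` = list(otx_can, fox_each)
  )
}

#' Build the full mutation series of an enhancer
#'
#' Applies every construct of a construct table to the enhancer and returns
#' one [apply_recipe()] report per construct. The degenerate-Fox construct
#' (recipes targeting `AACA`) is restricted to hits that do not overlap a
#' canonical AAACA site, mirroring the reported mutants in which only the
#' stand-alone degenerate words were altered.
#'
#' @param seq enhancer DNA string.
#' @param constructs named list of recipe lists (default
#'   [msxb_construct_table()]).
#' @param motifs motif set for before/after counts.
#' @return named list of `variant_report` objects, class `"mutation_series"`.
#' @export
build_series <- function(seq, constructs = msxb_construct_table(),
                         motifs = default_motif_set()) {
  seq <- check_dna(seq)
  if (length(constructs) == 0L)
    return(structure(stats::setNames(list(), character(0)),
                     class = "mutation_series"))
  if (is.null(names(constructs)) || any(!nzchar(names(constructs))))
    stop("configuration error: constructs must be named")
  bad <- !vapply(constructs, function(cc)
    is.list(cc) && length(cc) > 0 &&
      all(vapply(cc, inherits, logical(1), "mutation_recipe")), logical(1))
  if (any(bad))
    stop("configuration error: construct(s) without valid recipes: ",
         paste(names(constructs)[bad], collapse = ", "))
  out <- lapply(names(constructs), function(nm) {
    cc <- constructs[[nm]]
    degen <- vapply(cc, function(r) r$target == "AACA", logical(1))
    if (any(degen)) {
      # select stand-alone AACA hits only
      rep1 <- if (any(!degen)) apply_recipe(seq, cc[!degen], motifs = motifs)
              else NULL
      base_seq <- if (is.null(rep1)) seq else rep1$variant_seq
      r <- cc[degen][[1]]
      h <- find_sites(base_seq, motif("t", r$target, "non-canonical", "Fox"))
      can <- find_sites(base_seq, motif("c", "AAACA", "canonical", "Fox"))
      keep <- which(!vapply(seq_len(nrow(h)), function(i)
        any(can$start < h$end[i] & can$end > h$start[i]), logical(1)))
      rep2 <- apply_recipe(base_seq, r, which = keep, motifs = motifs)
      if (!is.null(rep1)) {
        rep2$changes <- rbind(rep1$changes, rep2$changes)
        rep2$changes <- rep2$changes[order(rep2$changes$pos), , drop = FALSE]
        rep2$counts_before <- rep1$counts_before
        rep2$n_sites_rewritten <- rep1$n_sites_rewritten +
          rep2$n_sites_rewritten
      }
      rep2
    } else {
      apply_recipe(seq, cc, motifs = motifs)
    }
  })
  names(out) <- names(constructs)
  structure(out, class = "mutation_series")
}

#' @export
print.mutation_series <- function(x, ...) {
  cat("<mutation_series> with", length(x), "construct(s)\n")
  for (nm in names(x))
    cat(sprintf("  %-8s %d site(s) rewritten, %d base(s) changed\n",
                nm, x[[nm]]$n_sites_rewritten, nrow(x[[nm]]$changes)))
  invisible(x)
}

#' Verify that a mutation knocked out its target and nothing else appeared
#'
#' Passes when (i) every targeted factor/class combination whose count
#' dropped reaches zero for the targeted class, and (ii) no new hit of any
#' tracked motif was created by the rewrite. Collateral (newly created) hits
#' are listed on failure.
#'
#' @param report a `variant_report` from [apply_recipe()].
#' @param motifs tracked motif set.
#' @param targeted character vector of motif names whose count must be zero
#'   in the variant; default: every motif whose count decreased.
#' @return list of class `"knockout_check"`: `pass`, `residual` (targeted
#'   motifs still present), `collateral` (`site_hits` of newly created hits).
#' @export
verify_knockout <- function(report, motifs = default_motif_set(),
                            targeted = NULL) {
  stopifnot(inherits(report, "variant_report"))
  before <- report$counts_before
  after <- report$counts_after
  if (is.null(targeted))
    targeted <- before$motif_name[after$count < before$count]
  residual <- targeted[after$count[match(targeted, after$motif_name)] > 0L]

  # collateral: hits in the variant absent from the input (by motif,
  # interval, strand)
  key <- function(h) paste(h$motif_name, h$start, h$end, h$strand)
  hb <- find_all_sites_seq_safe(report, motifs, what = "before")
  ha <- find_all_sites_seq_safe(report, motifs, what = "after")
  new <- ha[!(key(ha) %in% key(hb)), , drop = FALSE]
  rownames(new) <- NULL
  structure(list(pass = length(residual) == 0L && nrow(new) == 0L,
                 residual = residual, collateral = new),
            class = "knockout_check")
}

# reconstruct the pre-mutation sequence from the change log to enumerate hits
find_all_sites_seq_safe <- function(report, motifs, what) {
  seq <- report$variant_seq
  if (what == "before" && nrow(report$changes)) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[report$changes$pos + 1L] <- report$changes$from
    seq <- paste(chars, collapse = "")
  }
  find_all_sites(seq, motifs)
}

#' @export
print.knockout_check <- function(x, ...) {
  cat("<knockout_check>", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$residual))
    cat("  residual target motifs:", paste(x$residual, collapse = ", "), "\n")
  if (nrow(x$collateral)) {
    cat("  collateral new hits:\n")
    print(x$collateral)
  }
  invisible(x)
}
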