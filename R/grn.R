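GRN_NODES <- c("Fgf", "Erk", "Otx", "NodalL", "NodalSigHigh", "NodalSigLow",
               "Msxb", "Delta2", "Chordin", "Dmrt1", "Epi")

GRN_PERTURBATIONS <- c("mek_block", "alk_block", "lefty_oe", "otx_mo",
                       "otx_hd_enr", "fgf_oe", "nodal_oe", "otx_oe")

GRN_LINEAGES <- c("a", "b")

#' Cell context for a Boolean network simulation
#'
#' A context names the ectodermal lineage of the reported cell (a-line
#' anterior, b-line posterior), a set of global perturbations
#' (pharmacological treatments and pan-ectodermal overexpression constructs),
#' and whether the vegetal FGF signal reaches the cell. With
#' `fgf_input = TRUE` (default) the context describes the induced neural
#' precursor (a6.5 or b6.5); with `FALSE` it describes uninduced ectoderm of
#' the same lineage, used for "ectopic expression" observations.
#'
#' @param lineage `"a"` or `"b"` (also accepts `"a-line"` / `"b-line"`).
#' @param perturbations character vector over `mek_block` (U0126),
#'   `alk_block` (SB431542), `lefty_oe`, `otx_mo`, `otx_hd_enr`, `fgf_oe`
#'   (bFGF or pFOG-FGF9/16/20), `nodal_oe`, `otx_oe`.
#' @param fgf_input does vegetal FGF reach the reported cell?
#' @return object of class `"cell_context"`.
#' @export
cell_context <- function(lineage = "b", perturbations = character(0),
                         fgf_input = TRUE) {
  lineage <- sub("-line$", "", lineage)
  lineage <- match.arg(lineage, GRN_LINEAGES)
  perturbations <- unique(as.character(perturbations))
  bad <- setdiff(perturbations, GRN_PERTURBATIONS)
  if (length(bad))
    stop("configuration error: unknown perturbation label(s): ",
         paste(bad, collapse = ", "))
  structure(list(lineage = lineage, perturbations = perturbations,
                 fgf_input = isTRUE(fgf_input)),
            class = "cell_context")
}

#' The shipped posterior-neural Boolean ruleset
#'
#' Synchronous-convergence Boolean update rules encoding the FGF/Otx/Nodal
#' network acting in ascidian posterior (b-line) neural precursors, with an
#' initiation-phase rule for the Nodal ligand (first update: direct FGF
#' induction restricted to the b-line, or forced by overexpression drivers)
#' and a maintenance rule thereafter (Otx together with autocrine Nodal
#' signaling, or the drivers). Nodal signaling is two-tiered: the high
#' (autocrine) tier needed by *Msxb*/*Delta2* requires ligand expression in
#' the responding cell itself, while the low (ectoderm-wide) tier sufficient
#' for *Chordin* is reached whenever any ectodermal cell expresses the
#' ligand.
#'
#' Each rule is an R function of `(s, ctx, cells)` where `s` is the named
#' logical state vector of the cell being updated, `ctx` the evaluation
#' context (perturbation flags, `fgf_input`, `lineage`) and `cells` the list
#' of current state vectors of every cell in the embryo (for the
#' ectoderm-wide tier).
#'
#' @return object of class `"grn_ruleset"`: list with `init` and `maint`
#'   rule lists and `nodes`.
#' @export
default_ruleset <- function() {
  maint <- list(
    Fgf = function(s, ctx, cells) ctx$fgf_input || ctx$fgf_oe,
    Erk = function(s, ctx, cells) s[["Fgf"]] && !ctx$mek_block,
    Otx = function(s, ctx, cells)
      (s[["Erk"]] || ctx$otx_oe) && !ctx$otx_mo && !ctx$otx_hd_enr,
    NodalSigHigh = function(s, ctx, cells)
      s[["NodalL"]] && !ctx$alk_block && !ctx$lefty_oe,
    NodalSigLow = function(s, ctx, cells)
      any(vapply(cells, `[[`, logical(1), "NodalL")) &&
        !ctx$alk_block && !ctx$lefty_oe,
    NodalL = function(s, ctx, cells)
      (s[["Otx"]] && s[["NodalSigHigh"]]) || ctx$nodal_oe ||
        (ctx$otx_oe && s[["Otx"]]),
    Msxb = function(s, ctx, cells)
      s[["Otx"]] && (s[["NodalSigHigh"]] || ctx$otx_oe),
    Delta2 = function(s, ctx, cells)
      s[["Otx"]] && (s[["NodalSigHigh"]] || ctx$otx_oe),
    Chordin = function(s, ctx, cells) s[["NodalSigLow"]],
    Dmrt1 = function(s, ctx, cells)
      ctx$lineage == "a" && s[["Erk"]] && !s[["NodalSigHigh"]],
    Epi = function(s, ctx, cells) !s[["Erk"]]
  )
  init <- maint
  init$NodalL <- function(s, ctx, cells)
    (s[["Erk"]] && ctx$lineage == "b") || ctx$nodal_oe ||
      (ctx$otx_oe && s[["Otx"]])
  structure(list(nodes = GRN_NODES, init = init, maint = maint),
            class = "grn_ruleset")
}

#' @export
print.grn_ruleset <- function(x, ...) {
  cat("<grn_ruleset> nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

ctx_flags <- function(context) {
  fl <- as.list(stats::setNames(GRN_PERTURBATIONS %in% context$perturbations,
                                GRN_PERTURBATIONS))
  fl$fgf_input <- context$fgf_input
  fl$lineage <- context$lineage
  fl
}

# update one cell in place-order (deterministic sweep: each node reads the
# newest values already computed this step; signal nodes read NodalL of the
# previous step through `cells`)
sweep_cell <- function(rules, s, ctx, cells) {
  for (nd in GRN_NODES) s[[nd]] <- isTRUE(rules[[nd]](s, ctx, cells))
  s
}

#' Simulate the Boolean network to its fixed point
#'
#' The embryo is modeled as one cell per ectodermal lineage (the induced a-
#' and b-line neural precursors) plus, when the focal context has
#' `fgf_input = FALSE`, a third reporter cell of the focal lineage that does
#' not receive vegetal FGF. All cells share the (global) perturbations. The
#' first update uses the initiation-phase Nodal rule, later updates the
#' maintenance rule; iteration stops at the first repeated state.
#'
#' @param ruleset a [default_ruleset()]-shaped object.
#' @param context a [cell_context()].
#' @param max_steps maximum number of update steps (>= 2).
#' @return object of class `"grn_state"`: list with `states` (named logical
#'   vector for the focal cell), `embryo` (all cells), `converged`, `steps`.
#' @examples
#' grn_simulate(default_ruleset(), cell_context("b"))$states[["Msxb"]]
#' @export
grn_simulate <- function(ruleset = default_ruleset(),
                         context = cell_context(), max_steps = 12L) {
  stopifnot(inherits(context, "cell_context"), max_steps >= 2L)
  base <- ctx_flags(context)
  cell_ctxs <- list(
    a = utils::modifyList(base, list(lineage = "a", fgf_input = TRUE)),
    b = utils::modifyList(base, list(lineage = "b", fgf_input = TRUE))
  )
  focal <- context$lineage
  if (!context$fgf_input) {
    cell_ctxs$reporter <- utils::modifyList(
      base, list(lineage = context$lineage, fgf_input = FALSE))
    focal <- "reporter"
  }

  blank <- stats::setNames(rep(FALSE, length(GRN_NODES)), GRN_NODES)
  # step 0: seed the input cascade (FGF and its immediate transcriptional
  # consequences) so the initiation rule can read them
  cells <- lapply(cell_ctxs, function(cx) {
    s <- blank
    s[["Fgf"]] <- cx$fgf_input || cx$fgf_oe
    s[["Erk"]] <- s[["Fgf"]] && !cx$mek_block
    s[["Otx"]] <- (s[["Erk"]] || cx$otx_oe) && !cx$otx_mo && !cx$otx_hd_enr
    s
  })

  converged <- FALSE
  steps <- 0L
  for (step in seq_len(max_steps)) {
    rules <- if (step == 1L) ruleset$init else ruleset$maint
    prev <- cells
    cells <- lapply(names(cells), function(nm)
      sweep_cell(rules, prev[[nm]], cell_ctxs[[nm]], prev))
    names(cells) <- names(prev)
    steps <- step
    if (step >= 2L && identical(cells, prev)) { converged <- TRUE; break }
  }
  structure(list(states = cells[[focal]], embryo = cells,
                 converged = converged, steps = steps,
                 context = context),
            class = "grn_state")
}

#' @export
print.grn_state <- function(x, ...) {
  on_ <- names(x$states)[x$states]
  cat(sprintf("<grn_state> %s-line%s, %s: ON = {%s}%s\n",
              x$context$lineage,
              if (x$context$fgf_input) "" else " (uninduced)",
              if (length(x$context$perturbations))
                paste(x$context$perturbations, collapse = "+")
              else "control",
              paste(on_, collapse = ", "),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' The shipped qualitative observation table
#'
#' Lineage x perturbation x marker outcomes transcribed from the reported
#' in-situ hybridization panels: control and perturbed expression of *Msxb*,
#' *Delta2*, *Chordin*, *Dmrt1*, the epidermis marker (*Ap2-like2*, node
#' `Epi`) and the *Nodal* ligand itself, under MEK inhibition (U0126), Nodal
#' receptor inhibition (SB431542), Lefty, FGF9/16/20, Nodal and Otx
#' overexpression, Otx morpholino and dominant-negative Otx, singly and in
#' the reported combinations. `fgf_input = FALSE` rows describe uninduced
#' ectoderm ("ectopic" panels). Blastomere-level patterning (e.g. the
#' anterior Chordin subdomains) is below the model's one-cell-per-lineage
#' resolution and is excluded.
#'
#' @return data.frame with columns `lineage`, `perturbations`
#'   (comma-separated), `fgf_input`, `marker`, `expected` ("ON"/"OFF"),
#'   `provenance`.
#' @export
default_observations <- function() {
  o <- function(lineage, pert, marker, expected, prov, fgf = TRUE)
    data.frame(lineage = lineage, perturbations = pert, fgf_input = fgf,
               marker = marker, expected = expected, provenance = prov,
               stringsAsFactors = FALSE)
  rbind(
    # control precursors
    o("b", "", "Msxb", "ON", "Fig 2Bi"),
    o("b", "", "Delta2", "ON", "Fig 3B"),
    o("b", "", "Chordin", "ON", "Fig 3C"),
    o("b", "", "Epi", "OFF", "Fig S1C"),
    o("b", "", "NodalL", "ON", "Fig S3A-i"),
    o("a", "", "Dmrt1", "ON", "Fig 3D"),
    o("a", "", "Msxb", "OFF", "Fig 3A"),
    o("a", "", "Dmrt1", "OFF", "Fig 3D", fgf = FALSE),
    # MEK inhibition (U0126)
    o("b", "mek_block", "Msxb", "OFF", "Fig 2Biv"),
    o("b", "mek_block", "Delta2", "OFF", "Fig S1E"),
    o("b", "mek_block", "Chordin", "OFF", "Fig S1F"),
    o("b", "mek_block", "Epi", "ON", "Fig S1G"),
    o("a", "mek_block", "Epi", "ON", "Fig S1G"),
    # Nodal receptor inhibition (SB431542)
    o("b", "alk_block", "Msxb", "OFF", "Fig 2Bvii"),
    o("b", "alk_block", "Delta2", "OFF", "Fig S1I"),
    o("b", "alk_block", "Chordin", "OFF", "Fig S1J"),
    o("b", "alk_block", "Epi", "OFF", "Fig S1K"),
    o("b", "alk_block", "NodalL", "OFF", "Fig S3A (autoregulation)"),
    # Lefty overexpression
    o("b", "lefty_oe", "Msxb", "OFF", "Fig 3I"),
    o("b", "lefty_oe", "Delta2", "OFF", "Fig 3J"),
    o("b", "lefty_oe", "Chordin", "OFF", "Fig 3K"),
    o("a", "lefty_oe", "Dmrt1", "ON", "Fig 3L"),
    o("b", "lefty_oe", "NodalL", "OFF", "Fig S3A-iv"),
    # FGF overexpression: ectopic induction of uninduced ectoderm
    o("b", "fgf_oe", "Msxb", "ON", "Fig 3E", fgf = FALSE),
    o("b", "fgf_oe", "Delta2", "ON", "Fig 3F", fgf = FALSE),
    o("b", "fgf_oe", "Chordin", "ON", "Fig 3G", fgf = FALSE),
    o("a", "fgf_oe", "Dmrt1", "ON", "Fig 3H", fgf = FALSE),
    o("a", "fgf_oe", "Msxb", "OFF", "Fig 3E", fgf = FALSE),
    o("b", "fgf_oe,lefty_oe", "Msxb", "OFF", "Fig 3M", fgf = FALSE),
    o("b", "fgf_oe,lefty_oe", "Delta2", "OFF", "Fig 3N", fgf = FALSE),
    o("b", "fgf_oe,lefty_oe", "Chordin", "OFF", "Fig 3O", fgf = FALSE),
    o("a", "fgf_oe,lefty_oe", "Dmrt1", "ON", "Fig 3P", fgf = FALSE),
    # Nodal overexpression: posteriorization of anterior precursors
    o("a", "nodal_oe", "Msxb", "ON", "Fig 3Q"),
    o("a", "nodal_oe", "Delta2", "ON", "Fig 3R"),
    o("a", "nodal_oe", "Chordin", "ON", "Fig 3S"),
    o("b", "nodal_oe", "Chordin", "ON", "Fig 3S"),
    o("a", "nodal_oe", "Dmrt1", "OFF", "Fig 3T"),
    o("b", "nodal_oe", "Msxb", "OFF", "Fig 3Q (no ectopic)", fgf = FALSE),
    # FGF + Nodal co-overexpression
    o("a", "fgf_oe,nodal_oe", "Msxb", "ON", "Fig 3U", fgf = FALSE),
    o("a", "fgf_oe,nodal_oe", "Delta2", "ON", "Fig 3V", fgf = FALSE),
    o("a", "fgf_oe,nodal_oe", "Dmrt1", "OFF", "Fig 3X", fgf = FALSE),
    # Otx loss of function
    o("b", "otx_mo", "Msxb", "OFF", "Fig 4C"),
    o("b", "otx_mo", "Delta2", "OFF", "Fig 4F"),
    o("b", "otx_hd_enr", "Msxb", "OFF", "Fig S4B"),
    o("b", "otx_hd_enr", "Delta2", "OFF", "Fig S4D"),
    o("b", "otx_hd_enr", "Epi", "OFF", "Fig S4F"),
    o("b", "otx_hd_enr", "NodalL", "OFF", "Fig S3A-iii"),
    # Otx overexpression
    o("b", "otx_oe", "Msxb", "ON", "Fig 4B"),
    o("a", "otx_oe", "Msxb", "ON", "Fig 4B"),
    o("a", "otx_oe", "Delta2", "ON", "Fig 4E"),
    o("b", "otx_oe", "NodalL", "ON", "Fig S3A-ii"),
    o("b", "otx_oe,lefty_oe", "Msxb", "ON", "Fig S3B-iv"),
    o("a", "otx_oe,lefty_oe", "Delta2", "ON", "Fig S3B-viii"),
    # Nodal-mediated posteriorization requires Otx
    o("a", "nodal_oe,otx_hd_enr", "Msxb", "OFF", "Fig S3C"),
    o("a", "nodal_oe,otx_hd_enr", "Delta2", "OFF", "Fig S3C")
  )
}

#' Read / write an observation table as TSV
#' @param path file path.
#' @return `read_observations` returns the observation data.frame.
#' @export
read_observations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = NULL)
  df$perturbations <- as.character(df$perturbations)
  df$perturbations[is.na(df$perturbations)] <- ""
  df
}

#' @rdname read_observations
#' @param observations observation data.frame.
#' @export
write_observations <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

obs_context <- function(row) {
  pert <- strsplit(row$perturbations, ",", fixed = TRUE)[[1]]
  pert <- trimws(pert[nzchar(trimws(pert))])
  cell_context(row$lineage, pert, fgf_input = row$fgf_input)
}

#' Score a ruleset against a qualitative observation table
#'
#' Every observation row is simulated in its context and compared with the
#' expected marker state; the score is the matched fraction.
#'
#' @param ruleset a [default_ruleset()]-shaped object.
#' @param observations a [default_observations()]-shaped data.frame.
#' @param max_steps passed to [grn_simulate()].
#' @return object of class `"grn_consistency"`: `score`, `n`, `mismatches`
#'   (subset of rows with the observed model state added), `results`.
#' @export
consistency_score <- function(ruleset = default_ruleset(),
                              observations = default_observations(),
                              max_steps = 12L) {
  n <- nrow(observations)
  if (is.null(n) || n == 0L)
    return(structure(list(score = 1, n = 0L,
                          mismatches = observations, results = logical(0)),
                     class = "grn_consistency"))
  got <- character(n)
  for (i in seq_len(n)) {
    row <- observations[i, , drop = FALSE]
    sim <- grn_simulate(ruleset, obs_context(row), max_steps)
    if (!sim$converged)
      warning("simulation did not converge for row ", i)
    if (!row$marker %in% names(sim$states))
      stop("configuration error: unknown marker '", row$marker, "'")
    got[i] <- if (sim$states[[row$marker]]) "ON" else "OFF"
  }
  ok <- got == observations$expected
  mm <- observations[!ok, , drop = FALSE]
  if (nrow(mm)) mm$simulated <- got[!ok]
  structure(list(score = mean(ok), n = n, mismatches = mm, results = ok),
            class = "grn_consistency")
}

#' @export
print.grn_consistency <- function(x, ...) {
  cat(sprintf("<grn_consistency> %d/%d observations matched (score %.3f)\n",
              sum(x$results), x$n, x$score))
  if (nrow(x$mismatches)) {
    cat("  mismatches:\n")
    print(x$mismatches, row.names = FALSE)
  }
  invisible(x)
}

#' Marker state across all single perturbations and lineages
#'
#' @param ruleset ruleset to screen.
#' @param marker node name to report.
#' @param fgf_input context flag for all screened cells.
#' @return data.frame `perturbation` x `a`/`b` of "ON"/"OFF" states
#'   (first row: control).
#' @export
perturbation_screen <- function(ruleset = default_ruleset(), marker = "Msxb",
                                fgf_input = TRUE) {
  if (!marker %in% GRN_NODES)
    stop("configuration error: unknown marker '", marker, "'")
  perts <- c("control", GRN_PERTURBATIONS)
  states <- vapply(perts, function(p) {
    pv <- if (p == "control") character(0) else p
    vapply(GRN_LINEAGES, function(l) {
      s <- grn_simulate(ruleset, cell_context(l, pv, fgf_input))
      if (s$states[[marker]]) "ON" else "OFF"
    }, character(1))
  }, character(2))
  data.frame(perturbation = perts, a = states["a", ], b = states["b", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regulatory edges of the shipped ruleset, and edge deletion
#'
#' `grn_edges()` lists the gene-level regulatory edges the shipped rules use.
#' `delete_edge()` returns a modified copy of the shipped ruleset in which
#' one edge is removed: the source's contribution is replaced by its neutral
#' value (FALSE for an activating term, TRUE for an inhibitory one), leaving
#' every other interaction intact. Used to test that each edge is necessary
#' to reproduce the observation table.
#'
#' @return `grn_edges()`: data.frame with `from`, `to`, `sign`.
#' @export
grn_edges <- function() {
  e <- function(from, to, sign) data.frame(from = from, to = to, sign = sign,
                                           stringsAsFactors = FALSE)
  rbind(
    e("Fgf", "Erk", "+"),
    e("Erk", "Otx", "+"),
    e("Erk", "NodalL", "+"),      # initiation-phase induction
    e("Otx", "NodalL", "+"),      # maintenance
    e("NodalSigHigh", "NodalL", "+"),
    e("NodalL", "NodalSigHigh", "+"),
    e("NodalL", "NodalSigLow", "+"),
    e("Otx", "Msxb", "+"),
    e("NodalSigHigh", "Msxb", "+"),
    e("Otx", "Delta2", "+"),
    e("NodalSigHigh", "Delta2", "+"),
    e("NodalSigLow", "Chordin", "+"),
    e("Erk", "Dmrt1", "+"),
    e("NodalSigHigh", "Dmrt1", "-"),
    e("Erk", "Epi", "-")
  )
}

#' @rdname grn_edges
#' @param from,to edge endpoints (node names as in [grn_edges()]).
#' @export
delete_edge <- function(from, to) {
  rs <- default_ruleset()
  edges <- grn_edges()
  row <- edges[edges$from == from & edges$to == to, ]
  if (nrow(row) != 1L)
    stop("configuration error: unknown edge ", from, " -> ", to)
  repl <- list(
    "Fgf->Erk" = function(rs) {
      rs$maint$Erk <- rs$init$Erk <- function(s, ctx, cells) !ctx$mek_block &&
        FALSE
      rs
    },
    "Erk->Otx" = function(rs) {
      f <- function(s, ctx, cells)
        (FALSE || ctx$otx_oe) && !ctx$otx_mo && !ctx$otx_hd_enr
      rs$maint$Otx <- rs$init$Otx <- f
      rs
    },
    "Erk->NodalL" = function(rs) {
      rs$init$NodalL <- function(s, ctx, cells)
        (FALSE && ctx$lineage == "b") || ctx$nodal_oe ||
          (ctx$otx_oe && s[["Otx"]])
      rs
    },
    "Otx->NodalL" = function(rs) {
      rs$maint$NodalL <- function(s, ctx, cells)
        (TRUE && s[["NodalSigHigh"]]) || ctx$nodal_oe ||
          (ctx$otx_oe && s[["Otx"]])
      rs
    },
    "NodalSigHigh->NodalL" = function(rs) {
      rs$maint$NodalL <- function(s, ctx, cells)
        (s[["Otx"]] && TRUE) || ctx$nodal_oe || (ctx$otx_oe && s[["Otx"]])
      rs
    },
    "NodalL->NodalSigHigh" = function(rs) {
      f <- function(s, ctx, cells) TRUE && !ctx$alk_block && !ctx$lefty_oe
      rs$maint$NodalSigHigh <- rs$init$NodalSigHigh <- f
      rs
    },
    "NodalL->NodalSigLow" = function(rs) {
      f <- function(s, ctx, cells) TRUE && !ctx$alk_block && !ctx$lefty_oe
      rs$maint$NodalSigLow <- rs$init$NodalSigLow <- f
      rs
    },
    "Otx->Msxb" = function(rs) {
      f <- function(s, ctx, cells) s[["NodalSigHigh"]] || ctx$otx_oe
      rs$maint$Msxb <- rs$init$Msxb <- f
      rs
    },
    "NodalSigHigh->Msxb" = function(rs) {
      f <- function(s, ctx, cells) s[["Otx"]] && (TRUE || ctx$otx_oe)
      rs$maint$Msxb <- rs$init$Msxb <- f
      rs
    },
    "Otx->Delta2" = function(rs) {
      f <- function(s, ctx, cells) s[["NodalSigHigh"]] || ctx$otx_oe
      rs$maint$Delta2 <- rs$init$Delta2 <- f
      rs
    },
    "NodalSigHigh->Delta2" = function(rs) {
      f <- function(s, ctx, cells) s[["Otx"]] && (TRUE || ctx$otx_oe)
      rs$maint$Delta2 <- rs$init$Delta2 <- f
      rs
    },
    "NodalSigLow->Chordin" = function(rs) {
      f <- function(s, ctx, cells) FALSE
      rs$maint$Chordin <- rs$init$Chordin <- f
      rs
    },
    "Erk->Dmrt1" = function(rs) {
      f <- function(s, ctx, cells) ctx$lineage == "a" && !s[["NodalSigHigh"]]
      rs$maint$Dmrt1 <- rs$init$Dmrt1 <- f
      rs
    },
    "NodalSigHigh->Dmrt1" = function(rs) {
      f <- function(s, ctx, cells) ctx$lineage == "a" && s[["Erk"]]
      rs$maint$Dmrt1 <- rs$init$Dmrt1 <- f
      rs
    },
    "Erk->Epi" = function(rs) {
      f <- function(s, ctx, cells) TRUE
      rs$maint$Epi <- rs$init$Epi <- f
      rs
    }
  )
  key <- paste0(from, "->", to)
  repl[[key]](rs)
}
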