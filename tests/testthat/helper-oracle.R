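# Independent brute-force oracle for motif matching: expands the IUPAC
# pattern to its concrete word set and tests every offset by string
# comparison. Kept deliberately naive (O(n * m)) and free of any package
# matching code.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", W = "W", S = "S", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N")

oracle_revcomp <- function(s) {
  if (!nzchar(s)) return("")
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_expand <- function(core) {
  sets <- ORACLE_IUPAC[strsplit(core, "")[[1]]]
  words <- Reduce(function(acc, s) as.vector(outer(acc, s, paste0)),
                  sets, accumulate = FALSE)
  words
}

# 0-based starts of pattern occurrences on the forward strand; concrete
# expanded words contain no N, so N in the sequence matches nothing
oracle_match <- function(seq, core) {
  words <- oracle_expand(core)
  w <- nchar(core)
  n <- nchar(seq)
  if (n < w) return(integer(0))
  kmers <- substring(seq, 1:(n - w + 1), w:n)
  which(kmers %in% words) - 1L
}

# full both-strand hit table mirroring find_sites semantics, independently
oracle_find <- function(seq, core, strands = "both") {
  plus <- oracle_match(seq, core)
  minus <- if (strands == "both")
    setdiff(oracle_match(seq, oracle_revcomp(core)), plus)
  else integer(0)
  df <- data.frame(start = c(plus, minus),
                   strand = c(rep("+", length(plus)),
                              rep("-", length(minus))))
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random A/C/G/T sequence at a given AT fraction
random_seq <- function(n, at = 0.65) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# oracle per-class counting with most-specific-class suppression, written
# with plain nested loops
oracle_count_by_class <- function(seq, motifs) {
  rank_of <- c(strict = 1, canonical = 2, `non-canonical` = 3)
  hits <- do.call(rbind, lapply(motifs, function(m) {
    h <- oracle_find(seq, m$core)
    if (nrow(h) == 0)
      return(data.frame(name = character(0), start = integer(0),
                        end = integer(0), factor = character(0),
                        rank = numeric(0)))
    data.frame(name = m$name, start = h$start,
               end = h$start + nchar(m$core), factor = m$factor,
               rank = unname(rank_of[m$klass]))
  }))
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(hits))) {
      if (hits$factor[j] == hits$factor[i] && hits$rank[j] < hits$rank[i] &&
          hits$start[j] < hits$end[i] && hits$end[j] > hits$start[i]) {
        keep[i] <- FALSE
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  vapply(motifs, function(m) sum(hits$name == m$name), integer(1))
}

# independent window-scan oracle: enumerate every window, qualify by oracle
# counts, merge runs of qualifying offsets
oracle_scan <- function(seq, window = 300, level = 0) {
  n <- nchar(seq)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  q <- logical(n - window + 1)
  for (i in 0:(n - window)) {
    win <- substr(seq, i + 1, i + window)
    strict <- oracle_find(win, "GGATTA")
    fox <- oracle_find(win, "AAACA")
    sbe <- oracle_find(win, "AGAC")
    gatta <- oracle_find(win, "GATTA")
    # drop GATTA nested inside any GGATTA hit
    if (nrow(strict) && nrow(gatta)) {
      nested <- vapply(seq_len(nrow(gatta)), function(k)
        any(strict$start <= gatta$start[k] &
              gatta$start[k] + 5 <= strict$start + 6), logical(1))
      gatta <- gatta[!nested, , drop = FALSE]
    }
    q[i + 1] <- nrow(strict) >= 1 && nrow(fox) >= 1 && nrow(sbe) >= 1 &&
      nrow(gatta) >= level
  }
  if (!any(q)) return(data.frame(start = integer(0), end = integer(0)))
  offs <- which(q) - 1L
  brk <- c(TRUE, diff(offs) > window)
  grp <- cumsum(brk)
  data.frame(start = as.integer(tapply(offs, grp, min)),
             end = as.integer(tapply(offs, grp, max)) + window)
}
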