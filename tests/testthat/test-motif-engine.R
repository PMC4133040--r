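test_that("IUPAC motif compilation expands degenerate codes correctly", {
  m <- motif("Otx-non", "GHATTA", "non-canonical", "Otx")
  for (word in c("GAATTA", "GCATTA", "GTATTA"))
    expect_equal(nrow(find_sites(word, m, "plus")), 1)
  expect_equal(nrow(find_sites("GGATTA", m, "plus")), 0)

  lit <- motif("Otx-can", "GATTA")
  expect_equal(nrow(find_sites("GATTA", lit, "plus")), 1)
  expect_equal(nrow(find_sites("GACTA", lit, "plus")), 0)

  expect_error(motif("bad", "GAXTA"), "position 3")
  expect_error(motif("bad", "GA"), "length")
  expect_error(motif("bad", ""), "non-empty")
})

test_that("revcomp is the IUPAC involution", {
  expect_equal(revcomp("AAACA"), "TGTTT")
  expect_equal(revcomp("TGTTT"), "AAACA")
  expect_equal(revcomp(""), "")
  expect_error(revcomp("AXC"), "invalid sequence")
  set.seed(42)
  for (i in 1:25) {
    s <- random_seq(sample(1:80, 1))
    expect_equal(revcomp(revcomp(s)), s)
  }
})

test_that("find_sites reports all overlapping hits on both strands", {
  fox <- motif("Fox", "AAACA", "canonical", "Fox")
  h <- find_sites("AAACAAACA", fox)
  expect_equal(h$start, c(0L, 4L))
  expect_equal(h$strand, c("+", "+"))
  expect_equal(h$end - h$start, c(5L, 5L))

  otx <- motif("Otx", "GATTA")
  h <- find_sites("TAATC", otx)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0L)
  expect_equal(h$strand, "-")
  expect_equal(h$matched, "TAATC")

  # degenerate vs literal on the same 6-mer
  expect_equal(nrow(find_sites("GAATTA", otx)), 0)
  expect_equal(nrow(find_sites("GAATTA", motif("Otx-non", "GHATTA",
                                               "non-canonical", "Otx"))), 1)
})

test_that("N in the sequence matches no motif letter", {
  otx <- motif("Otx", "GATTA")
  expect_equal(nrow(find_sites("GATNA", otx)), 0)
  expect_equal(nrow(find_sites("GANTTANNN", motif("x", "GNATTA"))), 0)
  expect_equal(nrow(find_sites("NGATTAN", otx)), 1)
})

test_that("palindromic hits are reported once, on the plus strand", {
  pal <- motif("pal", "AGCT")  # reverse complement of itself
  h <- find_sites("TAGCTT", pal)
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
})

test_that("find_sites agrees with the brute-force oracle on random sequences", {
  set.seed(7)
  motifs <- default_motif_set(strict = TRUE)
  for (i in 1:150) {
    s <- random_seq(sample(20:120, 1))
    for (m in motifs) {
      got <- find_sites(s, m)
      exp <- oracle_find(s, m$core)
      expect_equal(got$start, exp$start, info = paste(m$name, s))
      expect_equal(got$strand, exp$strand, info = paste(m$name, s))
    }
  }
})

test_that("hit intervals are strand-symmetric under reverse complementation", {
  set.seed(11)
  motifs <- default_motif_set(strict = TRUE)
  for (i in 1:40) {
    s <- random_seq(80)
    n <- nchar(s)
    for (m in motifs) {
      h1 <- find_sites(s, m)
      h2 <- find_sites(revcomp(s), m)
      # mirror h2 intervals back into s coordinates
      mirrored <- sort(n - h2$end)
      expect_equal(sort(h1$start), mirrored, info = m$name)
    }
  }
})

test_that("counting is translation invariant", {
  set.seed(13)
  otx <- motif("Otx", "GATTA")
  s <- paste0("GATTA", random_seq(40), "TAATC")
  for (k in c(1, 7, 30)) {
    pad <- strrep("C", k)  # C background cannot complete a GATTA/TAATC
    h0 <- find_sites(s, otx)
    hk <- find_sites(paste0(pad, s), otx)
    expect_equal(hk$start, h0$start + k)
    expect_equal(hk$strand, h0$strand)
  }
})

test_that("per-class counts suppress less specific overlapping hits", {
  cc <- count_by_class("AAACAAACA")
  expect_equal(cc$count[cc$motif_name == "Fox-canonical"], 2L)
  expect_equal(cc$count[cc$motif_name == "Fox-non-canonical"], 0L)

  cc <- count_by_class("GATTAAGAC")
  expect_equal(cc$count[cc$motif_name == "Otx-canonical"], 1L)
  expect_equal(cc$count[cc$motif_name == "SBE"], 1L)
  expect_equal(sum(cc$count[cc$factor == "Fox"]), 0L)

  # a stand-alone degenerate Fox word is still counted
  cc <- count_by_class("TTAACATT")
  expect_equal(cc$count[cc$motif_name == "Fox-non-canonical"], 1L)

  # GATTA nested in strict GGATTA counts once at the strict class
  cc <- count_by_class("GGATTA", default_motif_set(strict = TRUE))
  expect_equal(cc$count[cc$motif_name == "Otx-strict"], 1L)
  expect_equal(cc$count[cc$motif_name == "Otx-canonical"], 0L)
})

test_that("per-class counts match the independent oracle on AT-rich sequence", {
  set.seed(17)
  motifs <- default_motif_set(strict = TRUE)
  s <- random_seq(10000, at = 0.65)
  got <- count_by_class(s, motifs)
  exp <- oracle_count_by_class(s, motifs)
  expect_equal(got$count, unname(exp))
  expect_gt(sum(got$count), 0)  # AT-rich background does produce hits
})

test_that("motif sets round-trip through their TSV configuration", {
  ms <- default_motif_set(strict = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_set(ms, path)
  ms2 <- read_motif_set(path)
  expect_equal(names(ms2), names(ms))
  expect_equal(vapply(ms2, `[[`, character(1), "core"),
               vapply(ms, `[[`, character(1), "core"))
  expect_error(motif_set(motif("a", "GATTA"), motif("a", "AGAC", factor = "Smad")),
               "duplicate")
})
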