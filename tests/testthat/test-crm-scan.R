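# scrubbed AT-rich padding without any tracked-motif hit
motif_free_pad <- function(n, seed) {
  loc <- generate_locus(locus_spec(n, exclusion = TRUE), seed = seed)
  loc$seq
}

test_that("window qualification implements the base requirement and ladder", {
  pad <- motif_free_pad(300, seed = 21)
  win <- function(words, total = 300) {
    body <- paste(words, collapse = substr(pad, 1, 12))
    paste0(body, substr(pad, 50, 50 + total - nchar(body) - 1))
  }
  w0 <- win(c("GGATTA", "TGTTT", "AGAC"))
  expect_true(window_qualifies(w0, scan_config(ladder_level = 0)))
  expect_false(window_qualifies(w0, scan_config(ladder_level = 1)))

  w1 <- win(c("GGATTA", "GATTA", "TGTTT", "AGAC"))
  expect_true(window_qualifies(w1, scan_config(ladder_level = 1)))
  expect_false(window_qualifies(w1, scan_config(ladder_level = 2)))

  # the GATTA inside GGATTA does not count as "additional" by default
  # but does when the nesting switch is flipped
  expect_true(window_qualifies(w0, scan_config(ladder_level = 1,
                                               count_nested_gatta = TRUE)))

  expect_false(window_qualifies(strrep("A", 300), scan_config()))
  expect_error(window_qualifies("ACGT", scan_config()), "degenerate")
})

test_that("scan recovers exactly the planted clusters", {
  spec <- locus_spec(10000, plants = list(crm_plant(2000, extra_gatta = 2),
                                          crm_plant(6000, extra_gatta = 2)))
  loc <- generate_locus(spec, seed = 3)
  sc <- crm_scan(loc$seq, scan_config(ladder_level = 2))
  expect_equal(nrow(sc$regions), 2)
  # each region covers its planted CRM
  for (i in 1:2) {
    expect_lte(sc$regions$start[i], loc$crms$start[i])
    expect_gte(sc$regions$end[i], loc$crms$end[i])
  }
  expect_true(all(sc$regions$level >= 2))
})

test_that("a single qualifying window yields one region spanning it", {
  pad <- motif_free_pad(400, seed = 31)
  words <- paste0("GGATTA", substr(pad, 1, 20), "TGTTT",
                  substr(pad, 30, 49), "AGAC")
  win <- paste0(words, substr(pad, 60, 60 + 300 - nchar(words) - 1))
  sc <- crm_scan(win, scan_config())
  expect_equal(nrow(sc$regions), 1)
  expect_equal(sc$regions$start, 0L)
  expect_equal(sc$regions$end, 300L)
})

test_that("the stringency ladder is monotone and regions are nested", {
  spec <- locus_spec(8000, plants = list(crm_plant(1000, extra_gatta = 0),
                                         crm_plant(3500, extra_gatta = 1),
                                         crm_plant(6500, extra_gatta = 2)))
  loc <- generate_locus(spec, seed = 5)
  scans <- lapply(0:3, function(L)
    crm_scan(loc$seq, scan_config(ladder_level = L)))
  n <- vapply(scans, function(s) nrow(s$regions), integer(1))
  expect_equal(n, c(3L, 2L, 1L, 0L))  # the 15 -> 7 -> 4 reduction pattern
  expect_true(all(diff(n) <= 0))
  # footprint nesting: union of level-(L+1) regions inside union of level-L
  for (L in 1:3) {
    hi <- scans[[L + 1]]$regions
    lo <- scans[[L]]$regions
    if (nrow(hi) == 0) next
    for (i in seq_len(nrow(hi)))
      expect_true(any(lo$start <= hi$start[i] & hi$end[i] <= lo$end))
  }
})

test_that("scan equals the brute-force all-windows oracle on small loci", {
  set.seed(41)
  for (rep in 1:3) {
    spec <- locus_spec(2500, plants = list(crm_plant(800, extra_gatta = 1)),
                       exclusion = FALSE)
    loc <- generate_locus(spec, seed = 100 + rep)
    for (L in 0:1) {
      got <- crm_scan(loc$seq, scan_config(ladder_level = L))$regions
      exp <- oracle_scan(loc$seq, window = 300, level = L)
      expect_equal(got$start, exp$start, info = paste("rep", rep, "L", L))
      expect_equal(got$end, exp$end, info = paste("rep", rep, "L", L))
    }
  }
})

test_that("coarser steps that still tile the qualifying run shift regions by less than one step", {
  spec <- locus_spec(5000, plants = list(crm_plant(1500, extra_gatta = 2)))
  loc <- generate_locus(spec, seed = 9)
  r1 <- crm_scan(loc$seq, scan_config(ladder_level = 2, step_bp = 1))$regions
  for (s in c(2L, 5L)) {
    rs <- crm_scan(loc$seq, scan_config(ladder_level = 2,
                                        step_bp = s))$regions
    expect_equal(nrow(rs), nrow(r1))
    expect_true(all(abs(rs$start - r1$start) < s))
    expect_true(all(abs(rs$end - r1$end) < s))
  }
})

test_that("region annotation reports the published compositions of the synthetic stand-ins", {
  counts_of <- function(seqname) {
    cc <- annotate_region(synthetic_enhancer(seqname))$counts
    stats::setNames(cc$count, cc$motif_name)
  }
  b <- counts_of("msxb_B")
  expect_equal(b[["Otx-canonical"]], 3L)
  expect_equal(b[["Fox-canonical"]], 2L)
  expect_equal(b[["SBE"]], 4L)
  expect_equal(b[["Otx-non-canonical"]], 1L)
  expect_equal(b[["Fox-non-canonical"]], 3L)

  pm <- counts_of("pm_msxb_line")
  expect_equal(unname(pm[c("Otx-canonical", "Fox-canonical", "SBE")]),
               c(6L, 7L, 7L))
})

test_that("degenerate inputs are handled", {
  empty <- annotate_region("")
  expect_equal(sum(empty$counts$count), 0L)
  expect_equal(nrow(empty$sites), 0L)
  expect_equal(nrow(crm_scan("", scan_config())$regions), 0L)

  # locus shorter than the window is scanned as one truncated window
  pad <- motif_free_pad(200, seed = 51)
  short <- paste0("GGATTA", substr(pad, 1, 10), "TGTTT", substr(pad, 20, 29),
                  "AGAC", substr(pad, 40, 79))
  sc <- crm_scan(short, scan_config())
  expect_equal(nrow(sc$regions), 1)
  expect_true(sc$truncated_tail)
})
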