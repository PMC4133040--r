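test_that("recipes rewrite targets through their templates", {
  v <- apply_recipe("GATTA", mutation_recipe("GATTA", "GcTTA"))
  expect_equal(v$variant_seq, "GCTTA")
  expect_equal(v$changes$pos, 1L)
  expect_equal(v$changes$from, "A")
  expect_equal(v$changes$to, "C")

  v <- apply_recipe("AGACAGAC", mutation_recipe("AGAC", "ctAC"))
  expect_equal(v$variant_seq, "CTACCTAC")
  expect_equal(nrow(v$changes), 4L)
  expect_equal(v$n_sites_rewritten, 2L)

  # one shared base knocks out both overlapping Fox cores
  v <- apply_recipe("AAACAAACA", mutation_recipe("AAACAAACA", "AAACgAACA"))
  expect_equal(v$variant_seq, "AAACGAACA")
  expect_equal(nrow(v$changes), 1L)
  cb <- v$counts_before; ca <- v$counts_after
  expect_equal(cb$count[cb$motif_name == "Fox-canonical"], 2L)
  expect_equal(ca$count[ca$motif_name == "Fox-canonical"], 0L)
})

test_that("minus-strand hits are rewritten in reverse-complement space", {
  # TAATC is GATTA on the minus strand; destroying the motif itself gives
  # revcomp(GcTTA) = TAAGC
  v <- apply_recipe("TAATC", mutation_recipe("GATTA", "GcTTA"))
  expect_equal(v$variant_seq, "TAAGC")
  expect_equal(v$changes$strand, "-")
  # the rewritten sequence carries no Otx word on either strand
  expect_equal(ca <- v$counts_after$count[v$counts_after$factor == "Otx"],
               c(0L, 0L))
})

test_that("recipe validation catches malformed inputs", {
  expect_error(mutation_recipe("GATTA", "GCTTA"), "lower case")
  expect_error(mutation_recipe("GATTA", "GcTT"), "equal length")
  expect_error(mutation_recipe("GAXTA", "GcXTA"), "IUPAC")
  expect_error(mutation_recipe("GAXTA", "GcTTA"), "non-IUPAC")
})

test_that("conflicting overlapping rewrites are an error, resolvable via `which`", {
  r1 <- mutation_recipe("GATTA", "GcTTA")
  r2 <- mutation_recipe("ATTAC", "gTTAC")
  expect_error(apply_recipe("GATTAC", list(r1, r2)), "conflict")
  # selecting one hit resolves it
  v <- apply_recipe("GATTAC", list(r1, r2), which = 1)
  expect_equal(v$variant_seq, "GCTTAC")
})

test_that("applying a recipe twice equals applying it once", {
  set.seed(91)
  seqs <- c(synthetic_enhancer("msxb_B"),
            replicate(5, random_seq(200)))
  recipes <- list(mutation_recipe("GATTA", "GcTTA"),
                  mutation_recipe("AGAC", "ctAC"))
  for (s in seqs) {
    for (r in recipes) {
      v1 <- apply_recipe(s, r)
      # idempotence holds whenever the rewrite is site-specific (no new
      # target manufactured from flanking context); collateral creation is
      # the case verify_knockout() exists to catch
      if (!verify_knockout(v1)$pass) next
      v2 <- apply_recipe(v1$variant_seq, r)$variant_seq
      expect_identical(v2, v1$variant_seq)
    }
  }
})

test_that("Hamming distance equals changed positions times rewritten sites", {
  set.seed(92)
  r <- mutation_recipe("AGAC", "ctAC")  # 2 lower-case positions
  for (i in 1:5) {
    s <- random_seq(300)
    v <- apply_recipe(s, r)
    hits <- v$n_sites_rewritten
    ham <- sum(strsplit(s, "")[[1]] != strsplit(v$variant_seq, "")[[1]])
    # non-overlapping AGAC/GTCT hits: every rewrite changes exactly 2 bases
    # (unless a changed base coincidentally equals the original)
    expect_lte(ham, 2 * hits)
    expect_equal(ham, nrow(v$changes))
  }
})

test_that("the full construct series reproduces the designed knockouts", {
  enh <- synthetic_enhancer("msxb_B")
  ser <- build_series(enh)
  expect_named(ser, c("Msxb-D", "Msxb-I", "Msxb-L", "Msxb-E", "Msxb-H",
                      "Msxb-G", "Msxb-F"))
  count_of <- function(v, what)
    v$counts_after$count[v$counts_after$motif_name == what]

  # D: canonical Otx gone, non-canonical GAATTA untouched
  expect_equal(count_of(ser[["Msxb-D"]], "Otx-canonical"), 0L)
  expect_equal(count_of(ser[["Msxb-D"]], "Otx-non-canonical"), 1L)
  # I: every Otx word gone
  expect_equal(sum(ser[["Msxb-I"]]$counts_after$count[
    ser[["Msxb-I"]]$counts_after$factor == "Otx"]), 0L)
  # L: every SBE gone
  expect_equal(count_of(ser[["Msxb-L"]], "SBE"), 0L)
  # E and H: overlapping canonical Fox pair gone
  expect_equal(count_of(ser[["Msxb-E"]], "Fox-canonical"), 0L)
  expect_equal(count_of(ser[["Msxb-H"]], "Fox-canonical"), 0L)
  expect_equal(nrow(ser[["Msxb-E"]]$changes), 1L)  # single-base mutant
  # G: stand-alone degenerate Fox gone, canonical pair intact
  expect_equal(count_of(ser[["Msxb-G"]], "Fox-non-canonical"), 0L)
  expect_equal(count_of(ser[["Msxb-G"]], "Fox-canonical"), 2L)
  # F: sensitized double mutant: canonical Otx and canonical Fox both gone
  expect_equal(count_of(ser[["Msxb-F"]], "Otx-canonical"), 0L)
  expect_equal(count_of(ser[["Msxb-F"]], "Fox-canonical"), 0L)

  # every construct is a clean, site-specific knockout
  for (nm in names(ser)) {
    chk <- verify_knockout(ser[[nm]])
    expect_true(chk$pass, info = nm)
  }
  # all variants preserve length
  for (nm in names(ser))
    expect_equal(nchar(ser[[nm]]$variant_seq), unname(nchar(enh)))
})

test_that("verify_knockout flags collateral site creation", {
  # AAGAC: rewriting the SBE yields ACTAC with no new tracked word
  v <- apply_recipe("AAGAC", mutation_recipe("AGAC", "ctAC"))
  expect_equal(v$variant_seq, "ACTAC")
  chk <- verify_knockout(v)
  expect_true(chk$pass)
  expect_equal(nrow(chk$collateral), 0L)

  # identity: nothing applied, vacuous pass
  v0 <- apply_recipe("GGGCCC", mutation_recipe("GATTA", "GcTTA"))
  expect_equal(v0$variant_seq, "GGGCCC")
  expect_true(verify_knockout(v0)$pass)

  # a rewrite that manufactures a Fox word is caught: TGT + emitted TT
  v1 <- apply_recipe("TGTAGAC", mutation_recipe("AGAC", "ttAC"))
  expect_equal(v1$variant_seq, "TGTTTAC")
  chk1 <- verify_knockout(v1)
  expect_false(chk1$pass)
  expect_true("Fox-canonical" %in% chk1$collateral$motif_name)
})

test_that("empty and malformed construct tables are handled", {
  enh <- synthetic_enhancer("msxb_B")
  expect_length(build_series(enh, list()), 0L)
  expect_error(build_series(enh, list(`Msxb-X` = list("not a recipe"))),
               "configuration error")
})
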