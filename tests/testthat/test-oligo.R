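panel <- hdac5_oligo_panel()

test_that("reverse complement maps the sense 20-mer to its antisense probe", {
  expect_equal(reverse_complement(panel$hdac5)$bases, panel$miD2861$bases)
  expect_equal(reverse_complement(panel$miD2861)$bases, panel$hdac5$bases)
  # alphabet preserved: RNA stays RNA
  expect_equal(reverse_complement(panel$passenger)$alphabet, "RNA")
  expect_equal(reverse_complement(oligo_seq("x", "a"))$bases, "t")
  expect_error(oligo_seq("bad", ""), "nchar")
  expect_error(oligo_seq("bad", "acgtx"), "alphabet")
  expect_error(oligo_seq("mixed", "acut"), "alphabet")
  expect_equal(oligo_seq("rna", "acgu")$alphabet, "RNA")
})

test_that("reverse complement is an involution on random 20-mers", {
  withr::with_seed(7, {
    for (i in 1:200) {
      o <- random_oligo(20)
      expect_identical(reverse_complement(reverse_complement(o))$bases,
                       o$bases)
    }
    # and for RNA
    r <- random_oligo(20, c("a", "c", "g", "u"))
    expect_identical(reverse_complement(reverse_complement(r))$bases,
                     r$bases)
  })
})

test_that("amplicon lengths follow the primer coordinate arithmetic", {
  expect_equal(amplicon_length(panel$USP2, panel$hdac5AS2), 580)
  # degenerate fully overlapping primer pair
  f <- oligo_seq("f", "acgtacgtacgtacgtacgt", "sense", c(101, 120))
  r <- oligo_seq("r", "acgtacgtacgtacgtacgt", "antisense", c(101, 120))
  expect_equal(amplicon_length(f, r), 20)
  # USP1 carries a printed 10-position span for a 20-mer: the computed
  # amplicon is 218 bp, not the printed 212 -- the mismatch is flagged,
  # not silently corrected
  expect_true(panel$USP1$span_mismatch)
  expect_equal(amplicon_length(panel$USP1, panel$miD2861), 218)
  expect_false(amplicon_length(panel$USP1, panel$miD2861) == 212)

  other <- oligo_seq("o", "acgt", "antisense", c(500, 503),
                     reference = "NM_000001")
  expect_error(amplicon_length(panel$USP1, other), "references")
  expect_error(amplicon_length(r, oligo_seq("up", "acgt", "antisense",
                                            c(1, 4))), "5'")
  expect_error(amplicon_length(panel$passenger, panel$miD2861),
               "coordinates")
})

test_that("duplex calls reproduce the gel-shift lane pattern", {
  # probe vs the four lanes: bound only to the target-site cDNA
  lanes <- list(passenger = FALSE, premiR2861 = FALSE,
                miD2861 = FALSE, hdac5 = TRUE)
  for (nm in names(lanes)) {
    d <- duplex_call(panel$miD2861, panel[[nm]])
    expect_identical(d$bound, lanes[[nm]])
  }
  expect_equal(duplex_call(panel$miD2861, panel$hdac5)$run, 20)

  # across the full printed panel, the only bound pairs are the two
  # designed antisense/target couples
  nms <- names(panel)
  bound_pairs <- character()
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (i < j && duplex_call(panel[[i]], panel[[j]])$bound) {
        bound_pairs <- c(bound_pairs, paste(nms[i], nms[j]))
      }
    }
  }
  expect_setequal(bound_pairs,
                  c("hdac5 miD2861", "premiR2861 mpremiR2861a"))
})

test_that("duplex run length equals the DP oracle and is symmetric", {
  nms <- names(panel)
  for (i in seq_along(nms)) {
    for (j in i:length(nms)) {
      a <- panel[[i]]
      b <- panel[[j]]
      d_ab <- duplex_call(a, b)
      d_ba <- duplex_call(b, a)
      expect_equal(d_ab$run, d_ba$run)
      expect_equal(d_ab$run, lcs_run_oracle(a$bases, b$bases),
                   info = paste(nms[i], nms[j]))
    }
  }
  withr::with_seed(31, {
    for (k in 1:50) {
      a <- random_oligo(sample(8:30, 1))
      b <- random_oligo(sample(8:30, 1))
      expect_equal(duplex_call(a, b)$run, lcs_run_oracle(a$bases, b$bases))
    }
  })
  # a non-self-complementary homopolymer never binds itself
  aa <- oligo_seq("polyA", strrep("a", 20))
  expect_false(duplex_call(aa, aa)$bound)
})

test_that("oligo FASTA round-trips metadata and matches the bundled fixture", {
  tf <- tempfile(fileext = ".fasta")
  write_oligo_fasta(panel, tf)
  back <- read_oligo_fasta(tf)
  expect_setequal(names(back), names(panel))
  for (nm in names(panel)) {
    expect_identical(back[[nm]]$bases, panel[[nm]]$bases)
    expect_identical(back[[nm]]$orientation, panel[[nm]]$orientation)
    expect_identical(back[[nm]]$target_span, panel[[nm]]$target_span)
  }
  fixture <- system.file("extdata", "hdac5_oligo_panel.fasta",
                         package = "mcemri")
  expect_true(nzchar(fixture))
  fromfile <- read_oligo_fasta(fixture)
  expect_identical(lapply(fromfile, `[[`, "bases"),
                   lapply(panel, `[[`, "bases"))
})
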