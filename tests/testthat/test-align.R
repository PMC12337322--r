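test_that("the seeded aligner agrees with a brute-force scan", {
  # small genome so the exhaustive oracle stays cheap
  ref <- generate_reference(1, 3000, 0.02, seed = 51)
  mm <- assign_states(ref, default_genome_fractions(), seed = 52)
  err <- chemistry_errors(p_seq_err = 0.005, dup_rate = 0,
                          side_product_rate = 0)
  sim <- simulate_reads(mm, 30, err, seed = 53)
  eq <- extract_quads(sim$r1, sim$r2)
  idx <- ref_index(ref)
  for (i in seq_len(nrow(eq$quads))) {
    got <- align_quad(eq$quads[i, ], idx)
    want <- brute_align(eq$quads[i, ], as.character(ref))
    expect_equal(got$aligned, want$aligned, info = eq$quads$name[i])
    if (got$aligned) {
      expect_equal(got$start, want$start, info = eq$quads$name[i])
      expect_equal(got$end, want$end, info = eq$quads$name[i])
    }
  }
})

test_that("zero-error quads align uniquely at their true coordinates", {
  mm <- tiny_methylome()
  sim <- simulate_reads(mm, 2000, zero_errors(), seed = 54)
  eq <- extract_quads(sim$r1, sim$r2)
  idx <- ref_index(mm)
  al <- align_quads(eq$quads, idx)
  expect_gte(mean(al$aligned), 0.99)
  tr <- sim$truth[match(al$name, sim$truth$name), ]
  ok <- al$aligned
  expect_true(all(al$contig[ok] == tr$contig[ok]))
  expect_true(all(al$start[ok] == tr$start[ok]))
  expect_true(all(al$end[ok] == tr$end[ok]))
})

test_that("a fragment present twice in the reference is a tie", {
  unit <- "ATTAGGATACGTAGGATTAATTGGTACATTAGATTAAGGTTAATTAAGGAATTAGGTTAATTCCGATTAGGA"
  dupref <- c(chr = paste0(unit, strrep("T", 40), unit))
  st <- cpg_sites(dupref)
  st$state <- rep("MM", nrow(st))
  mm <- duplex_methylome(dupref, st)
  # fragment entirely inside the first copy of the repeat
  frag <- data.frame(contig = "chr", start = 0L, end = 72L)
  cons <- build_construct(frag, mm, zero_errors())
  quad <- data.frame(name = "q1", a = cons$a, b = cons$b, c = cons$c,
                     d = cons$d, stringsAsFactors = FALSE)
  al <- align_quad(quad, ref_index(mm))
  expect_false(al$aligned)
})

test_that("deduplication keeps one named representative per interval", {
  al <- data.frame(
    name = c("r3", "r1", "r2", "r4"),
    contig = c("c", "c", "c", "c"),
    start = c(10L, 10L, 10L, 50L),
    end = c(110L, 110L, 110L, 150L),
    score = 0L, aligned = TRUE, stringsAsFactors = FALSE)
  dd <- deduplicate(al)
  expect_equal(nrow(dd), 2L)
  expect_setequal(dd$name, c("r1", "r4"))  # smallest name wins
  expect_identical(deduplicate(dd), dd)    # idempotent
  expect_equal(nrow(deduplicate(al[0, ])), 0L)
})

test_that("duplicate read pairs collapse to the unique true fragments", {
  mm <- tiny_methylome()
  err <- chemistry_errors(p_seq_err = 0, dup_rate = 0.1,
                          side_product_rate = 0)
  sim <- simulate_reads(mm, 1500, err, seed = 55)
  eq <- extract_quads(sim$r1, sim$r2)
  al <- align_quads(eq$quads, ref_index(mm))
  dd <- deduplicate(al)
  truth_unique <- unique(sim$truth[, c("contig", "start", "end")])
  expect_equal(nrow(dd), nrow(truth_unique))
})

test_that("calls are read at dyad offsets and non-C/T bases skip the site", {
  ref <- c(chr = "ATTAGGATTACGATTAGGATTAAGGATTAGGTTAGGATTAGAGGATTAGGATTAAT")
  st <- cpg_sites(ref)
  expect_equal(nrow(st), 1L)  # a single dyad in this contig
  dyad <- st$pos0
  st$state <- "HC"
  mm <- duplex_methylome(ref, st)
  frag <- data.frame(contig = "chr", start = 2L, end = 52L)
  cons <- build_construct(frag, mm, zero_errors())
  quads <- data.frame(name = "q", a = cons$a, b = cons$b, c = cons$c,
                      d = cons$d, stringsAsFactors = FALSE)
  al <- align_quads(quads, ref_index(mm, k = 12))
  calls <- call_quads(al, quads, ref_index(mm, k = 12))
  expect_equal(calls$pos0, dyad)
  expect_equal(calls[, c("a", "d", "b", "c")],
               as.data.frame(encode_calls("HC")),
               ignore_attr = TRUE)
  # corrupt the dyad base in insert a with a G: site must be skipped
  quads_bad <- quads
  quads_bad$a <- duplexCpG:::set_chars(quads$a, dyad - 2L + 1L, "G")
  calls_bad <- call_quads(al, quads_bad, ref_index(mm, k = 12))
  expect_equal(nrow(calls_bad), 0L)
  expect_equal(attr(calls_bad, "skipped"), 1L)
})

test_that("dyads truncated at the fragment edge are not called", {
  ref <- c(chr = "TTAGGATTAGCGTTAGGATTAGGATTAGGATTAGGTTAGGATTAGG")
  st <- cpg_sites(ref)  # dyad at pos0 = 10
  st$state <- "MM"
  mm <- duplex_methylome(ref, st)
  idx <- ref_index(mm, k = 12)
  sites <- duplexCpG:::prep_sites(mm)
  # fragment ends right on the dyad C: the G falls outside -> no call
  cons <- duplexCpG:::build_construct_impl(ref[["chr"]], 0L, 46L,
                                           sites[["chr"]], zero_errors())
  al <- data.frame(name = "q", contig = "chr", start = 0L, end = 46L,
                   score = 0L, aligned = TRUE, stringsAsFactors = FALSE)
  quads <- data.frame(name = "q", a = cons$a, b = cons$b, c = cons$c,
                      d = cons$d, stringsAsFactors = FALSE)
  expect_equal(nrow(call_quads(al, quads, idx)), 1L)
  al2 <- transform(al, end = 11L)
  quads2 <- quads
  quads2$a <- substr(quads$a, 1, 11)
  quads2$b <- substr(quads$b, 36, 46)
  quads2$c <- substr(quads$c, 1, 11)
  quads2$d <- substr(quads$d, 36, 46)
  expect_equal(nrow(call_quads(al2, quads2, idx)), 0L)
})

test_that("compiled site counts match a direct tally of truth quads", {
  mm <- tiny_methylome()
  sim <- simulate_reads(mm, 1200, zero_errors(), seed = 56)
  eq <- extract_quads(sim$r1, sim$r2)
  idx <- ref_index(mm)
  al <- deduplicate(align_quads(eq$quads, idx))
  sites <- compile_sites(call_quads(al, eq$quads, idx))
  expect_equal(sum(sites$implausible), 0L)
  expect_true(all(rowSums(sites[, CPG_STATES]) == sites$depth))
  # independent tally: decode the simulator's truth quads for the same
  # deduplicated fragments, restricted to dyads all four inserts cover
  tc <- sim$truth_calls[sim$truth_calls$name %in% al$name, ]
  tr <- sim$truth[match(tc$name, sim$truth$name), ]
  covered <- duplexCpG:::covered_by_quad(tc$pos0, tr$start, tr$end,
                                         read_len = 250L,
                                         adapters = hairpin_adapters())
  tc <- tc[covered, ]
  truth_states <- decode_state(tc$a, tc$d, tc$b, tc$c)
  want <- table(paste(tc$contig, tc$pos0), truth_states)
  for (s in CPG_STATES) {
    got <- setNames(sites[[s]], paste(sites$contig, sites$pos0))
    if (s %in% colnames(want)) {
      w <- want[, s]
      w <- w[w > 0]
      expect_equal(unname(got[names(w)]), unname(as.integer(w)), info = s)
    }
  }
})
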