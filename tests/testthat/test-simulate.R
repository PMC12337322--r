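test_that("fragment lengths and positions behave as specified", {
  mm <- tiny_methylome()
  fr <- fragmentize(mm, 1000, mean_len = 100, sd_len = 10, seed = 21)
  # CLT bound on the sample mean
  expect_lt(abs(mean(fr$end - fr$start) - 100), 2)
  expect_true(all(fr$end - fr$start >= 40))
  expect_true(all(fr$end - fr$start <= 200))
  expect_true(all(fr$start >= 0))
  w <- setNames(Biostrings::width(mm$reference), names(mm$reference))
  expect_true(all(fr$end <= w[fr$contig]))
  expect_identical(fragmentize(mm, 1000, 100, 10, seed = 21), fr)
})

test_that("short contigs are skipped and empty input yields no fragments", {
  ref <- c(big = strrep("ACGTATGTAT", 30), small = "ACGTA")
  st <- cpg_sites(ref)
  st$state <- rep("MM", nrow(st))
  mm <- duplex_methylome(ref, st)
  expect_warning(fr <- fragmentize(mm, 50, mean_len = 100, seed = 22),
                 "shorter than mean_len")
  expect_true(all(fr$contig == "big"))
  expect_equal(nrow(suppressWarnings(fragmentize(mm, 0, seed = 23))), 0L)
})

test_that("error-free constructs encode the true state at every dyad", {
  panel <- build_spikein_panel(seed = 24)
  frags <- data.frame(contig = paste0("spike_", CPG_STATES),
                      start = 0L, end = 150L)
  for (i in seq_len(nrow(frags))) {
    cons <- build_construct(frags[i, ], panel, zero_errors())
    s <- sub("^spike_", "", frags$contig[i])
    expected <- encode_calls(s)
    expect_equal(nrow(cons$truth), 4L)
    for (col in c("a", "d", "b", "c")) {
      expect_true(all(cons$truth[[col]] == expected[1, col]), info = s)
    }
    # inserts decode back: base at each dyad offset reflects the call
    off_p <- cons$truth$pos0 + 1L
    expect_identical(substring(cons$a, off_p, off_p),
                     ifelse(cons$truth$a == 1, "C", "T"))
  }
})

test_that("deamination failure limit retains every non-CpG cytosine", {
  panel <- build_spikein_panel(seed = 25)
  err <- chemistry_errors(p_fail_deam = 1, p_overdeam_m = 0,
                          p_overdeam_h = 0, p_copy_fail = 0,
                          p_copy_spurious = 0, p_seq_err = 0, dup_rate = 0,
                          side_product_rate = 0)
  frag <- data.frame(contig = "spike_CC", start = 0L, end = 150L)
  cons <- build_construct(frag, panel, err)
  plus <- substr(as.character(panel$reference)[["spike_CC"]], 1, 150)
  c_plus <- duplexCpG:::char_positions(plus, "C")
  # every original-strand C survives: non-CpG C by the failed deamination,
  # and the unmodified dyad C likewise (escaping deamination is what turns
  # a CC dyad into a false hmC-like original call)
  expect_identical(duplexCpG:::char_positions(cons$a, "C"), c_plus)
  expect_true(all(cons$truth$a == 1L))
  expect_true(all(cons$truth$d == 0L))
})

test_that("read layout places adapters at unique, parseable positions", {
  mm <- tiny_methylome()
  ad <- hairpin_adapters()
  sim <- simulate_reads(mm, 20, zero_errors(), ad, seed = 26)
  for (i in seq_along(sim$r1)) {
    hits <- gregexpr(ad$intact_rs, sim$r1[[i]], fixed = TRUE)[[1]]
    expect_equal(length(hits), 1L)
    hits2 <- gregexpr(ad$remnant_rs, sim$r2[[i]], fixed = TRUE)[[1]]
    expect_true(length(hits2) >= 1L)
  }
})

test_that("side products are emitted at the configured rate", {
  mm <- tiny_methylome()
  err <- chemistry_errors(p_seq_err = 0, dup_rate = 0,
                          side_product_rate = 0.2)
  sim <- simulate_reads(mm, 20000, err, seed = 27)
  frac <- mean(sim$truth$side_product)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 20000))
  # side products carry no truth calls
  expect_false(any(sim$truth_calls$name %in%
                     sim$truth$name[sim$truth$side_product]))
})

test_that("duplication appends re-observations; zero rate keeps names unique", {
  mm <- tiny_methylome()
  sim0 <- simulate_reads(mm, 500, zero_errors(), seed = 28)
  expect_false(any(duplicated(names(sim0$r1))))
  err <- chemistry_errors(p_seq_err = 0, dup_rate = 0.3,
                          side_product_rate = 0)
  sim <- simulate_reads(mm, 2000, err, seed = 29)
  dups <- grepl("_dup$", sim$truth$name)
  expect_gt(sum(dups), 0)
  # a duplicate replays its parent fragment exactly
  parent <- sub("_dup$", "", sim$truth$name[dups])
  pidx <- match(parent, sim$truth$name)
  expect_identical(sim$truth$start[dups], sim$truth$start[pidx])
  expect_identical(unname(sim$r1[sim$truth$name[dups]]),
                   unname(sim$r1[parent]))
})

test_that("single-error miscall rates match the analytic expectation", {
  # MM with only mC over-deamination: each strand's original or copy mC can
  # independently read as T, so MM leaks into MH/HM at ~2*eps*(1-eps) for
  # small eps; the exact rate comes from per-strand outcome enumeration
  eps <- 0.05
  err <- chemistry_errors(p_fail_deam = 0, p_overdeam_m = eps,
                          p_overdeam_h = 0, p_copy_fail = 0,
                          p_copy_spurious = 0, p_seq_err = 0, dup_rate = 0,
                          side_product_rate = 0)
  pq <- duplexCpG:::state_quad_probs("MM", err)  # brute-force enumeration
  quads <- all_call_quads()
  qstate <- ifelse(is.na(quads$state), "implausible", quads$state)
  names(qstate) <- paste0(quads$a, quads$d, quads$b, quads$c)
  p_expect <- sum(pq[names(qstate)[qstate %in% c("MH", "HM")]])
  expect_lt(abs(p_expect - 2 * eps * (1 - eps)) / (2 * eps * (1 - eps)),
            0.15)
  panel <- build_spikein_panel(seed = 30)
  sim <- simulate_reads(panel, 9000, err, seed = 31)
  tc <- sim$truth_calls[sim$truth_calls$state == "MM", ]
  called <- decode_state(tc$a, tc$d, tc$b, tc$c)
  n <- length(called)
  expect_gt(n, 2000)
  p_obs <- mean(called %in% c("MH", "HM"), na.rm = FALSE)
  expect_lt(abs(p_obs - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / n))
  # and the analytic quad distribution agrees with the sampler (4 s.d.
  # across the family of quads; rare quads are skipped where the normal
  # approximation to the binomial breaks down)
  qname <- paste0(tc$a, tc$d, tc$b, tc$c)
  for (q in names(pq)[pq > 5e-4]) {
    expect_lt(abs(mean(qname == q) - pq[[q]]),
              4 * sqrt(pq[[q]] * (1 - pq[[q]]) / n))
  }
})

test_that("simulated reads round-trip through FASTQ files", {
  mm <- tiny_methylome()
  sim <- simulate_reads(mm, 50, zero_errors(), seed = 32)
  pre <- tempfile()
  paths <- write_sim_reads(sim, pre)
  r1 <- duplexCpG:::read_fastq(paths[["r1"]])
  expect_identical(unname(r1), unname(sim$r1))
  expect_identical(names(r1), names(sim$r1))
  unlink(paths)
})
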