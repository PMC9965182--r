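rule_default <- amplification_rule()

test_that("a verbatim planted primer yields exactly one perfect site", {
  set.seed(301)
  primer <- "ACGGACAGACCACTTTGCGTGA"
  g <- genome_record("g", paste0(rand_seq(400), primer, rand_seq(400)))
  sites <- find_binding_sites(primer, g, rule_default)
  plus <- sites[sites$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 400)
  expect_equal(plus$mismatch_total, 0)
  expect_equal(plus$end - plus$start, nchar(primer))
})

test_that("the 3'-end mismatch rule rejects exactly the published criterion", {
  primer <- "ACGGACAGACCACTTTGCGTGA"
  plant_variant <- function(total, in_last3) {
    chars <- strsplit(primer, "")[[1]]
    n <- length(chars)
    pos3 <- (n - 2):n
    pos <- c(sample(pos3, in_last3),
             sample(setdiff(1:(n - 3), NULL), total - in_last3))
    chars[pos] <- vapply(chars[pos], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste(chars, collapse = "")
  }
  set.seed(302)
  # 5 total mismatches, 2 of them in the primer's last 3 bases: the site
  # is non-functional (both clauses hold) under a permissive scan cap
  v52 <- plant_variant(5, 2)
  g52 <- genome_record("g", paste0(rand_seq(200), v52, rand_seq(200)))
  loose <- amplification_rule(max_mismatch_per_primer = 8L)
  s52 <- find_binding_sites(primer, g52, loose)
  expect_equal(nrow(s52[s52$strand == "+", ]), 0)
  # 5 total but only 1 in the last 3: still functional
  v51 <- plant_variant(5, 1)
  g51 <- genome_record("g", paste0(rand_seq(200), v51, rand_seq(200)))
  s51 <- find_binding_sites(primer, g51, loose)
  expect_equal(nrow(s51[s51$strand == "+", ]), 1)
  expect_equal(s51$mismatch_total[s51$strand == "+"], 5)
  # 4 total with 2 in the last 3: functional (first clause fails)
  v42 <- plant_variant(4, 2)
  g42 <- genome_record("g", paste0(rand_seq(200), v42, rand_seq(200)))
  s42 <- find_binding_sites(primer, g42, loose)
  expect_equal(nrow(s42[s42$strand == "+", ]), 1)
  # default scan cap 4: the 5-mismatch site is outside the scan entirely
  expect_equal(nrow(find_binding_sites(primer, g51, rule_default)), 0)
})

test_that("site finder is exactly equivalent to the per-position oracle", {
  set.seed(303)
  n_cases <- 30
  for (i in seq_len(n_cases)) {
    primer <- rand_seq(sample(12:24, 1))
    glen <- sample(500:2000, 1)
    gseq <- rand_seq(glen)
    # plant variants with 0..6 mismatches on both strands so the rule
    # boundary is exercised
    for (k in sample(0:6, 3)) {
      chars <- strsplit(primer, "")[[1]]
      if (k > 0) {
        pos <- sample(length(chars), k)
        chars[pos] <- vapply(chars[pos], function(b)
          setdiff(c("A", "C", "G", "T"), b)[1], "")
      }
      variant <- paste(chars, collapse = "")
      if (runif(1) < 0.5) variant <- reverse_complement(variant)
      at <- sample(glen - nchar(variant), 1)
      substr(gseq, at, at + nchar(variant) - 1) <- variant
    }
    rule <- amplification_rule(max_mismatch_per_primer = sample(2:6, 1))
    got <- find_binding_sites(primer, genome_record("g", gseq), rule)
    want <- oracle_binding_sites(primer, gseq, rule)
    expect_equal(nrow(got), nrow(want), label = sprintf("case %d nrow", i))
    if (nrow(want)) {
      got <- got[order(got$start, got$strand), ]
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatch_total, want$mismatch_total)
      expect_equal(got$mismatch_3p_last3, want$mismatch_3p_last3)
    }
  }
})

test_that("IUPAC codes in the template are honored by the scan", {
  primer <- "ACGGACAGACCACTTTGCGTGA"
  # template with R at a primer A position: R = A/G matches A
  tmpl <- primer
  substr(tmpl, 1, 1) <- "R"
  g <- genome_record("g", paste0(rand_seq(100, seed = 304), tmpl, rand_seq(100)))
  s <- find_binding_sites(primer, g, rule_default)
  expect_equal(nrow(s[s$strand == "+", ]), 1)
  expect_equal(s$mismatch_total[s$strand == "+"], 0)
})

test_that("amplicon enumeration does convergent-pair arithmetic", {
  mk <- function(start, end, strand, id = "g") {
    data.frame(genome_id = id, start = start, end = end, strand = strand,
               mismatch_total = 0L, mismatch_3p_last3 = 0L,
               stringsAsFactors = FALSE)
  }
  # one + site at 100 (len 20), one - site ending at 300: product 200
  amps <- enumerate_amplicons(mk(100, 120, "+"), mk(280, 300, "-"))
  expect_equal(nrow(amps), 1)
  expect_equal(amps$length, 200)
  expect_equal(c(amps$start, amps$end), c(100, 300))
  # divergent orientation only: nothing
  expect_equal(nrow(enumerate_amplicons(mk(280, 300, "+"), mk(100, 120, "-"))), 0)
  # 3 + sites x 2 - sites, all convergent and within the cap: 6 products
  plus <- do.call(rbind, lapply(c(0, 50, 100), function(s) mk(s, s + 20, "+")))
  minus <- do.call(rbind, lapply(c(500, 700), function(s) mk(s, s + 20, "-")))
  expect_equal(nrow(enumerate_amplicons(plus, minus)), 6)
  # the product cap truncates long products
  tight <- amplification_rule(max_product = 300L)
  expect_equal(nrow(enumerate_amplicons(plus, minus, tight)), 0)
  # overlapping footprints do not amplify
  expect_equal(nrow(enumerate_amplicons(mk(100, 120, "+"), mk(110, 130, "-"))), 0)
})

test_that("amplicon counts are invariant under genome reverse complement", {
  set.seed(305)
  for (i in 1:5) {
    fwd <- rand_seq(20); rev <- rand_seq(20)
    g <- paste0(rand_seq(300), fwd, rand_seq(150), reverse_complement(rev),
                rand_seq(300))
    n_fwd <- nrow(pcr_amplicons(fwd, rev, genome_record("g", g)))
    # on the reverse-complemented genome the primer roles swap
    n_rc <- nrow(pcr_amplicons(fwd, rev,
                               genome_record("g", reverse_complement(g))))
    expect_equal(n_rc, n_fwd)
  }
})

test_that("tightening the mismatch cap never adds binding sites", {
  set.seed(306)
  primer <- rand_seq(20)
  gseq <- rand_seq(3000)
  for (k in sample(0:5, 4)) {
    chars <- strsplit(primer, "")[[1]]
    if (k > 0) {
      pos <- sample(20, k)
      chars[pos] <- vapply(chars[pos], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], "")
    }
    at <- sample(2950, 1)
    substr(gseq, at, at + 19) <- paste(chars, collapse = "")
  }
  g <- genome_record("g", gseq)
  counts <- vapply(0:6, function(mm) {
    nrow(find_binding_sites(primer, g, amplification_rule(mm)))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("specificity report separates reference and non-target counts", {
  set.seed(307)
  fwd <- "ACGGACAGACCACTTTGCGTGA"
  rev <- "TTGCTTACCAGGTGCCGCGTAT"
  target <- paste0(fwd, rand_seq(120), reverse_complement(rev))
  ref <- genome_record("ref", paste0(rand_seq(500), target, rand_seq(500)))
  clean_q <- genome_record("q1", rand_seq(1200))
  dirty_q <- genome_record("q2", paste0(rand_seq(300), target, rand_seq(300)))
  rep1 <- specificity_report(fwd, rev, ref, list(q1 = clean_q))
  expect_equal(rep1$reference_amplicons, 1)
  expect_equal(rep1$total_nontarget, 0)
  rep2 <- specificity_report(fwd, rev, ref, list(q1 = clean_q, q2 = dirty_q))
  expect_gte(rep2$nontarget_counts[["q2"]], 1)
  expect_equal(rep2$total_nontarget, sum(rep2$nontarget_counts))
  # a query copy with 6 fwd mismatches, 2 in its 3' last-3, is not counted
  fwd_dead <- strsplit(fwd, "")[[1]]
  fwd_dead[c(2, 5, 8, 11, 21, 22)] <- vapply(
    fwd_dead[c(2, 5, 8, 11, 21, 22)],
    function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  # low-complexity AT filler keeps shifted spurious sites far above the
  # loosened scan cap, so only the planted (rejected) site could count
  dead_target <- paste0(paste(fwd_dead, collapse = ""), strrep("AT", 60),
                        reverse_complement(rev))
  dead_q <- genome_record("q3", paste0(strrep("TA", 150), dead_target,
                                       strrep("AT", 150)))
  rep3 <- specificity_report(fwd, rev, ref, list(q3 = dead_q),
                             rule = amplification_rule(max_mismatch_per_primer = 8L))
  expect_equal(rep3$nontarget_counts[["q3"]], 0)
})

test_that("RISA profiles report deduplicated sorted spacer products", {
  fwd <- "TTGTACACACCGCCCGTC"
  rev <- "CCTTCATCGCCTCTGACTGC"
  toy <- make_rrn_toy(2, c(350L, 520L), fwd, rev, seed = 308L)
  prof <- risa_profile(toy, fwd, rev)
  expect_equal(prof, c(nchar(fwd) + 350 + nchar(rev),
                       nchar(fwd) + 520 + nchar(rev)))
  expect_equal(diff(prof), 170)
  # no operons: empty profile
  empty <- make_rrn_toy(0, integer(0), fwd, rev, seed = 309L)
  expect_length(risa_profile(empty, fwd, rev), 0)
  # duplicate spacers collapse to one band
  dup <- make_rrn_toy(2, c(400L, 400L), fwd, rev, seed = 310L)
  expect_length(risa_profile(dup, fwd, rev), 1)
})
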