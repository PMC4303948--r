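# PWM construction, scanning and site filtering

test_that("count matrices convert to log-odds with the pseudocount rule", {
  # uniform matrix, uniform background: all weights zero
  p0 <- pwm(matrix(0.25, 2, 4), "u", pseudocount = 0)
  expect_equal(unname(p0$matrix), matrix(0, 2, 4))
  # counts (8,0,0,0) with pseudocount 1: A weight log((9/12)/0.25)
  p <- test_pwm()
  expect_equal(unname(p$matrix[1, "A"]), log((9 / 12) / 0.25))
  expect_equal(p$length, 3L)
  expect_equal(p$consensus, "ACG")
  # invariants: background sums to 1, consensus attains the max score
  expect_equal(sum(p$background), 1)
  expect_equal(llr_score(p, p$consensus), p$max_score)
})

test_that("malformed PWM input is rejected", {
  expect_error(pwm(matrix(1, 2, 3), "bad"), "4 columns")
  expect_error(pwm(matrix(-1, 2, 4), "bad"), "non-negative")
  expect_error(pwm(matrix(numeric(0), 0, 4), "bad"), "zero-length")
  f <- withr::local_tempfile(lines = c(">tf", "1 2 3"))
  expect_error(read_pwm(f), "malformed")
})

test_that("PWM files round-trip through read/write", {
  f <- withr::local_tempfile(lines = c(">Bcd", "8 0 0 0", "0 8 0 0",
                                       "0 0 8 0"))
  p <- read_pwm(f)
  expect_equal(p$tf_name, "Bcd")
  expect_equal(p$length, 3L)
  expect_equal(unname(p$matrix[1, "A"]), log((9 / 12) / 0.25))
  f2 <- withr::local_tempfile()
  write_pwm(p, f2)
  p2 <- read_pwm(f2, pseudocount = 0)
  expect_equal(p2$matrix, p$matrix, tolerance = 1e-8)
})

test_that("llr_score equals explicit per-position summation", {
  set.seed(7)
  counts <- matrix(stats::runif(4 * 6, 0, 20), 6, 4)
  p <- pwm(counts, "rand")
  for (i in 1:100) {
    word <- random_dna(6)
    chars <- strsplit(word, "")[[1]]
    manual <- sum(vapply(seq_len(6), function(k) {
      p$matrix[k, chars[k]]
    }, numeric(1)))
    expect_equal(llr_score(p, word), manual)
  }
  # all-zero matrix scores 0 for any word
  pz <- pwm(matrix(1, 4, 4), "flat", pseudocount = 0)
  expect_equal(llr_score(pz, "ACGT"), 0)
  # ambiguous base: NA with warning
  expect_warning(s <- llr_score(p, "ACGNTT"), "ambiguous")
  expect_true(is.na(s))
  expect_error(llr_score(p, "ACG"), "length")
})

test_that("scanning finds a planted consensus on the right strand", {
  p <- test_pwm()
  seq <- paste0(random_dna(100, seed = 5), "ACG", random_dna(100))
  hits <- scan_sequence(p, seq, threshold = p$max_score)
  planted <- hits[hits$start == 100, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$end, 103)
  expect_equal(planted$strand, "+")
  expect_equal(planted$word, "ACG")
  expect_equal(planted$llr, p$max_score)
  # threshold above the max: empty result
  expect_equal(nrow(scan_sequence(p, seq, threshold = p$max_score + 1)), 0L)
  # results sorted by start
  all_hits <- scan_sequence(p, seq, threshold = 0)
  expect_true(!is.unsorted(all_hits$start))
})

test_that("scanning is strand-symmetric", {
  p <- test_pwm()
  seq <- random_dna(300, seed = 11)
  n <- nchar(seq)
  fwd <- scan_sequence(p, seq, threshold = 1)
  rev <- scan_sequence(p, gapcircuit:::reverse_complement(seq), threshold = 1)
  # mirror the reverse-complement hits back onto forward coordinates
  mirrored <- data.frame(start = n - rev$end,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         llr = rev$llr)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(mirrored$start, fwd$start)
  expect_equal(mirrored$strand, fwd$strand)
  expect_equal(mirrored$llr, fwd$llr)
})

test_that("a palindromic consensus is reported once per strand", {
  # consensus ACGT is its own reverse complement
  p <- pwm(matrix(c(8, 0, 0, 0,
                    0, 8, 0, 0,
                    0, 0, 8, 0,
                    0, 0, 0, 8), ncol = 4, byrow = TRUE), "pal")
  seq <- paste0(strrep("C", 50), "ACGT", strrep("C", 50))
  hits <- scan_sequence(p, seq, threshold = p$max_score)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(50, 50))
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("accessibility filtering keeps >=1 bp overlaps (half-open)", {
  sites <- data.frame(tf = "t", start = 10, end = 20, strand = "+",
                      word = "w", llr = 1)
  kept <- filter_sites_by_accessibility(sites,
                                        data.frame(start = 19, end = 30))
  expect_equal(nrow(kept), 1L)
  dropped <- filter_sites_by_accessibility(sites,
                                           data.frame(start = 20, end = 30))
  expect_equal(nrow(dropped), 0L)
})

test_that("interval filters agree with the all-pairs overlap oracle", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    start <- sample(0:500, n)
    sites <- data.frame(tf = "t", start = start,
                        end = start + sample(5:15, n, TRUE), strand = "+",
                        word = "w", llr = 0)
    m <- sample(1:5, 1)
    is <- sample(0:500, m)
    ints <- data.frame(start = is, end = is + sample(10:80, m, TRUE))
    kept <- filter_sites_by_accessibility(sites, ints)
    naive <- sites[vapply(seq_len(n), function(i) {
      any(sites$start[i] < ints$end & sites$end[i] > ints$start)
    }, logical(1)), , drop = FALSE]
    expect_equal(kept$start, naive$start)
    # idempotence
    expect_equal(filter_sites_by_accessibility(kept, ints)$start, kept$start)
  }
})

test_that("CRE restriction subsets sites and validates the name", {
  p <- test_pwm()
  seq <- random_dna(200, seed = 3)
  region <- regulatory_region("g", seq,
                              cres = list(all = c(0, 200),
                                          mid = c(80, 120),
                                          empty_cre = c(198, 200)))
  region <- predict_sites(region, list(p))
  region$sites <- scan_sequence(p, seq, threshold = 1)
  all_sites <- restrict_sites_to_cre(region, "all")
  expect_equal(nrow(all_sites), nrow(region$sites))
  mid <- restrict_sites_to_cre(region, "mid")
  naive <- region$sites[region$sites$start < 120 & region$sites$end > 80, ]
  expect_equal(mid$start, naive$start)
  expect_error(restrict_sites_to_cre(region, "nope"), "unknown CRE")
})

test_that("FASTA and BED round-trip through the readers", {
  seqs <- c(g1 = random_dna(120, seed = 21), g2 = random_dna(80))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  expect_equal(read_fasta(fa), seqs)

  sites <- data.frame(tf = c("a", "b"), start = c(5L, 40L), end = c(15L, 50L),
                      strand = c("+", "-"), word = "w", llr = c(2.5, -1.25))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, bed, chrom = "g1")
  back <- read_bed(bed)
  expect_equal(back$start, sites$start)
  expect_equal(back$end, sites$end)
  expect_equal(back$name, sites$tf)
  expect_equal(back$score, sites$llr)
  expect_equal(back$strand, sites$strand)
})

test_that("regions validate sites and report TSS-relative coordinates", {
  expect_error(
    regulatory_region("g", "ACGT",
                      sites = data.frame(tf = "t", start = 2, end = 9,
                                         strand = "+", word = "w", llr = 0)),
    "outside")
  region <- regulatory_region("g", random_dna(100, seed = 2),
                              tss_offset = 60L,
                              sites = data.frame(tf = "t", start = 10,
                                                 end = 20, strand = "+",
                                                 word = "w", llr = 0))
  rel <- sites_relative_to_tss(region)
  expect_equal(rel$tss_start, -50)
  expect_equal(rel$tss_end, -40)
})
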