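test_that("a planted consensus site is recovered at its exact coordinate and strand", {
  pwm <- rand_high_ic_pwm(12, seed = 3)
  cons <- pwm_consensus(pwm)
  left <- rand_dna(40, seed = 101)
  right <- rand_dna(48, seed = 102)
  g <- make_genome(c(chrA = paste0(left, cons, right)))
  regions <- GRanges("chrA", IRanges(1, 100))

  hits <- scan_regions(g, regions, pwm, p = 1e-4)
  expect_equal(length(hits), 1L)
  expect_equal(start(hits), 41L)
  expect_equal(as.character(strand(hits)), "+")
  expect_equal(mcols(hits)$matched_seq, cons)
  expect_equal(mcols(hits)$anchor, 41L + 6L)

  # plant on the minus strand instead
  g2 <- make_genome(c(chrA = paste0(left, rc_string(cons), right)))
  hits2 <- scan_regions(g2, regions, pwm, p = 1e-4)
  expect_equal(length(hits2), 1L)
  expect_equal(as.character(strand(hits2)), "-")
  expect_equal(mcols(hits2)$matched_seq, cons)
})

test_that("palindromic sites hit both strands before resolution, plus strand after", {
  pal <- "ACGCGT"
  expect_equal(rc_string(pal), pal)
  counts <- sapply(strsplit(pal, "")[[1]], function(b) {
    v <- setNames(rep(1, 4), BASES); v[b] <- 50; v
  })
  pwm <- new_pwm(counts, "pal")
  g <- make_genome(c(chrA = paste0(rand_dna(30, seed = 8), pal,
                                   rand_dna(30, seed = 9))))
  regions <- GRanges("chrA", IRanges(1, 66))
  raw <- scan_regions(g, regions, pwm, p = 1e-3, resolve_overlaps = FALSE)
  expect_equal(length(raw), 2L)
  expect_setequal(as.character(strand(raw)), c("-", "+"))
  expect_equal(unique(start(raw)), 31L)

  res <- scan_regions(g, regions, pwm, p = 1e-3)
  expect_equal(length(res), 1L)
  expect_equal(as.character(strand(res)), "+")
})

test_that("background hit counts follow the binomial expectation", {
  pwm <- rand_soft_pwm(8, seed = 14)
  p <- 1e-3
  tail_exact <- score_pvalue(pwm, score_threshold(pwm, p))
  expect_lte(tail_exact, p)
  expect_gte(tail_exact, p / 4)
  g <- make_genome(c(chrA = rand_dna(10000, seed = 55)))
  regions <- GRanges("chrA", IRanges(1, 10000))
  hits <- scan_regions(g, regions, pwm, p, resolve_overlaps = FALSE)
  expected <- 2 * (10000 - 7) * tail_exact
  expect_lt(abs(length(hits) - expected), 3 * sqrt(expected) + 1e-9)
})

test_that("scanning agrees exactly with a naive per-window rescoring oracle", {
  pwm <- rand_soft_pwm(7, seed = 31)
  L <- 7
  p <- 5e-3
  t <- score_threshold(pwm, p)
  seqs <- vapply(1:50, function(i) rand_dna(100, seed = 200 + i),
                 character(1))
  g <- make_genome(setNames(seqs, paste0("chr", 1:50)))
  regions <- GRanges(paste0("chr", 1:50), IRanges(1, 100))
  hits <- scan_regions(g, regions, pwm, p, resolve_overlaps = FALSE)

  oracle <- list()
  for (i in 1:50) {
    txt <- seqs[i]
    for (s in 1:(100 - L + 1)) {
      win <- substr(txt, s, s + L - 1)
      for (str in c("+", "-")) {
        mseq <- if (str == "+") win else rc_string(win)
        sc <- log_odds_score(pwm, mseq)
        if (sc >= t - 1e-9) {
          oracle[[length(oracle) + 1]] <-
            data.frame(chrom = paste0("chr", i), start = s, strand = str,
                       score = sc)
        }
      }
    }
  }
  odf <- do.call(rbind, oracle)
  odf <- odf[order(odf$chrom, odf$start, odf$strand), ]
  hdf <- data.frame(chrom = as.character(seqnames(hits)),
                    start = start(hits),
                    strand = as.character(strand(hits)),
                    score = mcols(hits)$score)
  hdf <- hdf[order(hdf$chrom, hdf$start, hdf$strand), ]
  rownames(odf) <- rownames(hdf) <- NULL
  expect_equal(hdf, odf, tolerance = 1e-9)
})

test_that("scanning the reverse-complemented genome mirrors hits with flipped strands", {
  pwm <- rand_soft_pwm(6, seed = 77)
  len <- 2000
  fwd_txt <- rand_dna(len, seed = 78)
  g <- make_genome(c(chrA = fwd_txt))
  g_rc <- make_genome(c(chrA = rc_string(fwd_txt)))
  regions <- GRanges("chrA", IRanges(1, len))
  h1 <- scan_regions(g, regions, pwm, 1e-2, resolve_overlaps = FALSE)
  h2 <- scan_regions(g_rc, regions, pwm, 1e-2, resolve_overlaps = FALSE)
  expect_equal(length(h1), length(h2))
  key <- function(h, mirror = FALSE) {
    st <- if (mirror) len + 1L - end(h) else start(h)
    sr <- as.character(strand(h))
    if (mirror) sr <- ifelse(sr == "+", "-", "+")
    sort(paste(st, sr, mcols(h)$matched_seq))
  }
  expect_equal(key(h1), key(h2, mirror = TRUE))
})

test_that("windows containing N are skipped", {
  pwm <- rand_high_ic_pwm(8, seed = 12)
  cons <- pwm_consensus(pwm)
  g <- make_genome(c(chrA = paste0("NNNNN", cons, "NNNNN")))
  regions <- GRanges("chrA", IRanges(1, 18))
  hits <- scan_regions(g, regions, pwm, 1e-3)
  expect_equal(length(hits), 1L)
  expect_equal(start(hits), 6L)
})

test_that("consensus scanning finds palindromic matches on both strands and respects anti positions", {
  planted <- "AGAACATTTTGTTCT"
  g <- make_genome(c(chrA = paste0(rand_dna(25, seed = 61), planted,
                                   rand_dna(25, seed = 62))))
  regions <- GRanges("chrA", IRanges(1, 65))
  all8 <- consensus_pattern("nGnACAnnnTGTnCn")
  hits <- scan_regions_consensus(g, regions, all8)
  # the site satisfies the self-complementary constrained core on both strands
  expect_equal(length(hits), 2L)
  expect_equal(unique(start(hits)), 26L)
  expect_setequal(as.character(strand(hits)), c("+", "-"))
  expect_true(all(is.na(mcols(hits)$score)))

  anti5 <- consensus_pattern("nGnACAnnnTGTnCn",
                             constrained = setdiff(all8$constrained, 5),
                             anti_positions = 5)
  expect_equal(length(scan_regions_consensus(g, regions, anti5)), 0L)

  expect_equal(length(scan_regions_consensus(g, GRanges(), all8)), 0L)
})

test_that("consensus hit sets are nested as constraints are added, matching enumeration", {
  g <- make_genome(c(chrA = rand_dna(20000, seed = 91)))
  regions <- GRanges("chrA", IRanges(1, 20000))
  all_pos <- consensus_pattern("nGnACAnnnTGTnCn")$constrained
  prev <- NULL
  txt <- as.character(g[[1]])
  for (k in 5:8) {
    sub <- all_pos[seq_len(k)]
    pat <- consensus_pattern("nGnACAnnnTGTnCn", constrained = sub)
    hits <- scan_regions_consensus(g, regions, pat)
    key <- paste(start(hits), strand(hits))
    # brute-force enumeration over all windows and strands
    cnt <- 0L
    for (s in 1:(20000 - 14)) {
      win <- substr(txt, s, s + 14)
      if (match_consensus(pat, win)) cnt <- cnt + 1L
      if (match_consensus(pat, rc_string(win))) cnt <- cnt + 1L
    }
    expect_equal(length(hits), cnt)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("region classification partitions by motif content", {
  regions <- GRanges("chrA", IRanges(c(1, 101, 201, 301), width = 50))
  hitsA <- manual_hits("chrA", c(10, 210), 5, c("+", "+"),
                       region_ids = c(1L, 3L))
  hitsB <- manual_hits("chrA", c(110, 220), 5, c("-", "+"),
                       region_ids = c(2L, 3L))
  cl <- classify_regions_by_motifs(regions, hitsA, hitsB)
  expect_equal(cl$counts,
               c(A_only = 1L, B_only = 1L, both = 1L, neither = 1L))
  expect_equal(sum(cl$counts), length(regions))

  empty <- hitsB[0]
  cl2 <- classify_regions_by_motifs(regions, hitsA, empty)
  expect_equal(unname(cl2$counts[c("B_only", "both")]), c(0L, 0L))

  bad <- manual_hits("chrA", 10, 5, "+", region_ids = 9L)
  expect_error(classify_regions_by_motifs(regions, hitsA, bad), "outside")
})

test_that("planted region memberships are classified according to the planting plan", {
  pwmA <- rand_high_ic_pwm(9, seed = 41, id = "A")
  pwmB <- rand_high_ic_pwm(9, seed = 43, id = "B")
  consA <- pwm_consensus(pwmA)
  consB <- pwm_consensus(pwmB)
  plan <- withr::with_seed(50, sample(c("A", "B", "both", "none"), 100,
                                      replace = TRUE))
  seqs <- vapply(seq_along(plan), function(i) {
    base <- rand_dna(80, seed = 1000 + i)
    ins <- switch(plan[i],
                  A = consA, B = consB,
                  both = paste0(consA, rand_dna(10, seed = 2000 + i), consB),
                  none = "")
    paste0(substr(base, 1, 30), ins, substr(base, 31, 80))
  }, character(1))
  g <- make_genome(setNames(seqs, paste0("r", seq_along(plan))))
  regions <- GRanges(paste0("r", seq_along(plan)),
                     IRanges(1, nchar(seqs)))
  hitsA <- scan_regions(g, regions, pwmA, 1e-5)
  hitsB <- scan_regions(g, regions, pwmB, 1e-5)
  cl <- classify_regions_by_motifs(regions, hitsA, hitsB)
  truth <- c(A_only = sum(plan == "A"), B_only = sum(plan == "B"),
             both = sum(plan == "both"), neither = sum(plan == "none"))
  expect_equal(cl$counts, truth)
})

test_that("regions on unknown chromosomes are reported by name", {
  g <- make_genome(c(chrA = rand_dna(100, seed = 1)))
  regions <- GRanges("chrZ", IRanges(10, 50))
  pwm <- rand_soft_pwm(5, seed = 2)
  expect_error(scan_regions(g, regions, pwm, 1e-2), "chrZ")
})
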