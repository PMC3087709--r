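test_that("the strict consensus matches its worked example exactly once per strand", {
  hits <- scan_bipartite("GTCACGCCCTGGTAAC")
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$start, 1L)
  expect_equal(fwd$spacer, 6L)
  expect_equal(fwd$match, "GTCACGCCCTGGTAAC")
  # the box is strand-symmetric: one locus, mirrored on the minus strand
  expect_equal(nrow(unique(hits[, c("start", "end")])), 1L)
  expect_equal(nrow(scan_bipartite(strrep("T", 16))), 0L)
})

test_that("relaxed half-sites recover the glnA-style site that strict mode misses", {
  glnA_site <- "TTAACTTCGACGAAAC"
  expect_equal(nrow(scan_bipartite(glnA_site)), 0L)
  relaxed <- scan_bipartite(glnA_site, relaxed_consensus())
  expect_gte(nrow(relaxed), 1L)
  expect_true(any(relaxed$start == 1L & relaxed$strand == "+"))
})

test_that("non-IUPAC pattern characters are rejected", {
  expect_error(bipartite_consensus("GTXAC", "GTNAC"), "IUPAC")
})

test_that("ambiguity codes in the subject are never matched", {
  expect_equal(nrow(scan_bipartite("GTNACGCCCTGGTAAC")), 0L)
  # but a clean copy elsewhere in the same sequence still matches
  seq2 <- paste0("GTNACGCCCTGGTAAC", "GTCACGCCCTGGTAAC")
  hits <- scan_bipartite(seq2)
  expect_true(all(hits$start >= 17L))
  expect_gte(nrow(hits), 1L)
})

test_that("bipartite scanning equals the exhaustive offset/spacer/strand search", {
  set.seed(77)
  consensi <- list(bipartite_consensus(),
                   relaxed_consensus(),
                   bipartite_consensus("GTAAC", "GTAAC", 4L, 18L))
  for (i in 1:100) {
    L <- sample(2000:5000, 1)
    s <- random_dna_chr(L, gc = 0.7)
    # salt with boxes so hits are not vanishingly rare
    for (k in 1:3) {
      p <- sample.int(L - 20L, 1)
      box <- paste0("GT", sample(c("A", "C", "G", "T"), 1), "AC",
                    random_dna_chr(6), "GT", sample(c("A", "C", "G", "T"), 1),
                    "AC")
      substr(s, p, p + 15L) <- box
    }
    cons <- consensi[[(i %% length(consensi)) + 1L]]
    got <- scan_bipartite(s, cons)
    want <- oracle_bipartite(s, cons$a, cons$b, cons$spacer_min,
                             cons$spacer_max)
    expect_equal(got[, c("start", "end", "strand", "spacer")],
                 want, ignore_attr = TRUE)
  }
})

test_that("scanning is symmetric under reverse complement", {
  set.seed(9)
  for (i in 1:10) {
    s <- random_dna_chr(1500, gc = 0.7)
    # salt with a box so the comparison is never vacuous
    p <- sample.int(1400, 1)
    substr(s, p, p + 15L) <- paste0("GT", sample(c("A", "C", "G", "T"), 1),
                                    "AC", random_dna_chr(6), "GT",
                                    sample(c("A", "C", "G", "T"), 1), "AC")
    L <- nchar(s)
    fwd <- scan_bipartite(s)
    rev <- scan_bipartite(rc_chr(s))
    expect_gte(nrow(fwd), 1L)
    remapped <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L,
                           strand = as.character(ifelse(rev$strand == "+",
                                                        "-", "+")))
    o1 <- fwd[order(fwd$start, fwd$strand), c("start", "end", "strand")]
    o2 <- remapped[order(remapped$start, remapped$strand), ]
    expect_equal(o1, o2, ignore_attr = TRUE)
  }
})

test_that("tandem boxes yield multiple overlapping full-site hits", {
  # two tandem copies of the minimal site: a-n6-a-n6-a-n6-a
  half <- function() paste0("GT", sample(c("A", "C", "G", "T"), 1), "AC")
  set.seed(3)
  s <- paste0(half(), "ACGTAC"  # spacer deliberately not containing GTnAC
              , half(), "CCGGTT", half(), "AAGGCC", half())
  hits <- scan_bipartite(s)
  expect_gte(nrow(hits[hits$strand == "+", ]), 2L)
})

test_that("the widely spaced mode finds two a-sites 18 bp apart", {
  s <- paste0("GTAAC", random_dna_chr(18), "GTAAC")
  expect_equal(nrow(scan_bipartite(s)), 0L)  # default 6 bp spacer misses it
  wide <- scan_bipartite(s, bipartite_consensus("GTAAC", "GTAAC", 18L, 18L))
  expect_equal(nrow(wide[wide$strand == "+", ]), 1L)
  expect_equal(wide$spacer[1], 18L)
})

test_that("promoter windows are centred, fixed-width and clipped at ends", {
  genome <- DNAStringSet(c(chr = random_dna_chr(10000)))
  region <- GRanges("chr", IRanges(501, 501))
  w <- promoter_windows(region, genome, width = 250)
  expect_equal(unname(nchar(as.character(w))), 250L)
  expect_equal(mcols(w)$window_start, 376)
  expect_equal(mcols(w)$window_end, 625)
  # a midpoint near the origin clips the window
  edge <- GRanges("chr", IRanges(51, 51))
  expect_message(we <- promoter_windows(edge, genome, width = 250),
                 "clipped")
  expect_equal(mcols(we)$window_start, 1)
  expect_equal(mcols(we)$window_end, 175)
  expect_error(promoter_windows(GRanges("chrX", IRanges(1, 2)), genome),
               "no sequence")
})

test_that("PWM columns are proper distributions with bounded information", {
  pwm <- build_pwm(c("GTAAC", "GTAAC"))
  expect_equal(unname(colSums(pwm$prob)), rep(1, 5))
  expect_true(all(pwm$ic >= 0 & pwm$ic <= 2))
  # dominant base per column spells the site
  expect_equal(rownames(pwm$prob)[apply(pwm$prob, 2, which.max)],
               c("G", "T", "A", "A", "C"))
  # closed form for a unanimous column: (n + eps) / (n + 4 eps)
  expect_equal(unname(pwm$prob["G", 1]), (2 + 0.5) / (2 + 4 * 0.5))
  expect_equal(unname(pwm$prob["A", 1]), 0.5 / (2 + 4 * 0.5))
  expect_error(build_pwm(c("GTAAC", "GTAACA")), "same length")
  expect_error(build_pwm("GTAAC"), "at least 2")
})

test_that("half-site columns of the bound-site PWM are more informative than the spacer", {
  sites <- fixture_sites()
  expect_true(all(nchar(sites) == 16L))
  pwm <- build_pwm(sites)
  flank_ic <- mean(pwm$ic[c(1:5, 12:16)])
  spacer_ic <- mean(pwm$ic[6:11])
  expect_gt(flank_ic, spacer_ic)
})

test_that("PWM scanning scores are per-column log-odds sums, maximal on the consensus", {
  sites <- c("GTAACGGGGGGGTAAC", "GTCACGGGGGGGTCAC", "GTGACGGGGGGGTGAC")
  pwm <- build_pwm(sites)
  hits <- pwm_scan(sites[1], pwm, threshold = -Inf)
  best <- hits[hits$strand == "+", ][1, ]
  expect_equal(best$start, 1L)
  lo <- log2(sweep(pwm$prob, 1, pwm$background, "/"))
  chars <- strsplit(sites[1], "")[[1]]
  expect_equal(best$score,
               sum(vapply(seq_along(chars),
                          function(j) lo[chars[j], j], numeric(1))))
  # threshold -Inf returns every offset on both strands
  s <- random_dna_chr(100)
  all_hits <- pwm_scan(s, pwm, threshold = -Inf)
  expect_equal(nrow(all_hits), 2L * (100L - 16L + 1L))
})

test_that("region annotation reports sites or the n/a flag per window", {
  wins <- DNAStringSet(c(with_site = paste0(random_dna_chr(50),
                                            "GTCACGCCCTGGTAAC",
                                            random_dna_chr(50)),
                         without = strrep("T", 116)))
  ann <- annotate_regions_with_sites(wins)
  expect_equal(ann$n_with_sites, 1L)
  expect_equal(ann$n_without_sites, 1L)
  expect_equal(ann$table$sites[ann$table$region == "without"], "n/a")
  expect_match(ann$table$sites[ann$table$region == "with_site"],
               "GTCACGCCCTGGTAAC")
  empty <- annotate_regions_with_sites(DNAStringSet())
  expect_equal(nrow(empty$table), 0L)
})

test_that("full-site length decomposes into two half-sites and the spacer", {
  expect_equal(consensus_spacer(fixture_sites()), 6L)
  expect_error(consensus_spacer(c("GTAAC", "GTAACGTAAC")), "differing")
})
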