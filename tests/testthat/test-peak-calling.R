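test_that("track threshold is mean plus k_sd sample standard deviations", {
  expect_equal(track_threshold(make_track(c(1, 1, 1, 1))), 1.0)
  tr <- make_track(c(0.8, 1.0, 1.2))
  expect_equal(track_threshold(tr, peak_params(k_sd = 2.5)),
               1.0 + 2.5 * sd(c(0.8, 1.0, 1.2)))
  # linearity: doubling every ratio doubles the threshold
  tr2 <- make_track(2 * c(0.8, 1.0, 1.2))
  expect_equal(track_threshold(tr2), 2 * track_threshold(tr))
  expect_error(track_threshold(make_track(1.0)), "at least 2 probes")
})

test_that("flat tracks and isolated high probes yield no peaks", {
  expect_length(call_peaks_single(make_track(rep(1, 20))), 0L)
  # a single probe above threshold is not a peak: two consecutive required
  v <- c(rep(1, 10), 5, rep(1, 10))
  expect_length(call_peaks_single(make_track(v)), 0L)
  # two consecutive high probes are
  v2 <- c(rep(1, 10), 5, 5, rep(1, 10))
  pk <- call_peaks_single(make_track(v2))
  expect_length(pk, 1L)
  expect_equal(pk$n_probes, 2L)
  expect_equal(pk$max_ratio, 5)
})

test_that("peak intervals span first to last qualifying probe", {
  v <- c(rep(1, 5), 6, 7, 6, rep(1, 5))
  tr <- make_track(v)  # probes every 100 bp, width 60
  pk <- call_peaks_single(tr, threshold = 2)
  expect_equal(start(pk), start(tr)[6])
  expect_equal(end(pk), end(tr)[8])
})

test_that("coverage gaps larger than max_probe_gap_bp split runs", {
  starts <- c(1L, 101L, 201L, 1001L, 1101L)
  v <- c(1, 5, 5, 5, 5)
  tr <- make_track(v, start = starts)
  # default max gap = 2 x median spacing (100) = 200; the 740 bp gap splits
  pk <- call_peaks_single(tr, threshold = 2)
  expect_length(pk, 2L)
  pk2 <- call_peaks_single(tr, peak_params(max_probe_gap_bp = 1000),
                           threshold = 2)
  expect_length(pk2, 1L)
})

test_that("peak caller matches the brute-force run enumerator on random tracks", {
  set.seed(101)
  n_tracks <- 200L
  for (i in seq_len(n_tracks)) {
    n <- 500L
    v <- exp(rnorm(n, 0, 0.3))
    k <- sample(c(0.5, 1, 1.5, 2.5), 1L)
    min_run <- sample(1:3, 1L)
    tr <- make_track(v, start = cumsum(c(1L, sample(c(90L, 100L, 300L),
                                                    n - 1L, TRUE,
                                                    c(.45, .45, .1)))),
                     width = 60L)
    params <- peak_params(k_sd = k, min_run = min_run,
                          max_probe_gap_bp = 150L)
    pk <- call_peaks_single(tr, params)
    thr <- track_threshold(tr, params)
    orc <- oracle_peaks(tr$ratio, start(tr), end(tr), thr, min_run, 150L)
    expect_equal(start(pk), orc$start)
    expect_equal(end(pk), orc$end)
  }
})

test_that("raising k_sd never increases total peak coverage", {
  set.seed(7)
  tr <- make_track(exp(rnorm(800, 0, 0.4)))
  grid <- c(0.5, 1, 1.5, 2, 2.5, 3)
  res <- lapply(grid, function(k)
    call_peaks_single(tr, peak_params(k_sd = k)))
  lens <- vapply(res, function(p) sum(width(p)), numeric(1))
  expect_true(all(diff(lens) <= 0))
  # peaks at a stricter threshold always lie inside peaks at a looser one
  for (i in seq_along(grid)[-1])
    if (length(res[[i]]))
      expect_true(all(overlapsAny(res[[i]], res[[i - 1]], type = "within")))
})

test_that("replicate merging applies reproducibility and control subtraction", {
  pk <- function(s, e) GRanges("chr", IRanges(s, e),
                               max_ratio = 5, n_probes = 3L,
                               replicate_id = NA_character_,
                               timepoint = "T30")
  # identical peak in both replicates, empty control -> one region
  m <- merge_replicates(list(rep1 = pk(100, 400), rep2 = pk(150, 450)),
                        control_peaks = NULL,
                        peak_params(min_replicates = 2))
  expect_length(m$regions, 1L)
  expect_equal(m$regions$n_replicates, 2L)
  expect_equal(start(m$regions), 100L)
  expect_equal(end(m$regions), 450L)
  expect_setequal(unlist(m$regions$supporting_replicates), c("rep1", "rep2"))
  # peak in only one replicate -> nothing
  m1 <- merge_replicates(list(rep1 = pk(100, 400), rep2 = pk(5000, 5400)),
                         NULL, peak_params(min_replicates = 2))
  expect_length(m1$regions, 0L)
  # reproducible peak also present in control -> diagnostics, not reported
  m2 <- merge_replicates(list(rep1 = pk(100, 400), rep2 = pk(150, 450)),
                         control_peaks = pk(380, 600),
                         peak_params(min_replicates = 2))
  expect_length(m2$regions, 0L)
  expect_length(m2$diagnostics, 1L)
  expect_true(m2$diagnostics$present_in_control)
})

test_that("raising min_replicates never increases the number of regions", {
  set.seed(13)
  pk_random <- function() {
    s <- sort(sample.int(10000L, 5L)) * 10L
    GRanges("chr", IRanges(s, s + 300L), max_ratio = 4, n_probes = 2L,
            replicate_id = NA_character_, timepoint = "T30")
  }
  sets <- list(a = pk_random(), b = pk_random(), c = pk_random())
  counts <- vapply(1:3, function(mr)
    length(merge_replicates(sets, NULL,
                            peak_params(min_replicates = mr))$regions),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("regions in a divergent gap report both flanking genes", {
  genes <- toy_genes(c(100L, 600L), c(300L, 900L), c("-", "+"),
                     seqlen = 1200L)
  region <- GRanges("chr", IRanges(400, 500))
  out <- assign_targets(region, genes)
  expect_true(out$intergenic)
  expect_setequal(unlist(out$target_gene_ids), c("g01", "g02"))
})

test_that("a region inside a gene is flagged and still assigned by the rule", {
  genes <- toy_genes(c(100L, 600L), c(300L, 900L), c("+", "+"),
                     seqlen = 1200L)
  region <- GRanges("chr", IRanges(150, 250))  # inside g01
  out <- assign_targets(region, genes)
  expect_false(out$intergenic)
  expect_equal(unlist(out$target_gene_ids), "g02")
})

test_that("convergent-context regions may have no target (logged)", {
  genes <- toy_genes(c(100L, 600L), c(300L, 900L), c("+", "-"),
                     seqlen = 1200L)
  region <- GRanges("chr", IRanges(400, 500))
  expect_message(out <- assign_targets(region, genes), "no downstream")
  expect_length(unlist(out$target_gene_ids), 0L)
})

test_that("target assignment agrees with an exhaustive nearest-gene search", {
  for (seed in 1:5) {
    seqlen <- 20000L
    genes <- random_annotation(30L, seqlen, seed)
    set.seed(seed + 100)
    s <- sort(sample.int(seqlen - 400L, 20L))
    regions <- GRanges("chr", IRanges(s, s + 300L))
    out <- assign_targets(regions, genes)
    for (i in seq_along(regions)) {
      expected <- character(0)
      right <- which(start(genes) >= start(regions)[i])
      if (length(right)) {
        j <- right[which.min(start(genes)[right])]
        if (as.character(strand(genes))[j] == "+")
          expected <- c(expected, genes$gene_id[j])
      }
      left <- which(end(genes) <= end(regions)[i])
      if (length(left)) {
        j <- left[which.max(end(genes)[left])]
        if (as.character(strand(genes))[j] == "-")
          expected <- c(expected, genes$gene_id[j])
      }
      expect_setequal(unlist(out$target_gene_ids[[i]]), unique(expected))
    }
  }
})

test_that("binding-region counts are reported overall and per timepoint", {
  expect_equal(count_binding_regions(GRanges())$total, 0L)
  regions <- GRanges("chr", IRanges(c(1, 500), c(100, 700)))
  mcols(regions)$timepoints <- CharacterList(list(c("T30", "T45"), "T30"))
  cnt <- count_binding_regions(regions)
  expect_equal(cnt$total, 2L)
  expect_equal(cnt$by_timepoint[["T30"]], 2L)
  expect_equal(cnt$by_timepoint[["T45"]], 1L)
})
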