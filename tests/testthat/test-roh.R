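test_that("L parameter evaluates the Lencz/Purfield formula, rounded up", {
  # ln(0.25)/ln(0.5) = 2 exactly
  expect_identical(l_parameter(1, 1, mean_het = 0.5, alpha = 0.25), 2L)
  # ceil(ln(5e-9)/ln(0.7)) = ceil(53.59) = 54
  expect_identical(l_parameter(1e6, 10, mean_het = 0.30, alpha = 0.05), 54L)
  # doubling n_snps adds at most ceil(ln 2 / |ln(1-h)|) and at least 0
  L1 <- l_parameter(1e6, 10, 0.30)
  L2 <- l_parameter(2e6, 10, 0.30)
  expect_gte(L2, L1)
  expect_lte(L2 - L1, ceiling(log(2) / abs(log(0.7))))
  expect_error(l_parameter(1e6, 10, mean_het = 0), "mean_het")
  expect_error(l_parameter(1e6, 10, mean_het = 1), "mean_het")
})

test_that("length classes use half-open boundaries above the 100 kb floor", {
  expect_equal(classify_length(250e3), "short")
  expect_equal(classify_length(399999), "short")
  expect_equal(classify_length(400e3), "medium")
  expect_equal(classify_length(799999), "medium")
  expect_equal(classify_length(800e3), "long")
  expect_equal(classify_length(1e6), "long")
  expect_error(classify_length(99e3), "floor")
})

test_that("an all-heterozygous sample yields no ROH", {
  gt <- make_gt(matrix(1L, 300, 1), pos = seq(1, by = 5000, length.out = 300))
  seg <- detect_roh(gt, roh_params(window_snp = 63), "ind1")
  expect_equal(nrow(seg), 0)
})

test_that("a clean homozygous run is called as one segment spanning all SNPs", {
  pos <- seq(1, by = 10000, length.out = 200)
  gt <- make_gt(matrix(0L, 200, 1), pos = pos)
  seg <- detect_roh(gt, roh_params(window_snp = 63), "ind1")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, pos[1])
  expect_equal(seg$end_bp, pos[200])
  expect_equal(seg$length_bp, 1990001L)
  expect_equal(seg$n_snps, 200L)
  expect_equal(seg$size_class, "long")
  # matches the literal oracle
  orc <- oracle_roh_scaffold(pos, rep(0L, 200), roh_params(window_snp = 63))
  expect_equal(seg$start_bp, orc$start_bp)
  expect_equal(seg$end_bp, orc$end_bp)
})

test_that("an over-long gap splits a run into independently qualified segments", {
  pos <- c(seq(1, by = 10000, length.out = 100),
           seq(1 + 99 * 10000 + 600000, by = 10000, length.out = 100))
  gt <- make_gt(matrix(0L, 200, 1), pos = pos)
  seg <- detect_roh(gt, roh_params(window_snp = 63), "ind1")
  expect_equal(nrow(seg), 2)
  expect_equal(seg$end_bp[1], pos[100])
  expect_equal(seg$start_bp[2], pos[101])
  expect_true(all(seg$n_snps == 100L))
})

test_that("scaffolds with fewer SNPs than one window yield nothing", {
  gt <- make_gt(matrix(0L, 30, 1))
  expect_equal(nrow(detect_roh(gt, roh_params(window_snp = 63), "ind1")), 0)
})

test_that("detector equals the brute-force oracle on random instances", {
  set.seed(2024)
  for (r in 1:40) {
    n <- sample(80:600, 1)
    p_het <- runif(1, 0, 0.35)
    p_mis <- runif(1, 0, 0.1)
    g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                prob = c((1 - p_het - p_mis) * 0.7,
                         p_het, (1 - p_het - p_mis) * 0.3, p_mis))
    # insert a homozygous stretch in about half the instances
    if (r %% 2 == 0) {
      a <- sample(seq_len(max(1, n - 150)), 1)
      b <- min(n, a + sample(60:150, 1))
      g[a:b] <- sample(c(0L, 2L), b - a + 1, replace = TRUE)
    }
    pos <- sort(sample.int(5e6, n))
    prm <- roh_params(window_snp = sample(20:70, 1),
                      window_het = sample(0:5, 1),
                      window_missing = sample(0:5, 1),
                      min_kb = sample(c(50, 100), 1),
                      gap_kb = sample(c(100, 500), 1),
                      seg_het = sample(0:2, 1))
    gt <- make_gt(matrix(g, ncol = 1), pos = pos)
    mine <- detect_roh(gt, prm, "ind1")
    orc <- oracle_roh_scaffold(pos, g, prm)
    expect_equal(nrow(mine), nrow(orc), info = paste("instance", r))
    if (nrow(orc)) {
      expect_equal(mine$start_bp, orc$start_bp, info = paste("instance", r))
      expect_equal(mine$end_bp, orc$end_bp, info = paste("instance", r))
      expect_equal(mine$n_snps, orc$n_snps, info = paste("instance", r))
      expect_equal(mine$n_het, orc$n_het, info = paste("instance", r))
    }
  }
})

test_that("summaries report F_ROH, counts, and size classes", {
  expect_equal(summarize_roh(
    data.frame(sample = character(), scaffold = character(),
               start_bp = integer(), end_bp = integer(),
               length_bp = integer(), n_snps = integer(),
               n_het = integer(), size_class = character()),
    200e6)$f_roh, 0)

  seg <- data.frame(sample = "x", scaffold = "s1",
                    start_bp = 1L, end_bp = 20e6, length_bp = 20e6,
                    n_snps = 10000L, n_het = 0L, size_class = "long")
  s <- summarize_roh(seg, 200e6)
  expect_equal(s$f_roh, 0.10)
  expect_equal(s$n_roh, 1)
  expect_equal(s$sum_kb, 20000)

  overlapping <- rbind(seg, transform(seg, start_bp = 10e6, end_bp = 30e6))
  expect_error(summarize_roh(overlapping, 200e6), "overlapping")
})

test_that("published-style class counts give the expected percentages", {
  pct <- class_percentages(c(short = 25930L, medium = 587L, long = 13L))
  expect_equal(unname(pct), c(97.74, 2.21, 0.05))
})

test_that("ROH export writes hom and BED flavors", {
  seg <- data.frame(sample = "x", scaffold = "s1",
                    start_bp = 1001L, end_bp = 201000L, length_bp = 200000L,
                    n_snps = 150L, n_het = 1L, size_class = "short")
  hom <- tempfile(); bed <- tempfile()
  write_roh(seg, hom, "hom")
  write_roh(seg, bed, "bed")
  h <- read.table(hom, header = TRUE)
  expect_equal(h$POS1, 1001)
  b <- read.table(bed)
  expect_equal(b$V2, 1000)  # BED start is 0-based
  expect_equal(b$V3, 201000)
})
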