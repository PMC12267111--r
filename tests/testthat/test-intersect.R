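seg_fixture <- function() {
  data.frame(sample = "x", scaffold = c("s1", "s1"),
             start_bp = c(1000L, 50000L), end_bp = c(2000L, 60000L),
             length_bp = c(1001L, 10001L), n_snps = c(10L, 20L),
             n_het = 0L, size_class = "short")
}

test_that("interval membership is inclusive at both segment ends", {
  seg <- seg_fixture()
  v <- data.frame(scaffold = "s1",
                  pos = c(999L, 1000L, 1500L, 2000L, 2001L, 55000L))
  fl <- intersect_variants(seg, v)
  expect_equal(as.vector(fl), c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(attr(fl, "segment_index"),
               c(NA, 1L, 1L, 1L, NA, 2L))
})

test_that("variants on scaffolds without segments fall outside", {
  v <- data.frame(scaffold = c("s1", "s2"), pos = c(1500L, 1500L))
  fl <- intersect_variants(seg_fixture(), v)
  expect_equal(as.vector(fl), c(TRUE, FALSE))
})

test_that("overlapping or unsorted segments are rejected", {
  bad <- seg_fixture()
  bad$start_bp[2] <- 1500L
  v <- data.frame(scaffold = "s1", pos = 1L)
  expect_error(intersect_variants(bad, v), "unsorted or overlapping")
})

test_that("sweep equals the naive oracle on random instances", {
  set.seed(77)
  for (r in 1:20) {
    n_seg <- sample(1:50, 1)
    starts <- sort(sample.int(1e6, n_seg))
    ends <- starts + sample.int(5000, n_seg)
    keep <- logical(n_seg)
    last_end <- -1
    for (i in seq_len(n_seg)) {
      if (starts[i] > last_end) {
        keep[i] <- TRUE
        last_end <- ends[i]
      }
    }
    seg <- data.frame(sample = "x",
                      scaffold = sample(c("s1", "s2"), sum(keep),
                                        replace = TRUE),
                      start_bp = starts[keep], end_bp = ends[keep],
                      length_bp = ends[keep] - starts[keep] + 1L,
                      n_snps = 10L, n_het = 0L, size_class = "short")
    seg <- seg[order(seg$scaffold, seg$start_bp), ]
    v <- data.frame(scaffold = sample(c("s1", "s2"), 1000, replace = TRUE),
                    pos = sample.int(1.1e6, 1000))
    expect_equal(as.vector(intersect_variants(seg, v)),
                 oracle_intersect(seg, v), info = paste("instance", r))
  }
})

test_that("context summary stratifies counts and conserves totals", {
  seg <- seg_fixture()
  seg$size_class <- c("short", "medium")
  v <- data.frame(scaffold = "s1",
                  pos = c(1100L, 1200L, 1300L, 55000L, 70000L, 80000L))
  states <- factor(c("realized", "realized", "potential", "realized",
                     "potential", "absent"),
                   levels = c("absent", "potential", "realized"))
  impacts <- c("HIGH", "MODERATE", "HIGH", "LOW", "HIGH", "HIGH")
  fl <- intersect_variants(seg, v)
  cx <- summarize_context(fl, states, impacts, seg)
  expect_equal(cx$n_in_roh, 4)
  expect_equal(cx$n_out_roh, 1)        # the absent carrier does not count
  expect_equal(cx$variants_per_roh, 2.0)
  expect_equal(unname(cx$by_size_class), c(3L, 1L, 0L))
  expect_equal(sum(cx$counts$count), cx$n_in_roh + cx$n_out_roh)
})

test_that("twelve deleterious sites in four tracts average three per tract", {
  seg <- data.frame(sample = "x", scaffold = "s1",
                    start_bp = c(1e5, 3e5, 5e5, 7e5),
                    end_bp = c(2e5, 4e5, 6e5, 8e5),
                    length_bp = 100001, n_snps = 100L, n_het = 0L,
                    size_class = "short")
  v <- data.frame(scaffold = "s1",
                  pos = as.integer(c(seq(1.1e5, 1.9e5, length.out = 3),
                                     seq(3.1e5, 3.9e5, length.out = 3),
                                     seq(5.1e5, 5.9e5, length.out = 3),
                                     seq(7.1e5, 7.9e5, length.out = 3))))
  states <- factor(rep("realized", 12),
                   levels = c("absent", "potential", "realized"))
  cx <- summarize_context(intersect_variants(seg, v), states,
                          rep("MODERATE", 12), seg)
  expect_equal(cx$variants_per_roh, 3.0)
})

test_that("zero tracts give zero per-tract rate and all-outside flags", {
  empty_seg <- seg_fixture()[0, ]
  v <- data.frame(scaffold = "s1", pos = c(100L, 200L))
  fl <- intersect_variants(empty_seg, v)
  expect_false(any(fl))
  cx <- summarize_context(fl, factor(c("realized", "potential"),
                                     levels = c("absent", "potential",
                                                "realized")),
                          c("HIGH", "LOW"), empty_seg)
  expect_equal(cx$variants_per_roh, 0)
  expect_equal(cx$n_out_roh, 2)
})

test_that("BED conversion round-trips 1-based inclusive coordinates", {
  d <- data.frame(scaffold = "s1", start_bp = 101L, end_bp = 200L)
  expect_equal(to_bed(d)$start_bp, 100L)
  expect_identical(from_bed(to_bed(d)), d)
})

test_that("realized deleterious variants are enriched inside truth tracts", {
  # sign test across replicates: inbred genomes place realized load
  # disproportionately inside autozygous tracts
  wins <- 0L; informative <- 0L
  for (s in 1:8) {
    sim <- simulate_pedigree_genomes(
      sim_config(first_cousin_pedigree(), n_scaffolds = 6,
                 scaffold_length_bp = 40e6, seed = 500 + s))
    tr <- sim$truth[sim$truth$sample == "cousin_child", ]
    # replicates with <1% autozygosity carry too few sites to be informative
    if (sum(tr$end_bp - tr$start_bp + 1) <
        0.01 * sum(sim$scaffold_lengths)) next
    tr$length_bp <- tr$end_bp - tr$start_bp + 1
    seg <- data.frame(sample = "cousin_child", scaffold = tr$scaffold,
                      start_bp = tr$start_bp, end_bp = tr$end_bp,
                      length_bp = tr$length_bp, n_snps = 1L, n_het = 0L,
                      size_class = "short")
    seg <- seg[order(seg$scaffold, seg$start_bp), ]
    pol <- polarize(sim$variants, sim$outgroup)
    st <- classify_zygosity(sim$genotypes, pol, "cousin_child")
    fl <- intersect_variants(seg, pol)
    del <- pol$impact %in% deleterious_impacts()
    realized <- st == "realized" & del
    in_len <- sum(as.numeric(tr$length_bp))
    out_len <- sum(as.numeric(sim$scaffold_lengths)) - in_len
    rate_in <- sum(realized & fl) / in_len
    rate_out <- sum(realized & !fl) / out_len
    informative <- informative + 1L
    if (rate_in > rate_out) wins <- wins + 1L
  }
  expect_gte(informative, 3)
  expect_equal(wins, informative)
})
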