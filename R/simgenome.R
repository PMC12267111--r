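#' Simulation configuration
#'
#' Bundles every knob of the pedigree genome simulator. Defaults describe a
#' bear-like whole-genome cohort: 1 SNP per 1.5 kb, founder per-site
#' heterozygosity 0.3 at variable sites, recombination at 1 cM/Mb, and
#' SnpEff-style impact labels on a small fraction of sites.
#'
#' @param pedigree a [pedigree_spec()].
#' @param n_scaffolds number of autosomal scaffolds.
#' @param scaffold_length_bp length of each scaffold in bp (>= 1 Mb so that
#'   tracts above the 100 kb ROH detection floor exist).
#' @param snp_density expected SNPs per bp (default 1/1500).
#' @param founder_het probability that a founder is heterozygous at a
#'   variable site (0-0.5]; the derived-allele frequency p <= 0.5 solves
#'   2p(1-p) = founder_het.
#' @param recomb_rate crossovers per bp per meiosis (default 1e-8 = 1 cM/Mb).
#' @param impact_fractions named fractions for HIGH, MODERATE, LOW and NONE
#'   impact labels; must sum to 1.
#' @param genotype_error_rate probability a truly homozygous call is emitted
#'   heterozygous (and a het emitted homozygous).
#' @param missing_rate probability a call is emitted missing.
#' @param gq_mean,dp_mean means of the synthetic per-call GQ (normal, sd 10)
#'   and DP (Poisson) values.
#' @param seed integer seed; a single global generator drives every draw so
#'   equal seeds give byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(pedigree,
                       n_scaffolds = 20,
                       scaffold_length_bp = 100e6,
                       snp_density = 1 / 1500,
                       founder_het = 0.3,
                       recomb_rate = 1e-8,
                       impact_fractions = c(HIGH = 0.002, MODERATE = 0.010,
                                            LOW = 0.020, NONE = 0.968),
                       genotype_error_rate = 0,
                       missing_rate = 0,
                       gq_mean = 60, dp_mean = 30,
                       seed = 1L) {
  stopifnot(inherits(pedigree, "pedigree_spec"))
  if (abs(sum(impact_fractions) - 1) > 1e-12)
    stop("impact_fractions must sum to 1")
  if (!all(c("HIGH", "MODERATE", "LOW", "NONE") %in% names(impact_fractions)))
    stop("impact_fractions needs HIGH, MODERATE, LOW, NONE")
  rates <- c(snp_density, founder_het, genotype_error_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (founder_het > 0.5)
    stop("founder_het > 0.5 has no diallelic solution (max 2p(1-p) = 0.5)")
  if (scaffold_length_bp < 1e6)
    warning("scaffold_length_bp < 1 Mb leaves no room for >= 100 kb tracts")
  structure(list(pedigree = pedigree, n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length_bp = scaffold_length_bp,
                 snp_density = snp_density, founder_het = founder_het,
                 recomb_rate = recomb_rate,
                 impact_fractions = impact_fractions,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate,
                 gq_mean = gq_mean, dp_mean = dp_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Pedigree specification
#'
#' Founders are unrelated individuals with freely drawn haplotypes; each
#' mating row creates one child from two existing parents. The ordering
#' must be topological (parents defined before their children).
#'
#' @param founders character vector of founder ids.
#' @param matings data.frame with columns `parent_a`, `parent_b`, `child`.
#' @param focal_samples ids whose genotypes are emitted.
#' @return a `pedigree_spec`.
#' @export
pedigree_spec <- function(founders, matings, focal_samples) {
  founders <- as.character(founders)
  if (is.null(matings) || nrow(matings) == 0) {
    matings <- data.frame(parent_a = character(), parent_b = character(),
                          child = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("parent_a", "parent_b", "child") %in% names(matings)))
  known <- founders
  for (i in seq_len(nrow(matings))) {
    pa <- matings$parent_a[i]; pb <- matings$parent_b[i]
    ch <- matings$child[i]
    if (!pa %in% known || !pb %in% known)
      stop("mating ", i, ": undefined parent (", pa, " x ", pb, ")")
    if (ch %in% known) stop("individual redefined: ", ch)
    known <- c(known, ch)
  }
  focal_samples <- as.character(focal_samples)
  if (!all(focal_samples %in% known))
    stop("focal sample(s) not in pedigree: ",
         paste(setdiff(focal_samples, known), collapse = ", "))
  structure(list(founders = founders, matings = matings,
                 focal_samples = focal_samples),
            class = "pedigree_spec")
}

#' First-cousin mating pedigree
#'
#' Two full siblings (children of shared grandparents g1 x g2) marry
#' unrelated founders; their children p1 and p2 are first cousins whose
#' offspring has expected inbreeding coefficient F = 1/16 = 0.0625.
#'
#' @param focal id given to the inbred offspring.
#' @return a [pedigree_spec()].
#' @export
first_cousin_pedigree <- function(focal = "cousin_child") {
  matings <- data.frame(
    parent_a = c("g1", "g1", "sibA", "sibB", "p1"),
    parent_b = c("g2", "g2", "inA",  "inB",  "p2"),
    child    = c("sibA", "sibB", "p1", "p2", focal),
    stringsAsFactors = FALSE)
  pedigree_spec(founders = c("g1", "g2", "inA", "inB"),
                matings = matings, focal_samples = focal)
}

## --- haplotype segment machinery -------------------------------------
## A haplotype is a data.frame(start, end, fid): contiguous 1-based
## inclusive intervals covering [1, L], fid = originating founder
## haplotype id. Founder k's haplotypes are fid 2k-1 and 2k.

merge_adjacent <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  keep <- c(TRUE, seg$fid[-1] != seg$fid[-nrow(seg)])
  idx <- cumsum(keep)
  data.frame(start = seg$start[keep],
             end = seg$end[!duplicated(idx, fromLast = TRUE)],
             fid = seg$fid[keep])
}

## Clip a haplotype's segments to [lo, hi]
clip_segments <- function(seg, lo, hi) {
  sel <- seg$end >= lo & seg$start <= hi
  s <- seg[sel, , drop = FALSE]
  if (nrow(s)) {
    s$start <- pmax(s$start, lo)
    s$end <- pmin(s$end, hi)
  }
  s
}

## One meiosis: recombine a parent's two haplotypes into a gamete.
## Poisson(rate * L) crossovers, uniform breakpoints, no interference.
meiose <- function(hapA, hapB, length_bp, rate) {
  k <- stats::rpois(1, rate * length_bp)
  phase <- sample.int(2L, 1L)
  if (k == 0) return(if (phase == 1L) hapA else hapB)
  ## crossover after position x: breakpoints split [1,L] into k+1 intervals
  xo <- sort(sample.int(length_bp - 1L, min(k, length_bp - 1L)))
  bounds <- c(1, xo + 1)
  ends <- c(xo, length_bp)
  pieces <- vector("list", length(bounds))
  for (i in seq_along(bounds)) {
    src <- if ((i + phase) %% 2L == 0L) hapA else hapB
    pieces[[i]] <- clip_segments(src, bounds[i], ends[i])
  }
  merge_adjacent(do.call(rbind, pieces))
}

## Intersection of two haplotypes' segment lists where fid matches:
## the individual's autozygous (IBD) tracts.
ibd_tracts <- function(hap1, hap2) {
  out <- list()
  i <- 1L; j <- 1L
  while (i <= nrow(hap1) && j <= nrow(hap2)) {
    lo <- max(hap1$start[i], hap2$start[j])
    hi <- min(hap1$end[i], hap2$end[j])
    if (lo <= hi && hap1$fid[i] == hap2$fid[j])
      out[[length(out) + 1L]] <- c(lo, hi, hap1$fid[i])
    if (hap1$end[i] < hap2$end[j]) i <- i + 1L else j <- j + 1L
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), fid = integer()))
  m <- do.call(rbind, out)
  d <- data.frame(start = m[, 1], end = m[, 2], fid = m[, 3])
  ## merge only abutting pieces of the same founder haplotype — tracts from
  ## different founder haplotypes are distinct even when adjacent
  if (nrow(d) > 1) {
    new_run <- c(TRUE, d$fid[-1] != d$fid[-nrow(d)] |
                   d$start[-1] != d$end[-nrow(d)] + 1)
    idx <- cumsum(new_run)
    d <- data.frame(start = d$start[new_run],
                    end = as.vector(tapply(d$end, idx, max)),
                    fid = d$fid[new_run])
    rownames(d) <- NULL
  }
  d
}

#' Simulate a pedigree-structured genotype cohort with known truth
#'
#' Founder haplotypes are drawn i.i.d. per site with derived-allele
#' frequency p solving 2p(1-p) = `founder_het` (p <= 0.5, ancestral =
#' reference). Haplotypes descend through the pedigree by crossover
#' recombination (Poisson crossover counts, uniform breakpoints, no
#' interference), and truth tracts record the maximal regions where a focal
#' individual's two haplotypes descend from the same founder haplotype —
#' autozygosity by descent. Impact classes are assigned independently per
#' site; the outgroup row carries the ancestral allele everywhere.
#'
#' @param config a [sim_config()].
#' @return list with elements:
#'   \describe{
#'     \item{genotypes}{[genotype_table()] of the focal samples}
#'     \item{truth}{data.frame of truth tracts (sample, scaffold, start_bp,
#'       end_bp, origin_founder), 1-based inclusive}
#'     \item{variants}{annotated-variant data.frame (scaffold, pos, ref,
#'       alt, ancestral, derived, impact, functional_category)}
#'     \item{outgroup}{data.frame (scaffold, pos, allele)}
#'     \item{scaffold_lengths}{named vector}
#'     \item{config}{the input config}
#'   }
#' @export
simulate_pedigree_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- config$pedigree
  L <- config$scaffold_length_bp
  scafs <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
  scaffold_lengths <- stats::setNames(rep(L, length(scafs)), scafs)

  n_founder_haps <- 2L * length(ped$founders)
  founder_hap_ids <- stats::setNames(
    lapply(seq_along(ped$founders), function(k) c(2L * k - 1L, 2L * k)),
    ped$founders)
  ## derived-allele frequency from target founder heterozygosity
  p_derived <- if (config$founder_het > 0)
    (1 - sqrt(1 - 2 * config$founder_het)) / 2 else 0

  all_sites <- vector("list", length(scafs))
  geno_blocks <- vector("list", length(scafs))
  truth <- list()

  for (s in seq_along(scafs)) {
    n_snp <- stats::rpois(1, config$snp_density * L)
    pos <- sort(sample.int(L, n_snp))
    alleles <- founder_hap_alleles(n_snp, n_founder_haps, p_derived)

    ## descend haplotypes through the pedigree on this scaffold
    haps <- list()
    for (k in seq_along(ped$founders)) {
      ids <- founder_hap_ids[[k]]
      haps[[ped$founders[k]]] <- list(
        data.frame(start = 1L, end = L, fid = ids[1]),
        data.frame(start = 1L, end = L, fid = ids[2]))
    }
    for (i in seq_len(nrow(ped$matings))) {
      pa <- haps[[ped$matings$parent_a[i]]]
      pb <- haps[[ped$matings$parent_b[i]]]
      haps[[ped$matings$child[i]]] <- list(
        meiose(pa[[1]], pa[[2]], L, config$recomb_rate),
        meiose(pb[[1]], pb[[2]], L, config$recomb_rate))
    }

    g <- matrix(NA_integer_, n_snp, length(ped$focal_samples))
    for (m in seq_along(ped$focal_samples)) {
      id <- ped$focal_samples[m]
      h1 <- haps[[id]][[1]]; h2 <- haps[[id]][[2]]
      fid1 <- h1$fid[findInterval(pos, h1$start)]
      fid2 <- h2$fid[findInterval(pos, h2$start)]
      g[, m] <- alleles[cbind(seq_len(n_snp), fid1)] +
        alleles[cbind(seq_len(n_snp), fid2)]
      tr <- ibd_tracts(h1, h2)
      if (nrow(tr))
        truth[[length(truth) + 1L]] <- data.frame(
          sample = id, scaffold = scafs[s],
          start_bp = tr$start, end_bp = tr$end,
          origin_founder = ped$founders[ceiling(tr$fid / 2)],
          stringsAsFactors = FALSE)
    }

    refalt <- draw_ref_alt(n_snp)
    all_sites[[s]] <- data.frame(scaffold = scafs[s], pos = pos,
                                 ref = refalt$ref, alt = refalt$alt,
                                 stringsAsFactors = FALSE)
    geno_blocks[[s]] <- g
  }

  sites <- do.call(rbind, all_sites)
  geno <- do.call(rbind, geno_blocks)
  n <- nrow(sites)
  ns <- length(ped$focal_samples)

  ## genotype error: hom emitted het, het emitted a random hom
  if (config$genotype_error_rate > 0) {
    err <- matrix(stats::runif(n * ns) < config$genotype_error_rate, n, ns)
    hom <- !is.na(geno) & geno != 1L & err
    het <- !is.na(geno) & geno == 1L & err
    geno[hom] <- 1L
    geno[het] <- 2L * (stats::runif(sum(het)) < 0.5)
  }
  if (config$missing_rate > 0) {
    mis <- matrix(stats::runif(n * ns) < config$missing_rate, n, ns)
    geno[mis] <- NA_integer_
  }
  gq <- matrix(pmax(0, round(stats::rnorm(n * ns, config$gq_mean, 10))), n, ns)
  dp <- matrix(stats::rpois(n * ns, config$dp_mean), n, ns)

  impact <- sample(names(config$impact_fractions), n, replace = TRUE,
                   prob = config$impact_fractions)
  variants <- data.frame(
    sites,
    ancestral = sites$ref, derived = sites$alt,
    impact = impact,
    functional_category = c(HIGH = "stop_gained", MODERATE = "missense_variant",
                            LOW = "synonymous_variant",
                            NONE = "intergenic_region")[impact],
    stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  outgroup <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                         allele = sites$ref, stringsAsFactors = FALSE)

  gt <- genotype_table(sites, geno, samples = ped$focal_samples,
                       gq = gq, dp = dp,
                       scaffold_lengths = scaffold_lengths, sort = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), scaffold = character(),
               start_bp = integer(), end_bp = integer(),
               origin_founder = character(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(genotypes = gt, truth = truth, variants = variants,
       outgroup = outgroup, scaffold_lengths = scaffold_lengths,
       config = config)
}

founder_hap_alleles <- function(n_snp, n_haps, p) {
  matrix(stats::rbinom(n_snp * n_haps, 1L, p), n_snp, n_haps)
}

draw_ref_alt <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Fraction of the genome covered by truth tracts, per sample
#'
#' @param truth truth-tract data.frame from [simulate_pedigree_genomes()].
#' @param scaffold_lengths named lengths of the simulated scaffolds.
#' @param samples optional sample ids to report (defaults to those present;
#'   pass explicitly to include samples with zero tracts).
#' @return named numeric vector of autozygous genome fractions.
#' @export
truth_fraction <- function(truth, scaffold_lengths, samples = NULL) {
  total <- sum(as.numeric(scaffold_lengths))
  if (is.null(samples)) samples <- unique(truth$sample)
  len <- vapply(samples, function(id) {
    tr <- truth[truth$sample == id, , drop = FALSE]
    sum(as.numeric(tr$end_bp - tr$start_bp + 1))
  }, numeric(1))
  len / total
}

#' Simulate an MSMC2-style coalescence-rate trajectory
#'
#' Inverts the standard scaling between the coalescence rate lambda and the
#' effective population size: lambda_i = 1 / (2 * mu * N_E(t_i)), evaluated
#' at each output segment's midpoint.
#'
#' @param ne_steps data.frame (or 3-column matrix) with columns `t_start`,
#'   `t_end`, `ne` giving piecewise-constant N_E in generations; steps must
#'   cover every segment midpoint implied by `boundaries`.
#' @param mu per-site per-generation mutation rate.
#' @param boundaries vector of segment time boundaries (length = number of
#'   output segments + 1), non-decreasing.
#' @return a `lambda_trajectory` data.frame with columns `time_index`,
#'   `left_time_boundary`, `right_time_boundary`, `lambda`.
#' @export
simulate_lambda <- function(ne_steps, mu, boundaries) {
  ne_steps <- as.data.frame(ne_steps)
  names(ne_steps)[1:3] <- c("t_start", "t_end", "ne")
  if (any(ne_steps$ne <= 0)) stop("N_E must be positive")
  if (is.unsorted(boundaries)) stop("boundaries must be non-decreasing")
  mids <- (boundaries[-length(boundaries)] + boundaries[-1]) / 2
  ne_at <- vapply(mids, function(t) {
    hit <- which(ne_steps$t_start <= t & t < ne_steps$t_end)
    if (!length(hit)) stop("ne_steps do not cover time ", t)
    ne_steps$ne[hit[1]]
  }, numeric(1))
  traj <- data.frame(time_index = seq_along(mids) - 1L,
                     left_time_boundary = boundaries[-length(boundaries)],
                     right_time_boundary = boundaries[-1],
                     lambda = 1 / (2 * mu * ne_at))
  class(traj) <- c("lambda_trajectory", "data.frame")
  traj
}
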