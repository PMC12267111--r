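# Independent brute-force oracles. These deliberately re-state the
# documented algorithms with plain loops and share no code with the
# package implementations.

# Literal sliding-window ROH scan for one scaffold.
oracle_roh_scaffold <- function(pos, g, p) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snps = integer(),
                      n_het = integer())
  n <- length(pos)
  Lw <- p$window_snp
  if (n < Lw) return(empty)
  nw <- n - Lw + 1L

  hit <- logical(nw)
  for (w in seq_len(nw)) {
    win <- g[w:(w + Lw - 1L)]
    hit[w] <- sum(win == 1L, na.rm = TRUE) <= p$window_het &&
      sum(is.na(win)) <= p$window_missing
  }
  pass <- logical(n)
  for (j in seq_len(n)) {
    ws <- max(1L, j - Lw + 1L):min(nw, j)
    pass[j] <- mean(hit[ws]) >= p$window_threshold
  }

  segs <- empty
  j <- 1L
  while (j <= n) {
    if (!pass[j]) { j <- j + 1L; next }
    k <- j
    while (k < n && pass[k + 1L]) k <- k + 1L

    # split candidate [j, k] at over-long gaps
    gap_pieces <- list()
    a <- j
    for (q in j:k) {
      if (q < k && pos[q + 1L] - pos[q] > p$gap_kb * 1000) {
        gap_pieces[[length(gap_pieces) + 1L]] <- c(a, q)
        a <- q + 1L
      }
    }
    gap_pieces[[length(gap_pieces) + 1L]] <- c(a, k)

    for (gp in gap_pieces) {
      # greedy split so that no piece holds more than seg_het hets
      het_pieces <- list()
      a2 <- gp[1]
      count <- 0L
      for (q in gp[1]:gp[2]) {
        if (!is.na(g[q]) && g[q] == 1L) {
          count <- count + 1L
          if (count > p$seg_het) {
            if (a2 <= q - 1L)
              het_pieces[[length(het_pieces) + 1L]] <- c(a2, q - 1L)
            a2 <- q + 1L
            count <- 0L
          }
        }
      }
      if (a2 <= gp[2]) het_pieces[[length(het_pieces) + 1L]] <- c(a2, gp[2])

      for (hp in het_pieces) {
        # trim ends to outermost homozygous non-missing call
        i0 <- hp[1]; i1 <- hp[2]
        while (i0 <= i1 && (is.na(g[i0]) || g[i0] == 1L)) i0 <- i0 + 1L
        while (i1 >= i0 && (is.na(g[i1]) || g[i1] == 1L)) i1 <- i1 - 1L
        if (i0 > i1) next
        ns <- i1 - i0 + 1L
        len <- pos[i1] - pos[i0] + 1L
        if (ns < p$min_snp) next
        if (len < p$min_kb * 1000) next
        if (len / ns > p$density_kb * 1000) next
        nh <- sum(g[i0:i1] == 1L, na.rm = TRUE)
        segs <- rbind(segs, data.frame(start_bp = pos[i0], end_bp = pos[i1],
                                       length_bp = len, n_snps = ns,
                                       n_het = nh))
      }
    }
    j <- k + 1L
  }
  segs
}

# Single-locus gene-dropping estimate of the inbreeding coefficient of a
# pedigree's focal individual: probability its two alleles are copies of
# one founder allele.
oracle_gene_drop_f <- function(ped, focal, n_rep = 20000) {
  founders <- ped$founders
  hits <- 0L
  for (r in seq_len(n_rep)) {
    alleles <- list()
    for (k in seq_along(founders))
      alleles[[founders[k]]] <- c(2L * k - 1L, 2L * k)
    for (i in seq_len(nrow(ped$matings))) {
      pa <- alleles[[ped$matings$parent_a[i]]]
      pb <- alleles[[ped$matings$parent_b[i]]]
      alleles[[ped$matings$child[i]]] <-
        c(pa[sample.int(2L, 1L)], pb[sample.int(2L, 1L)])
    }
    a <- alleles[[focal]]
    if (a[1] == a[2]) hits <- hits + 1L
  }
  hits / n_rep
}

# O(n * m) point-in-interval check.
oracle_intersect <- function(segments, variants) {
  flag <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    for (k in seq_len(nrow(segments))) {
      if (variants$scaffold[i] == segments$scaffold[k] &&
          variants$pos[i] >= segments$start_bp[k] &&
          variants$pos[i] <= segments$end_bp[k]) {
        flag[i] <- TRUE
        break
      }
    }
  }
  flag
}

# Allele-frequency formulation of per-individual load zygosity: BCFtools
# -q style thresholds on the sample's own derived-allele frequency.
oracle_zygosity_af <- function(geno, derived_is_alt,
                               carrier_min = 0.05, realized_min = 0.55) {
  if (is.na(geno)) return("absent")
  alt_af <- geno / 2
  af <- if (derived_is_alt) alt_af else 1 - alt_af
  if (af >= realized_min) "realized"
  else if (af >= carrier_min) "potential"
  else "absent"
}
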