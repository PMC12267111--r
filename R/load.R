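#' Polarize variants against an outgroup
#'
#' The outgroup individual is taken to carry the ancestral allele. When its
#' allele matches the site's ref or alt, the *other* allele is the derived
#' one (the reference itself can be derived); sites where the outgroup call
#' is missing or is a third allele are excluded, with the exclusion tally
#' attached as an attribute.
#'
#' @param variants data.frame with `scaffold`, `pos`, `ref`, `alt` and
#'   (optionally) `impact` / `functional_category` columns.
#' @param outgroup data.frame with `scaffold`, `pos`, `allele`.
#' @return the variants that could be polarized, with `ancestral` and
#'   `derived` columns set; `attr(, "n_excluded")` counts dropped sites.
#' @export
polarize <- function(variants, outgroup) {
  key_v <- paste(variants$scaffold, variants$pos)
  key_o <- paste(outgroup$scaffold, outgroup$pos)
  og <- outgroup$allele[match(key_v, key_o)]
  ancestral <- ifelse(!is.na(og) & og == variants$ref, variants$ref,
                      ifelse(!is.na(og) & og == variants$alt, variants$alt,
                             NA_character_))
  derived <- ifelse(is.na(ancestral), NA_character_,
                    ifelse(ancestral == variants$ref,
                           variants$alt, variants$ref))
  keep <- !is.na(ancestral)
  out <- variants[keep, , drop = FALSE]
  out$ancestral <- ancestral[keep]
  out$derived <- derived[keep]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Classify per-site load zygosity for one sample
#'
#' Maps each polarized site to the sample's derived-allele dosage and then
#' to a load state: dosage 0 is `absent`, 1 (heterozygous carrier) is
#' `potential` load, 2 (homozygous derived) is `realized` load. This equals
#' the per-individual allele-frequency filtering formulation (a het's
#' derived frequency 0.5 passes a 0.05 cut but not 0.55; a homozygote's 1.0
#' passes both). Missing genotypes classify as `absent`.
#'
#' @param x a `genotype_table` whose sites include the polarized variants.
#' @param variants polarized variant data.frame (from [polarize()]).
#' @param sample sample id.
#' @return factor of states (`absent`/`potential`/`realized`) along
#'   `variants`; `attr(, "n_missing")` counts missing genotypes.
#' @export
classify_zygosity <- function(x, variants, sample) {
  g <- sample_calls(x, sample)
  key_x <- paste(x$sites$scaffold, x$sites$pos)
  key_v <- paste(variants$scaffold, variants$pos)
  idx <- match(key_v, key_x)
  if (anyNA(idx))
    stop("variant position(s) absent from genotype table: ",
         key_v[which(is.na(idx))[1]])
  gv <- g[idx]
  ## derived dosage: flip the alt dosage where the reference is derived
  dosage <- ifelse(variants$derived == variants$alt, gv, 2L - gv)
  state <- rep("absent", length(dosage))
  state[!is.na(dosage) & dosage == 1L] <- "potential"
  state[!is.na(dosage) & dosage == 2L] <- "realized"
  out <- factor(state, levels = c("absent", "potential", "realized"))
  attr(out, "n_missing") <- sum(is.na(gv))
  out
}

#' Deleterious impact classes
#'
#' @return character vector `c("LOW", "MODERATE", "HIGH")`: the SnpEff-style
#'   classes counted as putatively deleterious (`NONE`/MODIFIER excluded).
#' @export
deleterious_impacts <- function() c("LOW", "MODERATE", "HIGH")

#' Cross-tabulate potential and realized load by impact class
#'
#' @param states factor from [classify_zygosity()], aligned with `impacts`.
#' @param impacts character vector of impact classes per site.
#' @param impact_levels which classes to tabulate (default the deleterious
#'   ones; pass `"HIGH"` for a high-impact-only split).
#' @return data.frame: `impact`, `potential`, `realized`, `total`.
#' @export
summarize_load <- function(states, impacts,
                           impact_levels = deleterious_impacts()) {
  stopifnot(length(states) == length(impacts))
  imp <- factor(impacts, levels = impact_levels)
  tab <- table(impact = imp, state = states)
  out <- data.frame(impact = rownames(tab),
                    potential = as.integer(tab[, "potential"]),
                    realized = as.integer(tab[, "realized"]),
                    stringsAsFactors = FALSE)
  out$total <- out$potential + out$realized
  out
}

#' Fixed deleterious load across a cohort
#'
#' Derived-allele frequencies are computed over all non-missing called
#' alleles in the cohort; variants whose derived frequency exceeds
#' `freq_threshold` (strictly) are counted as fixed load per impact class.
#'
#' @param x a `genotype_table` covering all cohort samples.
#' @param variants polarized variant data.frame.
#' @param freq_threshold strict lower bound on derived frequency
#'   (default 0.95).
#' @param impact_levels impact classes to tabulate.
#' @return list with `counts` (data.frame impact/count), `total`, and
#'   `frequencies` (per-variant derived frequency, NA where no calls).
#' @export
fixed_load <- function(x, variants, freq_threshold = 0.95,
                       impact_levels = deleterious_impacts()) {
  key_x <- paste(x$sites$scaffold, x$sites$pos)
  key_v <- paste(variants$scaffold, variants$pos)
  idx <- match(key_v, key_x)
  if (anyNA(idx)) stop("variant position(s) absent from genotype table")
  g <- x$geno[idx, , drop = FALSE]
  alt_dosage <- rowSums(g, na.rm = TRUE)
  n_called <- 2 * rowSums(!is.na(g))
  derived_dosage <- ifelse(variants$derived == variants$alt,
                           alt_dosage, n_called - alt_dosage)
  freq <- ifelse(n_called > 0, derived_dosage / n_called, NA_real_)
  fixed <- !is.na(freq) & freq > freq_threshold
  imp <- factor(variants$impact, levels = impact_levels)
  tab <- table(imp[fixed])
  counts <- data.frame(impact = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(counts = counts, total = sum(counts$count), frequencies = freq,
       n_skipped = sum(n_called == 0))
}
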