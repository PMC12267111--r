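#' Run the full diagnosis workflow on one cohort
#'
#' Orchestrates simulate (or load) -> filter -> ROH -> diversity -> load ->
#' ROH intersection -> demography and writes one TSV per stage plus a
#' combined per-sample wide table and a JSON manifest (seed, parameters,
#' package version) from which every table can be regenerated.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{sim}{a [sim_config()] (simulation mode), or instead
#'       `vcf`/`impact_tsv`/`outgroup_tsv`/`scaffold_tsv` paths}
#'     \item{roh}{a [roh_params()]; when omitted, the L value is calibrated
#'       from the data via [l_parameter()]}
#'     \item{gq_min,dp_low,dp_high}{call filters (defaults 20, 4, 300)}
#'     \item{fixed_freq}{fixed-load frequency threshold (default 0.95)}
#'     \item{mu}{mutation rate for demography (default 1e-8)}
#'     \item{lambda_file}{optional MSMC2-style trajectory to summarize; in
#'       simulation mode a constant-N_E trajectory is generated when absent}
#'     \item{min_scaffold_bp}{scaffold retention threshold (default 1.05e6)}
#'     \item{out_dir}{output directory}
#'   }
#' @return invisibly, a list of the per-stage tables and written paths.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gq_min <- config$gq_min %||% 20
  dp_low <- config$dp_low %||% 4
  dp_high <- config$dp_high %||% 300
  fixed_freq <- config$fixed_freq %||% 0.95
  mu <- config$mu %||% 1e-8
  min_scaffold_bp <- config$min_scaffold_bp %||% 1.05e6

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_pedigree_genomes(config$sim))
    gt <- sim$genotypes
    variants <- sim$variants
    outgroup <- sim$outgroup
    write_truth_bed(sim$truth, file.path(out_dir, "truth_tracts.bed"))
  } else {
    gt <- stage("read", read_vcf(
      config$vcf,
      scaffold_lengths = if (!is.null(config$scaffold_tsv))
        read_scaffold_lengths(config$scaffold_tsv) else NULL))
    variants <- stage("read", read_impact_tsv(config$impact_tsv))
    outgroup <- stage("read", read_outgroup_tsv(config$outgroup_tsv))
    sim <- NULL
  }

  gt <- stage("filter", {
    g <- filter_calls(gt, gq_min = gq_min, dp_low = dp_low,
                      dp_high = dp_high)
    filter_scaffolds(g, min_length_bp = min_scaffold_bp)
  })
  genome_bp <- retained_genome_length(gt)

  params <- config$roh
  if (is.null(params)) {
    mean_het <- mean(gt$geno == 1L, na.rm = TRUE)
    L <- l_parameter(n_sites(gt), length(gt$samples), mean_het)
    params <- roh_params(window_snp = L)
  }

  roh_by_sample <- stage("roh", lapply(gt$samples, function(id)
    detect_roh(gt, params, id)))
  names(roh_by_sample) <- gt$samples
  roh_all <- do.call(rbind, roh_by_sample)
  roh_summary <- do.call(rbind, lapply(gt$samples, function(id)
    summarize_roh(roh_by_sample[[id]], genome_bp)))
  roh_summary$sample <- gt$samples  # zero-ROH samples keep their id

  diversity <- stage("diversity", summarize_diversity(gt))

  pol <- stage("load", polarize(variants, outgroup))
  load_rows <- list(); ctx_rows <- list()
  for (id in gt$samples) {
    st <- classify_zygosity(gt, pol, id)
    ls <- summarize_load(st, pol$impact)
    ls$sample <- id
    load_rows[[id]] <- ls
    fl <- intersect_variants(roh_by_sample[[id]], pol)
    cx <- summarize_context(fl, st, pol$impact, roh_by_sample[[id]])
    ctx_rows[[id]] <- data.frame(
      sample = id, n_roh = cx$n_roh,
      deleterious_in_roh = cx$n_in_roh,
      deleterious_out_roh = cx$n_out_roh,
      variants_per_roh = cx$variants_per_roh,
      in_short = cx$by_size_class["short"],
      in_medium = cx$by_size_class["medium"],
      in_long = cx$by_size_class["long"],
      stringsAsFactors = FALSE)
  }
  load_summary <- do.call(rbind, load_rows)
  context_summary <- do.call(rbind, ctx_rows)
  rownames(load_summary) <- rownames(context_summary) <- NULL
  fixed <- stage("load", fixed_load(gt, pol, freq_threshold = fixed_freq))

  traj <- NULL
  if (!is.null(config$lambda_file)) {
    traj <- stage("demography", parse_msmc(config$lambda_file))
  } else if (!is.null(sim)) {
    traj <- simulate_lambda(
      data.frame(t_start = 0, t_end = 1e6, ne = 5e4), mu = mu,
      boundaries = seq(0, 28e3, length.out = 29))
  }
  demog <- if (!is.null(traj))
    stage("demography", geometric_mean_ne(traj, mu = mu)) else NULL

  wide <- Reduce(function(a, b) merge(a, b, by = "sample"),
                 list(diversity, roh_summary,
                      context_summary))
  if (!is.null(demog)) {
    wide$geo_mean_ne <- demog$ne
    wide$log10_ne <- demog$log10_ne
  }

  tsv <- function(d, f) {
    utils::write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(diversity, "diversity.tsv")
  tsv(roh_summary, "roh_summary.tsv")
  write_roh(roh_all, file.path(out_dir, "roh_segments.tsv"), "hom")
  tsv(load_summary, "load_summary.tsv")
  tsv(context_summary, "roh_context.tsv")
  tsv(fixed$counts, "fixed_load.tsv")
  if (!is.null(demog)) tsv(demog, "demography.tsv")
  tsv(wide, "combined.tsv")

  manifest <- list(
    package = "ursaroh",
    version = as.character(utils::packageVersion("ursaroh")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    roh_params = unclass(params),
    filters = list(gq_min = gq_min, dp_low = dp_low, dp_high = dp_high,
                   min_scaffold_bp = min_scaffold_bp,
                   fixed_freq = fixed_freq, mu = mu),
    n_samples = length(gt$samples),
    n_sites = n_sites(gt),
    retained_genome_bp = genome_bp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(genotypes = gt, roh = roh_by_sample,
                 roh_summary = roh_summary, diversity = diversity,
                 load = load_summary, context = context_summary,
                 fixed = fixed, demography = demog, params = params,
                 manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
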