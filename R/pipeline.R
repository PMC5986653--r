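# Pipeline orchestration: validate a run configuration, execute the three
# analyses (chromatin state + discriminating hyperacetylation, methylation
# signature, variant cascade) in dependency order, and write a run report.

.default_thresholds <- function() {
  list(fdr_max = 0.01, p_max = 0.0002, pairwise_p = 0.01, fc_sd_mult = 3.0,
       meth_p = 0.005, meth_p_strict = 0.0007, cov_min = 5,
       dp_min = 20, phred_min = 40, maf_max = 0.05, min_confirmations = 1,
       distance_max = 50000, rpkm_sum_min = 100)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. The configuration must name a bundle
#' directory (`bundle_dir`) containing a `manifest.json` as written by
#' [generate_bundle()], or spell out the same paths under `paths`. Omitted
#' thresholds receive the study defaults (FDR < 0.01, p < 0.0002,
#' methylation p < 0.005 / 0.0007, coverage >= 5, DP >= 20, Phred >= 40,
#' MAF <= 0.05, 3-SD fold-change rule). Every referenced path must exist and
#' every threshold must satisfy its bounds. Validation is idempotent: a
#' validated configuration re-validates to itself.
#'
#' @param config list or YAML file path.
#' @return validated configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("validate_config: config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("validate_config: config must be a list or YAML path", call. = FALSE)
  if (is.null(config$bundle_dir) && is.null(config$paths))
    stop("validate_config: missing key 'bundle_dir' (or explicit 'paths')",
         call. = FALSE)
  if (!is.null(config$bundle_dir)) {
    mf <- file.path(config$bundle_dir, "manifest.json")
    if (!file.exists(mf))
      stop("validate_config: bundle_dir has no manifest.json: ",
           config$bundle_dir, call. = FALSE)
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    paths <- manifest$paths
    rel <- setdiff(names(paths), c("chip_samples", "meth_samples"))
    paths[rel] <- lapply(paths[rel],
                         function(p) file.path(config$bundle_dir, p))
    if (is.null(config$paths)) config$paths <- paths
  }
  req <- c("peaks_dir", "regions_bed", "counts_tsv", "count_groups_tsv",
           "meth_dir", "meth_groups_tsv", "cohort_matrix_tsv", "variants_vcf")
  for (k in req) {
    if (is.null(config$paths[[k]]))
      stop("validate_config: missing path key '", k, "'", call. = FALSE)
    if (!file.exists(config$paths[[k]]))
      stop("validate_config: path for '", k, "' does not exist: ",
           config$paths[[k]], call. = FALSE)
  }
  th <- .default_thresholds()
  user <- config$thresholds
  for (k in names(user)) {
    if (!k %in% names(th))
      stop("validate_config: unknown threshold '", k, "'", call. = FALSE)
    th[[k]] <- user[[k]]
  }
  for (k in c("fdr_max", "p_max", "pairwise_p", "meth_p", "meth_p_strict"))
    if (th[[k]] <= 0 || th[[k]] > 1)
      stop("validate_config: threshold '", k, "' must lie in (0, 1]",
           call. = FALSE)
  for (k in c("fc_sd_mult", "cov_min", "distance_max"))
    if (th[[k]] <= 0)
      stop("validate_config: threshold '", k, "' must be > 0", call. = FALSE)
  for (k in c("dp_min", "phred_min", "maf_max", "min_confirmations"))
    if (th[[k]] < 0)
      stop("validate_config: threshold '", k, "' must be >= 0", call. = FALSE)
  config$thresholds <- th
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) config$out_dir <- "episig_out"
  class(config) <- "pipeline_config"
  config
}

.read_count_table <- function(config) {
  regions <- read_bed(config$paths$regions_bed)
  long <- read.delim(config$paths$counts_tsv, stringsAsFactors = FALSE)
  samples <- unique(long$sample)
  raw <- matrix(0, nrow(regions), length(samples),
                dimnames = list(NULL, samples))
  rid <- factor(long$region_id, levels = unique(long$region_id))
  raw[cbind(as.integer(rid), match(long$sample, samples))] <- long$raw_count
  grp <- read.delim(config$paths$count_groups_tsv, stringsAsFactors = FALSE)
  groups <- factor(setNames(grp$group, grp$sample)[samples],
                   levels = c("APL", "hrAPL"))
  list(counts = region_count_table(regions[, c("chrom", "start", "end")], raw),
       groups = groups)
}

.run_chromatin <- function(config, out, report) {
  th <- config$thresholds
  samples <- config$paths$chip_samples
  if (is.null(samples)) {
    beds <- list.files(config$paths$peaks_dir, pattern = "\\.H3K4me3\\.bed$")
    samples <- sub("\\.H3K4me3\\.bed$", "", beds)
  }
  read_mark <- function(sid, mark)
    peak_set(sid, mark, read_bed(file.path(config$paths$peaks_dir,
                                           paste0(sid, ".", mark, ".bed"))))
  cand <- lapply(samples, function(sid)
    define_candidate_regions(read_mark(sid, "H3K4me3"),
                             read_mark(sid, "H3K4me1")))
  names(cand) <- samples
  prom <- if (length(samples) >= 2)
    common_regions(lapply(cand, `[[`, "promoters"))
  else cand[[1]]$promoters
  enh <- if (length(samples) >= 2)
    common_regions(lapply(cand, `[[`, "enhancers"))
  else cand[[1]]$enhancers
  # pooled activity marks across samples
  ac <- merge_intervals(do.call(rbind, lapply(samples, function(sid)
    read_mark(sid, "H3K27ac")$intervals)))
  me3 <- merge_intervals(do.call(rbind, lapply(samples, function(sid)
    read_mark(sid, "H3K27me3")$intervals)))
  cls <- rbind(
    classify_activity(prom, "promoter", ac, me3),
    classify_activity(enh, "enhancer", ac, me3))
  write_bed(cls[, 1:3], file.path(out, "regulatory_regions.bed"),
            name = paste(cls$region_class, cls$activity, sep = ":"))
  report$chromatin <- list(
    n_samples = length(samples),
    common_promoters = nrow(prom), common_enhancers = nrow(enh),
    active_promoters = sum(cls$region_class == "promoter" &
                             cls$activity == "active"),
    active_enhancers = sum(cls$region_class == "enhancer" &
                             cls$activity == "active"))

  ctab <- .read_count_table(config)
  res <- nb_differential_test(ctab$counts, ctab$groups)
  res <- discriminating_regions(
    res, differential_thresholds(fdr_max = th$fdr_max, p_max = th$p_max,
                                 pairwise_p = th$pairwise_p,
                                 fc_sd_mult = th$fc_sd_mult),
    direction = "gain")
  write.table(res, file.path(out, "differential_regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(res[res$selected, c("chrom", "start", "end")],
            file.path(out, "discriminating_regions.bed"))
  norm <- sweep(ctab$counts$raw, 2, size_factors(ctab$counts$raw), "/")
  fc <- changed_regions_fc_sd(
    rowMeans(norm[, ctab$groups == "APL", drop = FALSE]),
    rowMeans(norm[, ctab$groups == "hrAPL", drop = FALSE]),
    fc_sd_mult = th$fc_sd_mult, regions = ctab$counts$regions)
  write.table(fc, file.path(out, "changed_regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$diff <- list(
    n_regions = nrow(res), discriminating = sum(res$selected),
    fc_gain = sum(fc$direction == "gain"),
    fc_loss = sum(fc$direction == "loss"))
  report
}

.run_methylation <- function(config, out, report) {
  th <- config$thresholds
  groups <- read.delim(config$paths$meth_groups_tsv, stringsAsFactors = FALSE)
  samples <- config$paths$meth_samples
  if (is.null(samples)) {
    files <- list.files(config$paths$meth_dir, pattern = "\\.calls\\.tsv$")
    samples <- sub("\\.calls\\.tsv$", "", files)
  }
  per_sample <- lapply(samples, function(s) {
    calls <- read_cpg_calls(file.path(config$paths$meth_dir,
                                      paste0(s, ".calls.tsv")))
    filter_coverage(combine_symmetric_cpgs(filter_cg_context(calls)),
                    min_total = th$cov_min)
  })
  names(per_sample) <- samples
  mat <- build_methylation_matrix(per_sample, groups)
  sig <- supervised_cpg_test(mat, primary = th$meth_p,
                             stringent = th$meth_p_strict)
  cohort <- read_cohort_matrix(config$paths$cohort_matrix_tsv, groups)
  sig <- refine_against_cohort(sig, cohort)
  write_signature(sig, file.path(out, "methylation_signature.tsv"))
  final <- sig[sig$in_final, , drop = FALSE]
  write_bed(data.frame(chrom = final$chrom, start = final$pos,
                       end = final$pos + 2, stringsAsFactors = FALSE),
            file.path(out, "final_cpgs.bed"))
  parts <- classify_direction(sig[sig$in_signature, , drop = FALSE])
  report$methylation <- list(
    n_cpgs_tested = nrow(sig), signature = sum(sig$in_signature),
    hypo = unname(parts$counts["hypo"]), hyper = unname(parts$counts["hyper"]),
    stringent = sum(sig$in_stringent), final = sum(sig$in_final))
  report
}

.run_variants <- function(config, out, report) {
  th <- config$thresholds
  v <- read_variants(config$paths$variants_vcf)
  casc <- run_cascade(v, filter_thresholds(
    dp_min = th$dp_min, phred_min = th$phred_min, maf_max = th$maf_max,
    min_confirmations = th$min_confirmations))
  write_variants_vcf(casc$survivors, file.path(out, "variants_filtered.vcf"))
  write_attrition(casc, file.path(out, "variant_attrition.tsv"))
  report$variants <- list(n_in = nrow(v), survivors = nrow(casc$survivors),
                          incomplete = casc$incomplete)
  report
}

#' Run the analysis pipeline
#'
#' Executes the requested analyses in dependency order on a validated
#' configuration, writes all stage outputs plus a machine-readable report
#' (`report.tsv`, key-value) under the configured output directory, and
#' returns the report. All stages are deterministic given their inputs, so
#' reruns produce digest-identical outputs.
#'
#' @param config a [validate_config()] result (or something it accepts).
#' @param analyses subset of `c("chromatin", "methylation", "variants")`.
#' @return report, invisibly: nested list of per-stage counts and thresholds.
#' @export
run_pipeline <- function(config,
                         analyses = c("chromatin", "methylation",
                                      "variants")) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (length(analyses)) analyses <- match.arg(analyses, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, thresholds = config$thresholds)
  t0 <- Sys.time()
  write_report <- function(report) {
    report$wall_time_s <- round(as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")), 3)
    flat <- unlist(report)
    write.table(data.frame(key = names(flat), value = as.character(flat)),
                file.path(out, "report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report
  }
  runners <- list(chromatin = .run_chromatin, methylation = .run_methylation,
                  variants = .run_variants)
  for (stage in names(runners)) {
    if (!stage %in% analyses) next
    report <- tryCatch(runners[[stage]](config, out, report),
                       error = function(e) {
                         # partial outputs stay on disk; the report marks
                         # the failed stage before the error propagates
                         report$failed_stage <- stage
                         write_report(report)
                         stop(e)
                       })
  }
  invisible(write_report(report))
}
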