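# Deterministic synthetic study bundles with planted ground truth.
#
# The generator emulates the study design: a small high-risk discovery group
# against a standard-risk group for ChIP-seq counts (negative-binomial with
# planted hyperacetylation), a 5 vs 10 methylation discovery design with
# planted hypo/hyper CpGs (beta-binomial noise), a 181-column AML cohort
# matrix with missingness, histone-mark peak sets with planted promoter /
# enhancer / activity structure, and a small VCF in which every filter stage
# has at least one record failing only that stage.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 5 high-risk vs 10 standard-risk
#' methylation samples plus a 181-sample AML cohort; negative-binomial region
#' counts with mean 100 and dispersion 0.05; planted CpGs shifted by
#' `|delta_beta| = 0.5` at mean coverage 30; two 5-Mb synthetic contigs and
#' about a thousand regions/CpGs, small enough for sub-minute full runs.
#'
#' @param seed integer random seed governing every generated artifact.
#' @param contigs named numeric vector of contig lengths.
#' @param n_promoters,n_enhancers planted locus counts for peak generation.
#' @param overlap_frac fraction of loci carrying both H3K4me3 and H3K4me1
#'   (hence excluded from candidates by construction).
#' @param active_frac fraction of loci planted as active (H3K27ac, no
#'   H3K27me3).
#' @param n_chip_samples ChIP discovery samples sharing the planted loci.
#' @param n_regions regions in the count table.
#' @param n_count_hrapl,n_count_other samples per count group.
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion.
#' @param planted_region_frac fraction of regions with planted
#'   hyperacetylation in the high-risk group.
#' @param region_log2fc planted log2 fold change of those regions.
#' @param libsize_jitter relative library-size spread (+/- 30% by default).
#' @param n_cpgs CpG dyads in the methylome.
#' @param n_meth_hrapl,n_meth_apl methylation discovery group sizes.
#' @param n_aml AML cohort columns.
#' @param n_planted_cpgs planted differential CpGs (half hypo, half hyper).
#' @param delta_beta planted group-mean beta shift.
#' @param coverage_mean mean CpG coverage (Poisson).
#' @param bb_overdispersion beta-binomial overdispersion rho in (0, 1).
#' @param aml_missing_rate per-cell missingness of the AML matrix.
#' @param noncg_frac extra non-CG calls written per CpG (exercises the
#'   context filter).
#' @param n_pass_variants VCF records passing the whole cascade.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              contigs = c(chrS1 = 5e6, chrS2 = 5e6),
                              n_promoters = 200, n_enhancers = 300,
                              overlap_frac = 0, active_frac = 0.6,
                              n_chip_samples = 2,
                              n_regions = 1000,
                              n_count_hrapl = 5, n_count_other = 5,
                              nb_mean = 100, nb_dispersion = 0.05,
                              planted_region_frac = 0.05, region_log2fc = 2,
                              libsize_jitter = 0.3,
                              n_cpgs = 1000,
                              n_meth_hrapl = 5, n_meth_apl = 10, n_aml = 181,
                              n_planted_cpgs = 50, delta_beta = 0.5,
                              coverage_mean = 30, bb_overdispersion = 0.02,
                              aml_missing_rate = 0.05, noncg_frac = 0.1,
                              n_pass_variants = 3) {
  cfg <- as.list(environment())
  if (any(contigs <= 0)) stop("simulation_config: contig lengths must be > 0",
                              call. = FALSE)
  for (f in c("overlap_frac", "active_frac", "planted_region_frac",
              "aml_missing_rate", "bb_overdispersion"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("simulation_config: ", f, " must lie in [0, 1]", call. = FALSE)
  if (nb_dispersion <= 0)
    stop("simulation_config: nb_dispersion must be > 0", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# evenly spaced, non-overlapping loci over the configured contigs
.place_loci <- function(contigs, n, min_width, max_width, gap_frac = 0.35) {
  total <- sum(contigs)
  per <- round(n * contigs / total)
  per[length(per)] <- n - sum(per[-length(per)])
  out <- NULL
  for (ci in seq_along(contigs)) {
    k <- per[ci]
    if (k <= 0) next
    slot <- floor(contigs[ci] / k)
    if (slot < max_width / (1 - gap_frac))
      stop("contig ", names(contigs)[ci], " too small for ", k, " loci",
           call. = FALSE)
    width <- round(runif(k, min_width, max_width))
    start <- (seq_len(k) - 1) * slot +
      round(runif(k, 0, pmax(0, slot - width - 1)))
    out <- rbind(out, data.frame(chrom = names(contigs)[ci], start = start,
                                 end = start + width,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Generate per-sample, per-mark peak sets with planted structure
#'
#' H3K4me3 peaks are placed at planted promoter loci and H3K4me1 peaks at
#' planted enhancer loci; a configurable fraction of loci additionally carry
#' the other mark (and are therefore excluded by
#' [define_candidate_regions()]). H3K27ac peaks are placed at loci planted
#' active and H3K27me3 peaks at loci planted inactive. Peak edges are
#' jittered per sample so common regions are the shared cores.
#'
#' @param config a [simulation_config()].
#' @return list: `peaks` (nested list `sample -> mark -> peak_set`),
#'   `truth` (locus data frame: coordinates, `class`, `active`,
#'   `cross_marked`).
#' @export
generate_peaks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  loci <- .place_loci(config$contigs, config$n_promoters + config$n_enhancers,
                      800, 2500)
  cls <- sample(rep(c("promoter", "enhancer"),
                    c(config$n_promoters, config$n_enhancers)))
  active <- runif(nrow(loci)) < config$active_frac
  cross <- runif(nrow(loci)) < config$overlap_frac
  truth <- cbind(loci, data.frame(class = cls, active = active,
                                  cross_marked = cross,
                                  stringsAsFactors = FALSE))
  samples <- sprintf("hr%02d", seq_len(config$n_chip_samples))
  jitter_iv <- function(iv, j = 60) {
    s <- pmax(0, iv$start + round(runif(nrow(iv), -j, j)))
    e <- iv$end + round(runif(nrow(iv), -j, j))
    data.frame(chrom = iv$chrom, start = s, end = pmax(e, s + 50),
               stringsAsFactors = FALSE)
  }
  peaks <- lapply(samples, function(sid) {
    me3_iv <- truth[truth$class == "promoter" | truth$cross_marked, 1:3]
    me1_iv <- truth[truth$class == "enhancer" | truth$cross_marked, 1:3]
    ac_iv <- truth[truth$active, 1:3]
    k27me3_iv <- truth[!truth$active, 1:3]
    list(H3K4me3 = peak_set(sid, "H3K4me3", jitter_iv(me3_iv)),
         H3K4me1 = peak_set(sid, "H3K4me1", jitter_iv(me1_iv)),
         H3K27ac = peak_set(sid, "H3K27ac", jitter_iv(ac_iv)),
         H3K27me3 = peak_set(sid, "H3K27me3", jitter_iv(k27me3_iv)))
  })
  names(peaks) <- samples
  list(peaks = peaks, truth = truth)
}

#' Generate a region count table with planted hyperacetylation
#'
#' Negative-binomial counts per region and sample at the configured mean and
#' dispersion, with library sizes varying by the configured jitter. Planted
#' regions receive the configured log2 fold change in the high-risk (hrAPL)
#' group.
#'
#' @param config a [simulation_config()].
#' @param regions optional interval data frame; generated when omitted.
#' @return list: `counts` (a [region_count_table()]), `groups` (factor,
#'   levels APL then hrAPL), `truth` (data frame with `planted`,
#'   `direction`).
#' @export
generate_counts <- function(config, regions = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  if (is.null(regions))
    regions <- .place_loci(config$contigs, config$n_regions, 500, 2000)
  n <- nrow(regions)
  samples <- c(sprintf("hr%02d", seq_len(config$n_count_hrapl)),
               sprintf("ap%02d", seq_len(config$n_count_other)))
  groups <- factor(rep(c("hrAPL", "APL"),
                       c(config$n_count_hrapl, config$n_count_other)),
                   levels = c("APL", "hrAPL"))
  libfac <- runif(length(samples), 1 - config$libsize_jitter,
                  1 + config$libsize_jitter)
  n_planted <- round(config$planted_region_frac * n)
  planted <- sort(sample.int(n, n_planted))
  mu <- matrix(config$nb_mean, n, length(samples))
  mu[planted, groups == "hrAPL"] <-
    config$nb_mean * 2^config$region_log2fc
  mu <- sweep(mu, 2, libfac, "*")
  raw <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                n, length(samples), dimnames = list(NULL, samples))
  norm <- sweep(raw, 2, libfac, "/")
  truth <- cbind(regions,
                 data.frame(planted = seq_len(n) %in% planted,
                            direction = ifelse(seq_len(n) %in% planted,
                                               "gain", "none"),
                            stringsAsFactors = FALSE))
  list(counts = region_count_table(regions, raw, norm), groups = groups,
       samples = samples, truth = truth, library_factors = libfac)
}

# beta-binomial draw: per-observation success probability from a beta with
# mean mu and overdispersion rho, then binomial counts
.rbetabinom <- function(n, size, mu, rho) {
  conc <- 1 / rho - 1
  p <- rbeta(n, mu * conc, (1 - mu) * conc)
  rbinom(n, size, p)
}

#' Generate a stranded WGBS methylome and AML cohort matrix
#'
#' CpG dyads receive beta-binomial methylation counts at the configured
#' coverage; planted CpGs shift the high-risk group mean beta by
#' `+/- delta_beta` (clamped into \[0, 1\] with a warning if a base value
#' would leave the range). Dyad counts are split between strands so that
#' recombining the written stranded calls reproduces the dyad counts
#' exactly. The AML cohort matrix draws from the standard-risk means (the
#' planted signature is specific to the high-risk group); missingness is
#' probe-structured as in array cohorts — a fraction `aml_missing_rate` of
#' CpG rows have missing cells in one or more AML samples, the rest are
#' complete across the cohort.
#'
#' @param config a [simulation_config()].
#' @return list: `calls` (named list of per-sample stranded call data
#'   frames), `dyads` (named list of per-sample combined dyad truth),
#'   `groups` (data frame `sample`, `group` covering discovery + AML),
#'   `cohort` (a `methylation_matrix` with discovery and AML columns),
#'   `truth` (CpG data frame with `planted`, `direction`).
#' @export
generate_methylome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  n <- config$n_cpgs
  cpg <- .place_loci(config$contigs, n, 2, 2)[, c("chrom", "start")]
  names(cpg)[2] <- "pos"
  n_planted <- min(config$n_planted_cpgs, n)
  planted <- sort(sample.int(n, n_planted))
  dir <- rep("none", n)
  dir[planted] <- rep_len(c("hypo", "hyper"), n_planted)
  d <- config$delta_beta
  base <- 0.02 + 0.96 * rbeta(n, 0.8, 0.8)
  base[dir == "hypo"] <- runif(sum(dir == "hypo"), min(d + 0.03, 0.97), 0.97)
  base[dir == "hyper"] <- runif(sum(dir == "hyper"), 0.03,
                                max(0.97 - d, 0.03))
  mu_hr <- base
  mu_hr[dir == "hypo"] <- base[dir == "hypo"] - d
  mu_hr[dir == "hyper"] <- base[dir == "hyper"] + d
  if (any(mu_hr < 0 | mu_hr > 1)) {
    warning("generate_methylome: planted beta shift clamped into [0, 1]")
    mu_hr <- pmin(1, pmax(0, mu_hr))
  }
  mu_hr <- pmin(0.995, pmax(0.005, mu_hr))
  mu_ap <- pmin(0.995, pmax(0.005, base))
  hr_samples <- sprintf("mhr%02d", seq_len(config$n_meth_hrapl))
  ap_samples <- sprintf("map%02d", seq_len(config$n_meth_apl))
  aml_samples <- sprintf("aml%03d", seq_len(config$n_aml))
  groups <- data.frame(
    sample = c(hr_samples, ap_samples, aml_samples),
    group = rep(c("hrAPL", "APL", "AML"),
                c(length(hr_samples), length(ap_samples),
                  length(aml_samples))),
    stringsAsFactors = FALSE)

  calls <- list()
  dyads <- list()
  disc_beta <- matrix(NA_real_, n, length(hr_samples) + length(ap_samples),
                      dimnames = list(paste(cpg$chrom, cpg$pos, sep = ":"),
                                      c(hr_samples, ap_samples)))
  for (s in c(hr_samples, ap_samples)) {
    mu <- if (s %in% hr_samples) mu_hr else mu_ap
    cov <- pmax(1L, rpois(n, config$coverage_mean))
    meth <- .rbetabinom(n, cov, mu, config$bb_overdispersion)
    disc_beta[, s] <- meth / cov
    cov_f <- rbinom(n, cov, 0.5)
    meth_f <- rhyper(n, m = meth, n = cov - meth, k = cov_f)
    fwd <- data.frame(chrom = cpg$chrom, pos = cpg$pos, strand = "+",
                      context = "CG", meth_count = meth_f,
                      total_count = cov_f, stringsAsFactors = FALSE)
    rev <- data.frame(chrom = cpg$chrom, pos = cpg$pos + 1, strand = "-",
                      context = "CG", meth_count = meth - meth_f,
                      total_count = cov - cov_f, stringsAsFactors = FALSE)
    cc <- rbind(fwd[fwd$total_count > 0, ], rev[rev$total_count > 0, ])
    # a sprinkling of non-CG calls, dropped by the context filter
    n_non <- round(config$noncg_frac * n)
    if (n_non > 0) {
      npos <- sample(seq_len(max(config$contigs) - 10), n_non)
      cc <- rbind(cc, data.frame(
        chrom = names(config$contigs)[1], pos = npos, strand = "+",
        context = sample(c("CHH", "CXG"), n_non, replace = TRUE),
        meth_count = 0L, total_count = pmax(1L, rpois(n_non, 10)),
        stringsAsFactors = FALSE))
    }
    cc <- cc[order(cc$chrom, cc$pos, cc$strand), ]
    rownames(cc) <- NULL
    calls[[s]] <- cc
    dy <- data.frame(chrom = cpg$chrom, pos = cpg$pos, meth_count = meth,
                     total_count = cov, beta = meth / cov,
                     stringsAsFactors = FALSE)
    dyads[[s]] <- dy
  }

  conc <- 1 / config$bb_overdispersion - 1
  aml_beta <- matrix(rbeta(n * config$n_aml,
                           rep(mu_ap, config$n_aml) * conc,
                           rep(1 - mu_ap, config$n_aml) * conc),
                     n, config$n_aml,
                     dimnames = list(rownames(disc_beta), aml_samples))
  # missingness is probe-structured, as in array cohorts: a fraction
  # aml_missing_rate of CpG rows fail in >= 1 AML sample, the rest are
  # complete, so the cohort completeness gate keeps most stringent CpGs
  n_patchy <- round(config$aml_missing_rate * n)
  patchy <- sort(sample.int(n, n_patchy))
  for (i in patchy) {
    k <- 1L + rbinom(1, config$n_aml - 1L, 0.1)
    aml_beta[i, sample.int(config$n_aml, k)] <- NA_real_
  }
  cohort_beta <- cbind(disc_beta, aml_beta)
  cohort <- structure(
    list(beta = cohort_beta,
         pos = data.frame(chrom = cpg$chrom, pos = cpg$pos,
                          stringsAsFactors = FALSE),
         groups = setNames(groups$group, groups$sample)[colnames(cohort_beta)]),
    class = "methylation_matrix")
  truth <- data.frame(chrom = cpg$chrom, pos = cpg$pos,
                      planted = dir != "none", direction = dir,
                      base_beta = mu_ap, hr_beta = mu_hr,
                      aml_complete = !(seq_len(n) %in% patchy),
                      stringsAsFactors = FALSE)
  list(calls = calls, dyads = dyads, groups = groups, cohort = cohort,
       truth = truth)
}

#' Generate a VCF exercising every branch of the filter cascade
#'
#' Builds the configured number of fully passing records plus, for each
#' cascade stage, at least one record failing only that stage (low depth, low
#' Phred, synonymous consequence, non-driver gene, common MAF, no confirming
#' track).
#'
#' @param config a [simulation_config()].
#' @return list: `variants` (data frame), `truth` (data frame with
#'   `survives` and `fails_stage`).
#' @export
generate_variants <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 3L)
  mk <- function(n, fails = "none", depth = NULL, quality = NULL,
                 consequence = "missense", driver = TRUE, maf = NULL,
                 confirm = "RNA-seq,ChIP-seq") {
    data.frame(
      depth = if (is.null(depth)) round(runif(n, 25, 80)) else rep(depth, n),
      quality = if (is.null(quality)) round(runif(n, 45, 90))
                else rep(quality, n),
      consequence = consequence,
      maf = if (is.null(maf)) round(runif(n, 0.0005, 0.04), 4)
            else rep(maf, n),
      is_driver = driver, confirmations = confirm, fails_stage = fails,
      stringsAsFactors = FALSE)
  }
  rows <- rbind(
    mk(config$n_pass_variants),
    mk(1, "quality", depth = 10),
    mk(1, "quality", quality = 30),
    mk(1, "functional", consequence = "synonymous"),
    mk(1, "functional", driver = FALSE),
    mk(1, "functional", maf = 0.2),
    mk(1, "confirmed", confirm = ""))
  # one passing record absent from the population panel (missing MAF = rare)
  rows$maf[1] <- NA_real_
  n <- nrow(rows)
  chrom <- sample(names(config$contigs), n, replace = TRUE)
  pos <- sample(seq_len(min(config$contigs) - 1), n)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         rows[, c("depth", "quality", "consequence", "maf",
                                  "is_driver", "confirmations")],
                         gene_id = sprintf("GENE%02d", seq_len(n)),
                         stringsAsFactors = FALSE)
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, ]
  rownames(variants) <- NULL
  truth <- data.frame(chrom = variants$chrom, pos = variants$pos,
                      fails_stage = rows$fails_stage[o],
                      survives = rows$fails_stage[o] == "none",
                      stringsAsFactors = FALSE)
  list(variants = variants, truth = truth)
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates peaks, counts, methylome, cohort matrix and variants, writes
#' them in the dialects the pipeline reads (BED, TSV, VCF), together with
#' truth tables and a JSON manifest echoing the configuration — everything a
#' single full-pipeline run needs.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed; must be writable).
#' @return the manifest, invisibly (list; also written as `manifest.json`).
#' @export
generate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("generate_bundle: output directory not writable: ", dir,
         call. = FALSE)
  for (sub in c("peaks", "meth", "truth"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)

  pk <- generate_peaks(config)
  for (sid in names(pk$peaks))
    for (mark in names(pk$peaks[[sid]]))
      write_bed(pk$peaks[[sid]][[mark]]$intervals,
                file.path(dir, "peaks",
                          paste0(sid, ".", sub("/", "-", mark), ".bed")))
  write.table(pk$truth, file.path(dir, "truth", "loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ct <- generate_counts(config)
  write_bed(ct$counts$regions, file.path(dir, "regions.bed"),
            name = sprintf("region%05d", seq_len(nrow(ct$counts$regions))))
  long <- data.frame(
    region_id = rep(sprintf("region%05d", seq_len(nrow(ct$counts$raw))),
                    ncol(ct$counts$raw)),
    sample = rep(colnames(ct$counts$raw), each = nrow(ct$counts$raw)),
    raw_count = as.vector(ct$counts$raw), stringsAsFactors = FALSE)
  write.table(long, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = ct$samples, group = as.character(ct$groups)),
              file.path(dir, "count_groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ct$truth, file.path(dir, "truth", "regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  me <- generate_methylome(config)
  for (s in names(me$calls))
    write.table(me$calls[[s]], file.path(dir, "meth", paste0(s, ".calls.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(me$groups, file.path(dir, "meth_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cb <- data.frame(cpg_id = rownames(me$cohort$beta), me$cohort$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cb, file.path(dir, "cohort_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  write.table(me$truth, file.path(dir, "truth", "cpgs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  va <- generate_variants(config)
  write_variants_vcf(va$variants, file.path(dir, "variants.vcf"))
  write.table(va$truth, file.path(dir, "truth", "variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    paths = list(
      peaks_dir = "peaks",
      chip_samples = names(pk$peaks),
      regions_bed = "regions.bed",
      counts_tsv = "counts.tsv",
      count_groups_tsv = "count_groups.tsv",
      meth_dir = "meth",
      meth_samples = names(me$calls),
      meth_groups_tsv = "meth_groups.tsv",
      cohort_matrix_tsv = "cohort_matrix.tsv",
      variants_vcf = "variants.vcf",
      truth_dir = "truth"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
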