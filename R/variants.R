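# Variant-reduction cascade: quality (DP/Phred) -> functional (missense,
# driver gene, population MAF) -> confirmation (independent RNA-seq/ChIP-seq
# evidence). The cascade is a pure conjunction, so the survivor set does not
# depend on stage order; the attrition table does, and reports the
# configured order quality -> functional -> confirmed.

#' Variant-filter thresholds
#'
#' Defaults are the study settings: read depth >= 20, Phred quality >= 40,
#' missense consequence in a known driver gene, population minor-allele
#' frequency <= 5% (1000 Genomes), and at least one confirming evidence
#' track. A variant absent from the frequency panel (missing MAF) is treated
#' as rare and retained.
#'
#' @param dp_min minimum read depth.
#' @param phred_min minimum Phred-scaled quality.
#' @param maf_max maximum population MAF.
#' @param require_missense require a missense consequence.
#' @param require_driver require the gene to be an annotated driver.
#' @param min_confirmations minimum number of confirming tracks.
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(dp_min = 20, phred_min = 40, maf_max = 0.05,
                              require_missense = TRUE, require_driver = TRUE,
                              min_confirmations = 1) {
  if (dp_min < 0 || phred_min < 0 || maf_max < 0 || min_confirmations < 0)
    stop("filter_thresholds: thresholds must be non-negative", call. = FALSE)
  structure(list(dp_min = dp_min, phred_min = phred_min, maf_max = maf_max,
                 require_missense = isTRUE(require_missense),
                 require_driver = isTRUE(require_driver),
                 min_confirmations = min_confirmations),
            class = "filter_thresholds")
}

.n_confirmations <- function(confirmations) {
  if (length(confirmations) == 0) return(integer(0))
  confirmations <- as.character(confirmations)
  vapply(strsplit(ifelse(is.na(confirmations), "", confirmations), ","),
         function(x) sum(nzchar(x) & x != "."), 0L)
}

#' Quality filter (read depth and Phred score)
#'
#' Retains variants with `depth >= dp_min` and `quality >= phred_min` (both
#' boundaries inclusive). Records with missing depth or quality are rejected
#' with reason "incomplete" and counted separately in the `incomplete`
#' attribute.
#'
#' @param variants variant data frame (see [read_variants()]).
#' @param thresholds a [filter_thresholds()].
#' @return surviving subset, with attribute `incomplete` (count).
#' @export
filter_quality <- function(variants, thresholds = filter_thresholds()) {
  inc <- is.na(variants$depth) | is.na(variants$quality)
  keep <- !inc & variants$depth >= thresholds$dp_min &
    variants$quality >= thresholds$phred_min
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "incomplete") <- sum(inc)
  out
}

#' Functional filter (consequence, driver gene, population MAF)
#'
#' Retains variants that are missense (when required), lie in an annotated
#' driver gene (when required), and have MAF missing or `<= maf_max`.
#'
#' @inheritParams filter_quality
#' @return surviving subset.
#' @export
filter_functional <- function(variants, thresholds = filter_thresholds()) {
  keep <- rep(TRUE, nrow(variants))
  if (thresholds$require_missense)
    keep <- keep & variants$consequence == "missense"
  if (thresholds$require_driver)
    keep <- keep & variants$is_driver
  keep <- keep & (is.na(variants$maf) | variants$maf <= thresholds$maf_max)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confirmation filter (independent evidence tracks)
#'
#' Retains variants confirmed by at least `min_confirmations` companion
#' tracks (RNA-seq and/or ChIP-seq pileup evidence, precomputed upstream).
#'
#' @inheritParams filter_quality
#' @return surviving subset.
#' @export
filter_confirmed <- function(variants, thresholds = filter_thresholds()) {
  keep <- .n_confirmations(variants$confirmations) >=
    thresholds$min_confirmations
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full variant-filter cascade
#'
#' Applies the stages in order quality -> functional -> confirmed and
#' records per-stage attrition. Because each stage is a pure per-record
#' predicate, the survivor set is independent of stage order.
#'
#' @inheritParams filter_quality
#' @return list of class `variant_cascade`: `survivors` (data frame),
#'   `attrition` (data frame `stage`, `n_in`, `n_out`, `n_dropped`),
#'   `incomplete` (count of records lacking depth/quality).
#' @export
run_cascade <- function(variants, thresholds = filter_thresholds()) {
  stages <- list(quality = filter_quality, functional = filter_functional,
                 confirmed = filter_confirmed)
  cur <- variants
  att <- data.frame(stage = character(), n_in = integer(), n_out = integer(),
                    n_dropped = integer(), stringsAsFactors = FALSE)
  incomplete <- 0L
  for (nm in names(stages)) {
    n_in <- nrow(cur)
    cur <- stages[[nm]](cur, thresholds)
    if (nm == "quality") {
      incomplete <- attr(cur, "incomplete")
      attr(cur, "incomplete") <- NULL
    }
    att <- rbind(att, data.frame(stage = nm, n_in = n_in, n_out = nrow(cur),
                                 n_dropped = n_in - nrow(cur),
                                 stringsAsFactors = FALSE))
  }
  attr(cur, "incomplete") <- NULL
  structure(list(survivors = cur, attrition = att, incomplete = incomplete),
            class = "variant_cascade")
}

#' @export
print.variant_cascade <- function(x, ...) {
  cat("variant_cascade:", x$attrition$n_in[1], "->",
      nrow(x$survivors), "variants\n")
  print(x$attrition, row.names = FALSE)
  invisible(x)
}

# ---- VCF I/O ----------------------------------------------------------------

#' Read variants from a VCF file
#'
#' Reads a VCF v4.x file (via `vcfR`) into the flat variant table the cascade
#' consumes. DP is taken from the INFO `DP` key, quality from QUAL;
#' consequence, MAF, gene, driver status and confirming tracks come from the
#' INFO keys `CSQ_CLASS`, `MAF`, `GENE`, `DRIVER` (0/1) and `CONFIRM`
#' (comma-separated track names, or `.`).
#'
#' @param path VCF path.
#' @return data frame: `chrom`, `pos` (1-based, as in the VCF), `ref`, `alt`,
#'   `depth`, `quality`, `consequence`, `maf`, `gene_id`, `is_driver`,
#'   `confirmations`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info1 <- function(key) suppressWarnings(vcfR::extract.info(v, key))
  maf <- suppressWarnings(as.numeric(info1("MAF")))
  data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             depth = suppressWarnings(as.numeric(info1("DP"))),
             quality = suppressWarnings(as.numeric(fix[, "QUAL"])),
             consequence = info1("CSQ_CLASS"),
             maf = maf,
             gene_id = info1("GENE"),
             is_driver = !is.na(info1("DRIVER")) & info1("DRIVER") == "1",
             confirmations = info1("CONFIRM"),
             stringsAsFactors = FALSE)
}

#' Write a variant table as VCF
#'
#' Emits a minimal plain-text VCF v4.2 with the INFO keys [read_variants()]
#' reads back.
#'
#' @param variants variant data frame.
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"1000G minor allele frequency\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=DRIVER,Number=1,Type=Integer,Description=\"Driver gene flag\">",
    "##INFO=<ID=CONFIRM,Number=.,Type=String,Description=\"Confirming evidence tracks\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- paste0(
    "DP=", ifelse(is.na(variants$depth), ".", variants$depth),
    ";CSQ_CLASS=", variants$consequence,
    ifelse(is.na(variants$maf), "", paste0(";MAF=", variants$maf)),
    ";GENE=", variants$gene_id,
    ";DRIVER=", as.integer(variants$is_driver),
    ";CONFIRM=", ifelse(is.na(variants$confirmations) |
                          !nzchar(variants$confirmations), ".",
                        variants$confirmations))
  body <- paste(variants$chrom, format(variants$pos, scientific = FALSE,
                                       trim = TRUE),
                ".", variants$ref, variants$alt,
                ifelse(is.na(variants$quality), ".", variants$quality),
                "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the cascade attrition table
#'
#' @param cascade a [run_cascade()] result.
#' @param path output TSV path.
#' @export
write_attrition <- function(cascade, path) {
  write.table(cascade$attrition, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
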