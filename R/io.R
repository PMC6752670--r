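# Plain-text interchange: TSV site/cohort tables, CSV droplet tables, a
# minimal sites-only VCF for confirmed calls, and JSON run manifests.

#' Write / read a pileup site table (TSV)
#'
#' Columns: `site_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `ref_count`, `alt_count`, `error_rate`, and `true_maf` when the table
#' comes from the simulator.
#'
#' @param sites Site data frame.
#' @param path Output file.
#' @return `path`, invisibly (writer); the data frame (reader).
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a droplet count table (CSV)
#'
#' Columns: `sample_id`, `tissue`, `mu`, `wt`, `na`.
#'
#' @param droplets Droplet-count data frame.
#' @param path Output file.
#' @return `path`, invisibly (writer); the data frame (reader).
#' @export
write_droplet_table <- function(droplets, path) {
  utils::write.csv(droplets, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_droplet_table
#' @export
read_droplet_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a cohort table (TSV)
#'
#' @param cohort Cohort data frame (`subject_id`, `sex`, status columns).
#' @param path Output file.
#' @return `path`, invisibly (writer); the data frame (reader).
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write confirmed calls as a minimal VCF
#'
#' Sites-only VCFv4.2 with the MAF estimate in INFO (`MAF`,
#' `MAF_CI95_LO`, `MAF_CI95_HI`, `CALL`, `SUBJECT`). Coordinates are
#' 1-based as in the site tables.
#'
#' @param calls Data frame with `chrom`, `pos`, `ref`, `alt`, `map_maf`,
#'   `ci_low`, `ci_high`, `call`, `subject_id`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaicfrac",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"MAP mutant allelic fraction\">",
    "##INFO=<ID=MAF_CI95_LO,Number=1,Type=Float,Description=\"Lower 95 interval bound\">",
    "##INFO=<ID=MAF_CI95_HI,Number=1,Type=Float,Description=\"Upper 95 interval bound\">",
    "##INFO=<ID=CALL,Number=1,Type=String,Description=\"Pipeline call label\">",
    "##INFO=<ID=SUBJECT,Number=1,Type=String,Description=\"Subject identifier\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- if (nrow(calls) == 0) character() else sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tMAF=%.6g;MAF_CI95_LO=%.6g;MAF_CI95_HI=%.6g;CALL=%s;SUBJECT=%s",
    calls$chrom, calls$pos, calls$ref, calls$alt, calls$map_maf,
    calls$ci_low, calls$ci_high, calls$call, calls$subject_id)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a reproducibility manifest (JSON)
#'
#' Records the configuration, seed and package version of a run so it can
#' be regenerated byte-identically.
#'
#' @param config Run configuration (list).
#' @param seed Seed used.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  drop_fn <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) return(lapply(x, drop_fn))
    x
  }
  payload <- list(
    package = "mosaicfrac",
    version = as.character(utils::packageVersion("mosaicfrac")),
    seed = seed,
    config = drop_fn(unclass(config))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
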