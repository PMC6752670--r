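# End-to-end orchestration: screen every subject's site, route candidate
# mosaics to the appropriate validation assay (hotspot variants have
# pre-designed TaqMan ddPCR assays; everything else goes to amplicon
# validation), quantify, and aggregate confirmed mosaics into the
# sex-stratified contingency analysis.

#' Recurrent MECP2 hotspot variants with pre-designed genotyping assays
#'
#' The ten recurrent MECP2 sites used as the default hotspot list for
#' validation routing: the eight classic C>T transition hotspots plus the
#' two further recurrent sites quantified in the cohort. Identifiers are
#' `"GENE:c.change"`; the list is a plain character vector and fully
#' configurable.
#'
#' @return Character vector of variant identifiers.
#' @export
mecp2_hotspots <- function() {
  paste0("MECP2:", c(
    "c.316C>T",  # p.Arg106Trp
    "c.317G>A",  # p.Arg106Gln
    "c.397C>T",  # p.Arg133Cys
    "c.473C>T",  # p.Thr158Met
    "c.502C>T",  # p.Arg168Ter
    "c.763C>T",  # p.Arg255Ter
    "c.806delG", # p.Gly269fs
    "c.808C>T",  # p.Arg270Ter
    "c.880C>T",  # p.Arg294Ter
    "c.916C>T"   # p.Arg306Cys
  ))
}

# Small synthetic variant catalog (positions are placeholders on the
# MECP2 locus) used to assign a variant identity to simulated subjects.
variant_catalog <- function() {
  data.frame(
    variant_id = c("MECP2:c.316C>T", "MECP2:c.502C>T", "MECP2:c.880C>T",
                   "MECP2:c.419C>T", "MECP2:c.455C>G", "MECP2:c.674C>T"),
    chrom = "X",
    pos = c(153296689L, 153296363L, 153296070L,
            153296586L, 153296550L, 153296331L),
    ref = c("G", "G", "G", "G", "G", "G"),
    alt = c("A", "A", "A", "A", "C", "A"),
    stringsAsFactors = FALSE
  )
}

#' Route a candidate mosaic variant to its validation assay
#'
#' Hotspot variants have pre-designed droplet digital PCR genotyping
#' assays and are routed to `"ddpcr"`; non-hotspot variants are routed to
#' amplicon validation (`"pasm"`). An unknown or missing identifier falls
#' back to `"pasm"` with a warning. `both = TRUE` requests both assays
#' (some variants in the study were validated by both).
#'
#' @param label Screening label of the site; must be
#'   `"mosaic_candidate"`.
#' @param variant_id Variant identifier (`"GENE:c.change"`).
#' @param hotspots Character vector of hotspot identifiers.
#' @param both Request both validation assays.
#' @return Character vector of assay names (`"ddpcr"`, `"pasm"`).
#' @export
route_candidate <- function(label, variant_id,
                            hotspots = mecp2_hotspots(), both = FALSE) {
  stopifnot(identical(label, "mosaic_candidate"))
  if (isTRUE(both)) {
    return(c("ddpcr", "pasm"))
  }
  if (is.na(variant_id) || !nzchar(variant_id)) {
    warning("unknown variant identifier; routed to amplicon validation",
            call. = FALSE)
    return("pasm")
  }
  if (variant_id %in% hotspots) "ddpcr" else "pasm"
}

#' Pipeline configuration
#'
#' Bundles the cohort simulation settings, the assay parameters of the
#' three quantification stages, and the decision thresholds, all at the
#' study defaults: panel screening at ~1000x from ~3000 input copies with
#' per-base error 1e-3; amplicon validation at ~12,000x from ~6000
#' copies; ddPCR with 5e4 template molecules in 5e5 droplets.
#'
#' @param n_male,n_female,rate_male,rate_female,maf_distribution,exact_counts
#'   Cohort settings, see [cohort_sim_config()].
#' @param depth,input_copies,error_rate Panel screening assay.
#' @param amplicon_depth,amplicon_copies,n_controls Amplicon validation
#'   assay (controls are variant-free sites used to fit the error model).
#' @param ddpcr_copies,ddpcr_droplets ddPCR assay.
#' @param screen_thr,pasm_thr Decision thresholds.
#' @param hotspots Hotspot list for routing.
#' @param require_both If `TRUE`, confirmation requires every attempted
#'   validation assay to confirm, instead of at least one.
#' @param validate_both Run both assays on every candidate.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_male = 18, n_female = 453,
                            rate_male = 3 / 18, rate_female = 2 / 453,
                            maf_distribution = list(name = "uniform",
                                                    min = 0.065,
                                                    max = 0.38),
                            exact_counts = FALSE,
                            depth = 1000, input_copies = 3000,
                            error_rate = 1e-3,
                            amplicon_depth = 12000,
                            amplicon_copies = 6000, n_controls = 10,
                            ddpcr_copies = 5e4, ddpcr_droplets = 5e5,
                            screen_thr = screen_thresholds(),
                            pasm_thr = pasm_thresholds(),
                            hotspots = mecp2_hotspots(),
                            require_both = FALSE, validate_both = FALSE,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

validate_one <- function(assay, true_maf, config, error_model) {
  if (assay == "pasm") {
    amp <- simulate_amplicon(sim_config(
      true_maf = true_maf, depth = config$amplicon_depth,
      input_copies = config$amplicon_copies,
      error_rate = config$error_rate))
    pasm_maf(amp$alt_count, amp$ref_count + amp$alt_count, error_model)
  } else {
    d <- simulate_droplets(droplet_sim_config(
      true_maf = true_maf, total_copies = config$ddpcr_copies,
      n_droplets = config$ddpcr_droplets))
    maf_from_droplets(d)
  }
}

#' Run the full mosaicism pipeline on a synthetic cohort
#'
#' End-to-end analysis: simulate the cohort and each subject's deep-panel
#' site, screen every site with the Bayesian genotyper, route candidate
#' mosaics to validation (hotspot variants to ddPCR, others to amplicon
#' validation, with a shared error model fitted once from simulated
#' negative-control amplicon sites), confirm candidates whose validation
#' estimate clears the thresholds, and aggregate confirmed calls into the
#' sex-stratified 2x2 table with exact Fisher/odds-ratio statistics.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, the per-subject table
#'   (TSV), confirmed-call VCF, cohort report (JSON) and reproducibility
#'   manifest are written there.
#' @return A `pipeline_report` list: `subjects` (per-subject data frame),
#'   `table` (confirmed-by-sex [contingency_table()]), `fisher_p`, `or`
#'   (one-sided [odds_ratio_exact()] result), `or_two_sided`, `rates`
#'   (overall/male/female [rate_summary()]s), `confirmed_vcf` (data
#'   frame), `degenerate` flag, `config`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  with_seed(config$seed, {
    cohort <- simulate_cohort(cohort_sim_config(
      n_male = config$n_male, n_female = config$n_female,
      rate_male = config$rate_male, rate_female = config$rate_female,
      maf_distribution = config$maf_distribution,
      exact_counts = config$exact_counts))
    n <- nrow(cohort)
    catalog <- variant_catalog()
    # mosaic subjects cycle through the catalog; everyone else carries a
    # non-hotspot site (their site is reference-homozygous anyway)
    vidx <- rep(4L, n)
    if (any(cohort$is_mosaic)) {
      vidx[cohort$is_mosaic] <-
        (seq_len(sum(cohort$is_mosaic)) - 1L) %% nrow(catalog) + 1L
    }
    cohort$variant_id <- catalog$variant_id[vidx]

    # one shared error model for the amplicon stage, from control sites
    controls <- simulate_pileup(sim_config(
      true_maf = 0, depth = config$amplicon_depth,
      input_copies = config$amplicon_copies,
      error_rate = config$error_rate, n_sites = config$n_controls))
    error_model <- fit_error_model(controls)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      site <- simulate_pileup(sim_config(
        true_maf = cohort$true_maf[i], depth = config$depth,
        input_copies = config$input_copies,
        error_rate = config$error_rate))
      post <- maf_posterior(site$alt_count,
                            site$ref_count + site$alt_count,
                            error_rate = config$error_rate)
      call <- classify_site(post, config$screen_thr,
                            site_id = cohort$subject_id[i])
      row <- data.frame(
        subject_id = cohort$subject_id[i], sex = cohort$sex[i],
        is_mosaic = cohort$is_mosaic[i], true_maf = cohort$true_maf[i],
        variant_id = cohort$variant_id[i],
        screen_label = call$label, screen_maf = call$map_maf,
        screen_ci_low = call$ci_low, screen_ci_high = call$ci_high,
        route = NA_character_, validation = NA_character_,
        final_maf = NA_real_, final_ci_low = NA_real_,
        final_ci_high = NA_real_, provenance = NA_character_,
        confirmed = FALSE, stringsAsFactors = FALSE)
      if (call$label == "mosaic_candidate") {
        plan <- route_candidate("mosaic_candidate",
                                cohort$variant_id[i],
                                hotspots = config$hotspots,
                                both = config$validate_both)
        verdicts <- character(0)
        best <- NULL
        for (assay in plan) {
          est <- validate_one(assay, cohort$true_maf[i], config,
                              error_model)
          v <- validate_candidate(est, config$pasm_thr)
          verdicts[assay] <- v
          if (v == "mosaic_confirmed" &&
              (is.null(best) || est$ci_high - est$ci_low <
                 best$ci_high - best$ci_low)) {
            best <- est
          }
        }
        confirmed <- if (config$require_both) {
          all(verdicts == "mosaic_confirmed")
        } else {
          any(verdicts == "mosaic_confirmed")
        }
        row$route <- paste(plan, collapse = "+")
        row$validation <- paste(sprintf("%s:%s", names(verdicts),
                                        verdicts), collapse = ";")
        row$confirmed <- confirmed
        if (confirmed) {
          row$final_maf <- best$map_maf
          row$final_ci_low <- best$ci_low
          row$final_ci_high <- best$ci_high
          row$provenance <- best$method
        }
      }
      rows[[i]] <- row
    }
    subjects <- do.call(rbind, rows)

    degenerate <- sum(subjects$confirmed) == 0 ||
      sum(subjects$confirmed) == nrow(subjects)
    tab <- as_contingency(subjects, status_col = "confirmed")
    or1 <- suppressWarnings(odds_ratio_exact(tab, sides = 1))
    or2 <- suppressWarnings(odds_ratio_exact(tab, sides = 2))

    conf <- subjects[subjects$confirmed, , drop = FALSE]
    cidx <- match(conf$variant_id, catalog$variant_id)
    confirmed_vcf <- data.frame(
      chrom = catalog$chrom[cidx], pos = catalog$pos[cidx],
      ref = catalog$ref[cidx], alt = catalog$alt[cidx],
      map_maf = conf$final_maf, ci_low = conf$final_ci_low,
      ci_high = conf$final_ci_high,
      call = rep("mosaic_confirmed", nrow(conf)),
      subject_id = conf$subject_id, stringsAsFactors = FALSE)

    report <- structure(list(
      subjects = subjects, table = tab,
      fisher_p = or1$p_two_sided, or = or1, or_two_sided = or2,
      rates = list(
        overall = rate_summary(sum(subjects$confirmed), n),
        male = rate_summary(tab$a, tab$a + tab$b),
        female = rate_summary(tab$c, tab$c + tab$d)),
      confirmed_vcf = confirmed_vcf, degenerate = degenerate,
      config = config), class = "pipeline_report")

    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_cohort_table(subjects, file.path(outdir, "subjects.tsv"))
      write_calls_vcf(confirmed_vcf,
                      file.path(outdir, "confirmed_calls.vcf"))
      jsonlite::write_json(
        list(table = unclass(tab), fisher_p = report$fisher_p,
             or_cmle = or1$or_cmle, or_ci_low = or1$ci_low,
             or_ci_high_two_sided = or2$ci_high,
             degenerate = degenerate),
        file.path(outdir, "cohort_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_manifest(config, config$seed,
                     file.path(outdir, "manifest.json"))
    }
    report
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "pipeline report: %d subjects, %d confirmed mosaic\n",
    nrow(x$subjects), sum(x$subjects$confirmed)))
  cat(sprintf("2x2 (mosaic/non-mosaic): males %d/%d, females %d/%d\n",
              x$table$a, x$table$b, x$table$c, x$table$d))
  if (x$degenerate) {
    cat("note: degenerate contingency margin; exact test uninformative\n")
  }
  print(x$or)
  invisible(x)
}

#' Generate a self-contained fixture bundle
#'
#' Writes the input files (site tables, droplet CSVs, cohort TSV and a
#' JSON manifest) for a named scenario, so tests and examples run from
#' plain-text inputs. Identical scenario + seed gives byte-identical
#' bundles.
#'
#' @param scenario One of `"study_cohort"` (sex-stratified cohort whose
#'   truth table is exactly 3/15 mosaic males and 2/451 mosaic females),
#'   `"negative"` (no mosaics), `"tissue_germline_only"`,
#'   `"tissue_early_embryonic"` (multi-tissue ddPCR panels).
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
generate_fixtures <- function(scenario = c("study_cohort", "negative",
                                           "tissue_germline_only",
                                           "tissue_early_embryonic"),
                              seed = 1, outdir) {
  scenario <- match.arg(scenario)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)
  with_seed(seed, {
    if (scenario %in% c("study_cohort", "negative")) {
      cfg <- if (scenario == "study_cohort") {
        cohort_sim_config(exact_counts = TRUE)
      } else {
        cohort_sim_config(rate_male = 0, rate_female = 0)
      }
      cohort <- simulate_cohort(cfg)
      add(write_cohort_table(cohort, file.path(outdir, "cohort.tsv")))
      sites <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
        s <- simulate_pileup(sim_config(true_maf = cohort$true_maf[i]))
        s$site_id <- cohort$subject_id[i]
        s
      }))
      add(write_site_table(sites, file.path(outdir, "sites.tsv")))
      mos <- cohort[cohort$is_mosaic, , drop = FALSE]
      droplets <- do.call(rbind, c(list(
        data.frame(sample_id = character(), tissue = character(),
                   mu = numeric(), wt = numeric(), na = numeric(),
                   stringsAsFactors = FALSE)),
        lapply(seq_len(nrow(mos)), function(i) {
          d <- simulate_droplets(droplet_sim_config(mos$true_maf[i]))
          data.frame(sample_id = mos$subject_id[i], tissue = "blood",
                     mu = d$mu, wt = d$wt, na = d$na,
                     stringsAsFactors = FALSE)
        })))
      add(write_droplet_table(droplets,
                              file.path(outdir, "droplets.csv")))
      add(write_manifest(cfg, seed, file.path(outdir, "manifest.json")))
    } else {
      sc <- sub("^tissue_", "", scenario)
      panel <- simulate_tissue_panel(sc)
      add(write_droplet_table(panel,
                              file.path(outdir, "droplets.csv")))
      add(write_manifest(list(scenario = sc), seed,
                         file.path(outdir, "manifest.json")))
    }
  })
  invisible(paths)
}
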