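#' Read a pipeline run configuration
#'
#' YAML with fields: `paths` (genotypes, phenotypes, localities, assays,
#' spectra — all but genotypes optional), `seed`, `chain` (iterations,
#' burn_in, thin), `thresholds` (null_allele, strong_verdict, alpha,
#' hwe_alpha), `n_perm`, `bottleneck` (logical), `out_dir`.
#'
#' @param path YAML file path.
#' @return A `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a plain list with the same fields.
#' @export
as_run_config <- function(cfg) {
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$n_perm <- cfg$n_perm %||% 1000
  cfg$bottleneck <- isTRUE(cfg$bottleneck)
  cfg$chain <- utils::modifyList(
    list(iterations = 65000, burn_in = 15000, thin = 50), cfg$chain %||% list())
  cfg$thresholds <- utils::modifyList(
    list(null_allele = 0.15, strong_verdict = 0.125, alpha = 0.05,
         hwe_alpha = 0.05), cfg$thresholds %||% list())
  cfg$out_dir <- cfg$out_dir %||% "pipeline_out"
  class(cfg) <- "run_config"
  cfg
}

## one structured line per stage; wall time goes to the log message only so
## that the JSON report stays byte-identical across reruns
stage_log <- function(.report, .stage, .t0, ...) {
  info <- list(...)
  message(sprintf("[%s] %.2fs %s", .stage, as.numeric(Sys.time()) - .t0,
                  paste(names(info), unlist(info), sep = "=", collapse = " ")))
  .report$stages[[.stage]] <- c(list(stage = .stage), info)
  .report
}

#' Run the full analysis pipeline
#'
#' Sequences the study replica end-to-end: locus QC (Hardy-Weinberg
#' screening with Bonferroni correction across loci, null-allele screening,
#' with an exclusion log accounting for every input locus), per-population
#' diversity summary, global/pairwise theta and AMOVA, isolation-by-
#' distance Mantel test (skipped with a warning when no locality table is
#' configured), spectral brightness and behavioral scoring, region
#' comparisons and latitude regressions, and the Pst-Fst table. Every
#' stochastic stage derives its seed from the config seed, so identical
#' configurations give identical outputs. Tables are written as TSV and the
#' whole bundle as one JSON report carrying the config.
#'
#' @param config a `run_config` (from [read_run_config()] / [as_run_config()]).
#' @return The report bundle (list), invisibly written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else as_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(cfg), stages = list())
  t0 <- as.numeric(Sys.time())

  ds <- read_genepop(cfg$paths$genotypes)
  if (!is.null(cfg$regions)) {
    ds$ind$region <- unname(unlist(cfg$regions)[ds$ind$pop])
    ds <- microsat_dataset(ds$ind, ds$loci, ds$a1, ds$a2)
  }
  report <- stage_log(report, "read_genotypes", t0,
                      individuals = nrow(ds$ind), loci = length(ds$loci))

  ## ---- locus QC: HWE (Bonferroni across loci) + null alleles ----
  pops <- populations(ds)
  hwe_p <- sapply(ds$loci, function(l) {
    min(vapply(pops, function(p) {
      hwe_test(ds, p, l, n_perm = cfg$n_perm,
               seed = derive_seed(cfg$seed, paste0("hwe", p, l)))$p
    }, 0))
  })
  hwe_fail <- hwe_p * length(ds$loci) < cfg$thresholds$hwe_alpha
  nulls <- null_allele_screen(ds, cfg$thresholds$null_allele)
  excl <- data.frame(locus = ds$loci,
                     hwe_min_p = unname(hwe_p),
                     hwe_excluded = unname(hwe_fail),
                     null_allele_r = nulls$null_allele_r,
                     null_excluded = nulls$flagged,
                     excluded = unname(hwe_fail) | nulls$flagged)
  keep_loci <- ds$loci[!excl$excluded]
  if (length(keep_loci) < 2) stop("stage locus_qc: fewer than 2 loci survive QC")
  ds_qc <- subset_dataset(ds, loci = keep_loci)
  write.table(excl, file.path(cfg$out_dir, "locus_qc.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  report$locus_qc <- excl
  report <- stage_log(report, "locus_qc", t0, excluded = sum(excl$excluded))

  ## ---- per-population diversity summary ----
  div <- diversity_summary(ds_qc, bottleneck = cfg$bottleneck,
                           seed = derive_seed(cfg$seed, "div"))
  write.table(div, file.path(cfg$out_dir, "diversity.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  report$diversity <- div
  report <- stage_log(report, "diversity", t0, populations = nrow(div))

  ## ---- differentiation: theta, pairwise, AMOVA ----
  fst <- weir_cockerham_theta(ds_qc, pairwise = TRUE, n_perm = cfg$n_perm,
                              seed = derive_seed(cfg$seed, "fst"))
  males <- tryCatch(subset_dataset(ds_qc, sex = "M"), error = function(e) NULL)
  fst_m <- if (!is.null(males) && nrow(males$ind) > 0 &&
               length(populations(males)) >= 2) {
    tryCatch(weir_cockerham_theta(males, n_boot = 1000, n_perm = 0,
                                  seed = derive_seed(cfg$seed, "fstM")),
             error = function(e) NULL)
  } else NULL
  am <- amova(ds_qc, n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, "amova"))
  write.table(fst$per_locus, file.path(cfg$out_dir, "fst_per_locus.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(as.data.frame(fst$pairwise),
              file.path(cfg$out_dir, "fst_pairwise.tsv"), sep = "\t",
              quote = FALSE)
  write.table(am$components, file.path(cfg$out_dir, "amova.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  report$fst <- list(theta = fst$theta, ci = fst$ci,
                     male_theta = fst_m$theta %||% NA,
                     male_ci = fst_m$ci %||% c(NA, NA))
  report$amova <- list(components = am$components, phi = as.list(am$phi),
                       p = as.list(am$p))
  report <- stage_log(report, "differentiation", t0,
                      theta = signif(fst$theta, 4))

  ## ---- IBD Mantel ----
  if (!is.null(cfg$paths$localities) && file.exists(cfg$paths$localities)) {
    loc <- read_table(cfg$paths$localities, "locality")
    map <- cfg$pop_to_locality
    map <- if (is.null(map)) setNames(intersect(pops, loc$name),
                                      intersect(pops, loc$name))
           else setNames(unlist(map), names(map))
    geo <- distance_matrix(loc, map[names(map) %in% rownames(fst$pairwise)])
    common <- intersect(rownames(geo), rownames(fst$pairwise))
    mt <- mantel(pairwise_matrix(unclass(geo)[common, common]),
                 pairwise_matrix(fst$pairwise[common, common]),
                 n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, "mantel"))
    report$ibd <- list(Z = mt$Z, r = mt$r, p = mt$p)
    report <- stage_log(report, "ibd", t0, r = signif(mt$r, 3))
  } else {
    warning("no locality table configured: IBD stage skipped")
    report <- stage_log(report, "ibd", t0, skipped = TRUE)
  }

  ## ---- trait assembly ----
  phen <- NULL
  if (!is.null(cfg$paths$phenotypes) && file.exists(cfg$paths$phenotypes)) {
    phen <- read_table(cfg$paths$phenotypes, "phenotype")
  }
  if (!is.null(cfg$paths$spectra) && file.exists(cfg$paths$spectra)) {
    spec <- read_table(cfg$paths$spectra, "spectrum")
    bright <- brightness_phenotypes(spec)
    phen <- if (is.null(phen)) bright else {
      out <- rbind(as.data.frame(phen), as.data.frame(bright))
      class(out) <- class(bright); out
    }
  }
  if (!is.null(cfg$paths$assays) && file.exists(cfg$paths$assays)) {
    logs <- read_table(cfg$paths$assays, "assay")
    sc <- exploration_score(logs)
    beh <- data.frame(individual = rep(sc$bird, 2),
                      population = rep(sc$population, 2),
                      region = "R1", sex = "M", year = 2015,
                      trait = rep(c("exploration", "neophobia"),
                                  each = nrow(sc)),
                      value = c(sc$exploration, sc$neophobia))
    report$behavior <- sc
    phen <- if (is.null(phen)) validate_phenotypes(beh) else {
      out <- rbind(as.data.frame(phen), beh)
      class(out) <- c("phenotype_table", "data.frame"); out
    }
  }

  if (!is.null(phen)) {
    traits <- unique(phen$trait)
    ## region comparisons + latitude regressions
    comps <- lapply(traits, function(tr) {
      tryCatch(compare_regions(phen, tr, alpha = cfg$thresholds$alpha),
               error = function(e) NULL)
    })
    comps <- Filter(Negate(is.null), comps)
    comp_tab <- do.call(rbind, lapply(comps, function(cm) {
      data.frame(trait = cm$trait, test = as.character(cm$test),
                 statistic = cm$statistic, p = cm$p, p_adj = cm$p_adj,
                 letters = paste(names(cm$letters), cm$letters,
                                 sep = ":", collapse = " "))
    }))
    if (!is.null(comp_tab)) {
      write.table(comp_tab, file.path(cfg$out_dir, "region_comparisons.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      report$region_comparisons <- comp_tab
    }
    report <- stage_log(report, "trait_comparisons", t0,
                        traits = length(traits))

    ## ---- Pst-Fst (genotyped subset only) ----
    sub <- phen[phen$individual %in% ds_qc$ind$id, ]
    if (nrow(sub) && length(unique(sub$population)) >= 3 &&
        !is.na(fst$ci[2])) {
      tab3 <- pst_fst_table(
        sub, fst_upper = fst$ci[2],
        fst_upper_male = if (!is.null(fst_m)) fst_m$ci[2] else fst$ci[2],
        strong_threshold = cfg$thresholds$strong_verdict,
        iterations = cfg$chain$iterations, burn_in = cfg$chain$burn_in,
        thin = cfg$chain$thin, seed = derive_seed(cfg$seed, "pst"))
      write.table(tab3, file.path(cfg$out_dir, "pst_fst.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      report$pst_fst <- tab3
      report <- stage_log(report, "pst_fst", t0, traits = nrow(tab3))
    } else {
      report <- stage_log(report, "pst_fst", t0, skipped = TRUE)
    }
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
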