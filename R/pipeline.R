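#' Run the full polycross genomic-selection pipeline
#'
#' Orchestrates simulate -> QC -> relationship matrices -> pedigree
#' reconstruction -> model fits -> selection report as one reproducible run.
#' The configuration is a list (or a YAML file) with elements:
#' \describe{
#'   \item{sim}{arguments for [sim_config()] (the trial is simulated).}
#'   \item{traits}{list of [trait_config()] argument lists.}
#'   \item{thresholds}{optional [threshold_config()] arguments.}
#'   \item{models}{subset of `ablup_px`, `ablup_fs_a`, `ablup_fs_ad`,
#'     `gblup_a`, `gblup_ad` (default `gblup_a`).}
#'   \item{selection_fraction}{top fraction selected (default 0.05).}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{integer seed; recorded in the manifest.}
#' }
#' All stage outputs are written as plain text (CSV/TSV/VCF/JSON) and listed
#' with checksums in `manifest.json`; a rerun with the same configuration and
#' seed reproduces every file bit-for-bit.
#'
#' @param config list or path to a YAML file.
#' @return the manifest (invisibly also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  known_models <- c("ablup_px", "ablup_fs_a", "ablup_fs_ad", "gblup_a",
                    "gblup_ad")
  models <- if (is.null(config$models)) "gblup_a" else config$models
  if (!all(models %in% known_models))
    stop("unknown model name(s): ",
         paste(setdiff(models, known_models), collapse = ", "))
  if (is.null(config$traits) || !length(config$traits))
    stop("config$traits must list at least one trait")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }
  write_csv <- function(obj, path) utils::write.csv(obj, path, row.names = FALSE)

  ## stage 1: simulate the trial
  sim_args <- config$sim
  sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)
  founders <- simulate_founders(cfg)
  cross <- simulate_polycross(founders, cfg)
  design <- make_design(rownames(cross$dosage), cfg)
  traits <- lapply(config$traits, function(a) do.call(trait_config, a))
  sim_ph <- simulate_phenotypes(cross$dosage, design, traits, cfg)
  pheno <- sim_ph$phenotypes
  pheno <- cbind(id = design$id, pheno[setdiff(names(pheno), "id")])
  emit(pheno, "phenotypes.csv", write_csv)
  emit(cross$truth$recorded_pedigree, "recorded_pedigree.csv", write_csv)
  all_dosage <- rbind(founders$dosage, cross$dosage)
  emit(all_dosage, "genotypes.tsv", function(o, p) write_dosage(o, p))

  ## stage 2: QC + genomic relationship matrices
  filt <- filter_snps(all_dosage)
  imp <- impute_missing(filt$dosage)
  G <- G_additive(imp)
  emit(G, "G_additive.tsv", function(o, p) write_relmat(o, p))
  Gd <- if (any(c("gblup_ad") %in% models)) G_dominance(imp) else NULL

  ## stage 3: pedigree reconstruction
  th <- do.call(threshold_config,
                if (is.null(config$thresholds)) list() else config$thresholds)
  female_ids <- intersect(founders$female_ids, rownames(G))
  male_ids <- intersect(founders$male_ids, rownames(G))
  recon <- reconstruct_pedigree(G, cross$truth$recorded_pedigree,
                                female_ids, male_ids, th)
  emit(recon$maternity, "maternity.csv", write_csv)
  emit(recon$paternity, "paternity.csv", write_csv)
  emit(recon$pedigree, "corrected_pedigree.csv", write_csv)
  emit(recon$contribution_test[c("chi2", "df", "p_value", "expected_count")],
       "contribution_test.json",
       function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))

  ## pedigree kernels
  px_ped <- rbind(
    data.frame(id = setdiff(unique(cross$truth$recorded_pedigree$mother), NA),
               mother = NA_character_, father = NA_character_),
    data.frame(id = cross$truth$recorded_pedigree$id,
               mother = cross$truth$recorded_pedigree$mother,
               father = NA_character_))
  A_px <- if ("ablup_px" %in% models) A_additive(px_ped) else NULL
  A_fs <- if (any(c("ablup_fs_a", "ablup_fs_ad") %in% models))
    A_additive(recon$pedigree) else NULL
  Ad_fs <- if ("ablup_fs_ad" %in% models) A_dominance(recon$pedigree) else NULL

  ## stage 4: model fits per trait
  multi_site <- cfg$n_sites > 1L
  base_random <- c("rep_in_site", "set_in_rep", "additive",
                   if (multi_site) "site_x_additive")
  fit_one <- function(model, tc) {
    kernels <- switch(model,
      ablup_px = list(a = A_px, d = NULL),
      ablup_fs_a = list(a = A_fs, d = NULL),
      ablup_fs_ad = list(a = A_fs, d = Ad_fs),
      gblup_a = list(a = G, d = NULL),
      gblup_ad = list(a = G, d = Gd))
    random <- base_random
    if (!is.null(kernels$d))
      random <- c(random, "dominance", if (multi_site) "site_x_dominance")
    fit_treemodel(pheno, tc$name, kernels$a, kernels$d, random = random,
                  covariates = names(tc$covariate_effects),
                  lognormal = tc$lognormal)
  }
  frac <- if (is.null(config$selection_fraction)) 0.05
  else config$selection_fraction
  comparison <- NULL
  reports <- list()
  for (tc in traits) {
    fits <- lapply(models, fit_one, tc = tc)
    names(fits) <- models
    for (model in models) {
      f <- fits[[model]]
      bv <- breeding_values(f)
      emit(bv, sprintf("blup_%s_%s.csv", tc$name, model), write_csv)
      h2 <- heritability(f)
      rb <- if (multi_site) typeB_correlation(f)
      else list(estimate = NA, se = NA)
      comparison <- rbind(comparison, data.frame(
        trait = tc$name, model = model, logLik = f$loglik, AIC = f$aic,
        sigma2_a = unname(varcomp(f)["additive"]),
        h2 = h2$estimate, h2_se = h2$se,
        rB = rb$estimate, converged = f$converged))
    }
    ## selection vs the genomic reference when available
    ref_model <- if ("gblup_a" %in% models) "gblup_a" else models[1]
    ref_bv <- breeding_values(fits[[ref_model]])
    off_ids <- rownames(cross$dosage)
    pop_mean <- mean(if (tc$lognormal) log(pheno[[tc$name]])
                     else pheno[[tc$name]])
    ref_sel <- select_top(ref_bv[ref_bv$id %in% off_ids, ], frac)
    for (model in models) {
      bv <- breeding_values(fits[[model]])
      bv <- bv[bv$id %in% off_ids, ]
      rep_ <- selection_report(
        bv, rel = A_fs %||% G, population_mean = pop_mean, fraction = frac,
        model_label = model,
        reference = if (model != ref_model)
          list(bvs = stats::setNames(ref_bv$value, ref_bv$id)[bv$id],
               selected = ref_sel))
      reports[[paste(tc$name, model, sep = "_")]] <-
        rep_[setdiff(names(rep_), "selected_ids")]
    }
  }
  emit(comparison, "model_comparison.csv", write_csv)
  emit(reports, "selection_report.json",
       function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE))

  manifest <- list(
    seed = seed, models = models,
    package_version = as.character(utils::packageVersion("polycrossGS")),
    n_offspring = nrow(cross$dosage), n_snps_retained = ncol(imp),
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
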