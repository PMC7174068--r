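write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Build the standard set of TMB counting methods
#'
#' One whole-exome method with and one without synonymous variants, plus one
#' non-synonymous method per panel (the common configuration of the assays
#' being emulated; panels that count all coding variants can be added by
#' hand with [tmb_method()]).
#'
#' @param exome_fp Exome `panel_footprint`.
#' @param panel_fps List of panel `panel_footprint`s.
#' @return Named list of [tmb_method()] objects with labels
#'   `WES.allcoding`, `WES.nonsyn`, `<panel>.nonsyn`.
#' @export
standard_methods <- function(exome_fp, panel_fps) {
  methods <- list(
    tmb_method("WES.allcoding",
               inclusion_policy(include_synonymous = TRUE, region = exome_fp)),
    tmb_method("WES.nonsyn",
               inclusion_policy(include_synonymous = FALSE, region = exome_fp)))
  for (fp in panel_fps) {
    methods[[length(methods) + 1L]] <- tmb_method(
      paste0(fp$panel_name, ".nonsyn"),
      inclusion_policy(include_synonymous = FALSE, region = fp))
  }
  names(methods) <- vapply(methods, `[[`, character(1), "label")
  methods
}

#' Run the full synthetic study end to end
#'
#' Simulates the study inputs (annotation, panels, per-sample VCFs, clinical
#' table), then runs every downstream stage through its file interface:
#' footprint estimation from the GTF, variant ingestion from the VCFs, TMB
#' computation, between-method concordance, and TMB-quartile survival
#' analysis. All artifacts are plain TSV/JSON under `out_dir`:
#'
#' \preformatted{
#'   inputs/      annotation.gtf, panel_*.txt, vcf/<sample>.vcf, clinical.tsv
#'   footprints/  footprints.tsv
#'   tmb/         tmb_long.tsv, tmb_wide.tsv
#'   concordance/ pairwise.tsv, bland_altman_wes_syn_toggle.json
#'   survival/    hr.tsv, km.tsv, cuts.tsv
#'   manifest.json
#' }
#'
#' Identical configuration and seed give byte-identical artifacts.
#'
#' @param out_dir Output directory.
#' @param cfg A [sim_config()].
#' @param lambda Deming error-variance ratio.
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @param quartile_mode `"pan_cohort"` or `"intra_tumor_type"`.
#' @param roundtrip_files If TRUE (default) variants are written as VCFs and
#'   parsed back, and the annotation is written as GTF and reloaded, so the
#'   file interfaces are exercised; FALSE skips the disk round trip and uses
#'   the in-memory objects (identical results, faster).
#' @return Invisibly, a list with the computed objects (`footprints`,
#'   `tmb`, `pairwise`, `bland_altman`, `survival`) and `paths`.
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(), lambda = 1,
                         ties = c("efron", "breslow"),
                         quartile_mode = c("pan_cohort", "intra_tumor_type"),
                         roundtrip_files = TRUE) {
  ties <- match.arg(ties); quartile_mode <- match.arg(quartile_mode)
  dirs <- file.path(out_dir, c("inputs", "inputs/vcf", "footprints", "tmb",
                               "concordance", "survival"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)

  message("stage simulate: ", cfg$n_genes, " genes, ", cfg$n_samples, " samples")
  genome <- simulate_genome(cfg)
  in_paths <- write_genome(genome, file.path(out_dir, "inputs"))
  cohort <- simulate_cohort(cfg, genome)
  vcf_paths <- write_cohort_vcfs(cohort, file.path(out_dir, "inputs", "vcf"))

  message("stage footprint")
  models <- if (roundtrip_files) load_gene_models(in_paths$gtf) else genome$models
  panels <- if (roundtrip_files) {
    lapply(genome$panels, function(p)
      read_panel_genes(file.path(out_dir, "inputs", paste0("panel_", p$name, ".txt")),
                       name = p$name))
  } else genome$panels
  exome_fp <- exome_footprint(models)
  panel_fps <- lapply(panels, panel_footprint, models = models)
  fps <- c(list(WES = exome_fp), panel_fps)
  write_tsv_plain(footprint_report(fps), file.path(out_dir, "footprints", "footprints.tsv"))

  message("stage tmb")
  variants <- if (roundtrip_files) {
    dplyr::bind_rows(lapply(vcf_paths, read_variants))
  } else cohort$variants
  methods <- standard_methods(exome_fp, panel_fps)
  m <- tmb_matrix(variants, methods, samples = cohort$samples$sample_id)
  write_tsv_plain(tibble::as_tibble(m), file.path(out_dir, "tmb", "tmb_long.tsv"))
  write_tsv_plain(tmb_wide(m), file.path(out_dir, "tmb", "tmb_wide.tsv"))

  message("stage concordance")
  pw <- comparison_matrix(m, lambda = lambda)
  write_tsv_plain(pw, file.path(out_dir, "concordance", "pairwise.tsv"))
  wide <- tmb_wide(m)
  ba <- bland_altman(wide[["WES.nonsyn"]], wide[["WES.allcoding"]])
  jsonlite::write_json(
    list(x_method = "WES.nonsyn", y_method = "WES.allcoding",
         mean_bias = ba$mean_bias, loa_low = ba$loa_low,
         loa_high = ba$loa_high, n = ba$n),
    file.path(out_dir, "concordance", "bland_altman_wes_syn_toggle.json"),
    auto_unbox = TRUE, digits = NA)

  message("stage survival")
  tmb_wes <- tibble::as_tibble(m)[m$method_label == "WES.nonsyn",
                                  c("sample_id", "tmb")]
  clinical <- simulate_survival(cfg, tmb_wes,
                                tumor_type = cohort$samples$tumor_type)
  write_clinical(clinical, file.path(out_dir, "inputs", "clinical.tsv"))
  clinical_in <- if (roundtrip_files)
    read_clinical(file.path(out_dir, "inputs", "clinical.tsv")) else clinical
  surv <- survival_report(m, clinical_in, mode = quartile_mode, ties = ties)
  write_tsv_plain(surv$hr, file.path(out_dir, "survival", "hr.tsv"))
  write_tsv_plain(surv$km, file.path(out_dir, "survival", "km.tsv"))
  write_tsv_plain(surv$cuts, file.path(out_dir, "survival", "cuts.tsv"))

  cfg_json <- cfg
  cfg_json$tumor_types <- as.data.frame(cfg$tumor_types)
  artifacts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  artifacts <- setdiff(artifacts, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "panelTMB",
    version = as.character(utils::packageVersion("panelTMB")),
    seed = cfg$seed,
    flags = list(lambda = lambda, ties = ties, quartile_mode = quartile_mode,
                 roundtrip_files = roundtrip_files),
    config = unclass(cfg_json),
    files = as.list(setNames(unname(tools::md5sum(artifacts)),
                             sub(paste0("^", out_dir, "/?"), "", artifacts))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genome = genome, cohort = cohort, footprints = fps,
                 tmb = m, pairwise = pw, bland_altman = ba, survival = surv,
                 clinical = clinical,
                 paths = list(out_dir = out_dir)))
}
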