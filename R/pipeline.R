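# End-to-end orchestration: synthesize -> derive -> score -> robustness ->
# associate, with a manifest sufficient to re-run bit-identically.

#' Pipeline configuration
#'
#' Either real inputs (paths to an expression compendium, cohort matrix,
#' annotations and standards) or synthetic configs per stage, never both.
#'
#' @param compendium,cohort,annotations,standards optional file paths
#'   (compendium/cohort TSV or GCT, annotations TSV, standards as a
#'   two-column cell_type TAB gene TSV).
#' @param synthetic logical: generate inputs with the bundled generators.
#' @param compendium_cfg,cohort_cfg generator configs (synthetic mode).
#' @param derivation a [derivation_params()] list.
#' @param robustness_fractions,robustness_reps gene-dropout grid; `NULL`
#'   skips the robustness stage.
#' @param out_dir output directory.
#' @param seed mandatory master seed for all stochastic stages.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(compendium = NULL, cohort = NULL,
                            annotations = NULL, standards = NULL,
                            synthetic = is.null(compendium),
                            compendium_cfg = NULL, cohort_cfg = NULL,
                            derivation = NULL,
                            robustness_fractions = seq(0, 0.5, by = 0.25),
                            robustness_reps = 10L,
                            out_dir = tempfile("immunodissect_run"),
                            seed = 1L) {
  if (synthetic && !is.null(compendium))
    stop2("give either real input paths or synthetic = TRUE, not both")
  if (!synthetic && (is.null(compendium) || is.null(standards)))
    stop2("real-input mode needs compendium and standards paths")
  seed <- as.integer(seed)
  structure(list(compendium = compendium, cohort = cohort,
                 annotations = annotations, standards = standards,
                 synthetic = synthetic,
                 compendium_cfg = compendium_cfg %||%
                   compendium_config(seed = child_seed(seed, 1L)),
                 cohort_cfg = cohort_cfg %||%
                   tumor_cohort_config(seed = child_seed(seed, 2L)),
                 derivation = derivation %||%
                   derivation_params(seed = child_seed(seed, 3L)),
                 robustness_fractions = robustness_fractions,
                 robustness_reps = as.integer(robustness_reps),
                 out_dir = out_dir, seed = seed),
            class = "PipelineConfig")
}

read_standards_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop2("standards TSV needs cell_type and gene columns")
  build_standards(split(as.character(df[[2L]]), df[[1L]]))
}

#' Run the full pipeline
#'
#' Executes synthesize (or load) -> derive one marker set per lymphocyte
#' cell type -> score the cohort -> gene-dropout robustness -> association
#' suite, writing GMT signatures, ranked TSVs, the score table, the
#' robustness and association reports, and a YAML manifest (config, seed,
#' package version, input hashes). Identical config + seed give byte-identical
#' outputs. Any stage failure aborts with the stage name; outputs written so
#' far are marked incomplete in the manifest.
#'
#' @param cfg a [pipeline_config()].
#' @return the run directory path, invisibly; the manifest lists all outputs.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "immunodissect",
                   version = as.character(utils::packageVersion("immunodissect")),
                   seed = cfg$seed, synthetic = cfg$synthetic,
                   status = "incomplete", outputs = list())
  write_manifest <- function()
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  write_manifest()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$status <<- paste0("failed at stage: ", name)
      write_manifest()
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # --- inputs -------------------------------------------------------------
  comp <- stage("synthesize/load compendium", {
    if (cfg$synthetic) generate_compendium(cfg$compendium_cfg)
    else list(expression = read_expression_matrix(cfg$compendium),
              standards = read_standards_tsv(cfg$standards))
  })

  # --- derive -------------------------------------------------------------
  markers <- stage("derive", {
    zc <- suppressWarnings(zscore_transform(comp$expression))
    lapply(comp$standards[intersect(LYMPHOCYTES, names(comp$standards))],
           function(std) suppressWarnings(
             nanodissect(zc, std, cfg$derivation)))
  })
  signatures <- lapply(markers, `[[`, "signature")
  stage("write signatures", {
    write_gmt(signatures, file.path(cfg$out_dir, "signatures.gmt"))
    for (nm in names(markers))
      utils::write.table(markers[[nm]]$ranked,
                         file.path(cfg$out_dir, paste0("ranked_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$signatures <- "signatures.gmt"
  })

  # --- cohort + scores ----------------------------------------------------
  cohort <- stage("synthesize/load cohort", {
    if (cfg$synthetic) generate_tumor_cohort(cfg$cohort_cfg, signatures)
    else if (!is.null(cfg$cohort))
      list(expression = read_expression_matrix(cfg$cohort),
           annotations = if (!is.null(cfg$annotations))
             read_annotations(cfg$annotations) else NULL,
           er_genes = NULL)
    else NULL
  })
  if (is.null(cohort)) {
    manifest$status <- "complete (derivation only; no cohort supplied)"
    write_manifest()
    return(invisible(cfg$out_dir))
  }

  scores <- stage("score", {
    zt <- suppressWarnings(zscore_transform(cohort$expression))
    st <- suppressMessages(score_table(zt, signatures,
                                       er_signature = cohort$er_genes))
    utils::write.table(format(st, digits = 10),
                       file.path(cfg$out_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$outputs$scores <- "scores.tsv"
    attr(st, "zmatrix") <- zt
    st
  })

  # --- robustness ---------------------------------------------------------
  ann <- cohort$annotations
  if (!is.null(cfg$robustness_fractions) && !is.null(ann) &&
      "infiltration_category" %in% names(ann)) {
    stage("robustness", {
      zt <- attr(scores, "zmatrix")
      cats <- ann$infiltration_category[match(colnames(zt), ann$sample_id)]
      rob <- do.call(rbind, lapply(names(signatures), function(nm) {
        rr <- robustness_analysis(zt, signatures[[nm]], cats,
                                  fractions = cfg$robustness_fractions,
                                  reps = cfg$robustness_reps,
                                  seed = child_seed(cfg$seed, 4L))
        cbind(signature = nm, rr$results,
              max_preserved_fraction = rr$max_preserved_fraction)
      }))
      utils::write.table(format(rob, digits = 10),
                         file.path(cfg$out_dir, "robustness.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$outputs$robustness <- "robustness.tsv"
    })
  }

  # --- association --------------------------------------------------------
  if (!is.null(ann)) {
    stage("associate", {
      suite <- suppressWarnings(suppressMessages(
        run_association_suite(scores, ann)))
      utils::write.table(format(suite$report, digits = 10),
                         file.path(cfg$out_dir, "association_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (nm in names(suite$survival))
        utils::write.table(format(suite$survival[[nm]]$curves, digits = 10),
                           file.path(cfg$out_dir, paste0("km_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$outputs$association <- "association_report.tsv"
    })
  } else message("no annotations; association stage skipped")

  manifest$status <- "complete"
  cfgfile <- file.path(cfg$out_dir, "config.yaml")
  cfg_serializable <- lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(cfg_serializable, cfgfile)
  manifest$config_md5 <- unname(tools::md5sum(cfgfile))
  write_manifest()
  invisible(cfg$out_dir)
}
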