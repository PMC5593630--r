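# Synthetic data with the statistical structure the analysis assumes: a
# blood compendium with planted cell-type-specific gene programs, and tumor
# cohorts built as mixtures of a tumor baseline, an ER program, and immune
# programs whose infiltration fractions are anti-correlated with ER
# activity. Every generator is a pure function of its config (incl. seed).

LYMPHOCYTES <- c("Bcell", "CTL", "Th1", "Th2")
COMPENDIUM_CELL_TYPES <- c(LYMPHOCYTES, "monocyte")

#' Configuration for the synthetic blood compendium
#'
#' Defaults emulate a few hundred mixed-condition blood microarray samples on
#' a log-intensity scale: five cell-type programs (B cell, CTL, Th1, Th2,
#' monocyte) of `genes_per_program` genes each, with `overlap_Th1_Th2` genes
#' shared between the two T-helper programs and no other overlap. A program
#' gene is shifted up by `program_effect` in samples where its cell type is
#' active (each cell type independently active with `active_prob`).
#'
#' @param n_samples,n_genes compendium dimensions (default 400 x 4000).
#' @param genes_per_program program size (default 120).
#' @param overlap_Th1_Th2 genes shared by the Th1 and Th2 programs (default 30).
#' @param program_effect mean log-intensity shift of a program gene in
#'   active samples (default 2.0).
#' @param noise_sd baseline Gaussian noise sd (default 1.0).
#' @param active_prob per-sample activation probability of each cell type
#'   (default 0.3).
#' @param standard_size seed genes sampled per cell type to build the tiered
#'   standards (default 40).
#' @param seed RNG seed.
#' @return a `CompendiumConfig` list.
#' @export
compendium_config <- function(n_samples = 400L, n_genes = 4000L,
                              genes_per_program = 120L,
                              overlap_Th1_Th2 = 30L, program_effect = 2.0,
                              noise_sd = 1.0, active_prob = 0.3,
                              standard_size = 40L, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              cell_types = COMPENDIUM_CELL_TYPES,
              genes_per_program = as.integer(genes_per_program),
              overlap_Th1_Th2 = as.integer(overlap_Th1_Th2),
              program_effect = program_effect, noise_sd = noise_sd,
              active_prob = active_prob,
              standard_size = as.integer(standard_size),
              seed = as.integer(seed))
  n_program_genes <- 5L * cfg$genes_per_program - cfg$overlap_Th1_Th2
  if (cfg$overlap_Th1_Th2 >= cfg$genes_per_program)
    stop2("overlap_Th1_Th2 must be smaller than genes_per_program")
  if (n_program_genes > cfg$n_genes)
    stop2("programs (", n_program_genes, " genes) exceed the gene universe (",
          cfg$n_genes, ")")
  if (cfg$standard_size > cfg$genes_per_program)
    stop2("standard_size exceeds genes_per_program")
  structure(cfg, class = "CompendiumConfig")
}

gene_universe <- function(n) sprintf("g%05d", seq_len(n))

# Deterministic block allocation of program genes in the universe.
allocate_programs <- function(cfg) {
  genes <- gene_universe(cfg$n_genes)
  p <- cfg$genes_per_program; v <- cfg$overlap_Th1_Th2
  cuts <- function(from, len) genes[from:(from + len - 1L)]
  th1_unique <- cuts(2L * p + 1L, p - v)
  shared <- cuts(3L * p - v + 1L, v)
  list(Bcell = cuts(1L, p),
       CTL = cuts(p + 1L, p),
       Th1 = c(th1_unique, shared),
       Th2 = c(shared, cuts(3L * p + 1L, p - v)),
       monocyte = cuts(4L * p - v + 1L, p))
}

#' Generate the synthetic blood compendium
#'
#' Expression is baseline Gaussian noise plus `program_effect` added to a
#' program's genes in the samples where that cell type is active. Tiered
#' standards are built from a seeded subsample of each true program: shared
#' Th1/Th2 seed genes (sampled once, entering both lists) become low-tier
#' positives, unique seeds high-tier positives, and the other cell types'
#' unique seeds the negatives.
#'
#' @param cfg a [compendium_config()].
#' @return list with `expression` (raw `ExpressionMatrix`), `programs`
#'   (named list of true program genes), `standards` (named list of
#'   `GeneStandard`), and `activity` (samples x cell types 0/1 matrix).
#' @export
generate_compendium <- function(cfg = compendium_config()) {
  stopifnot(inherits(cfg, "CompendiumConfig"))
  programs <- allocate_programs(cfg)
  genes <- gene_universe(cfg$n_genes)
  samples <- sprintf("comp%04d", seq_len(cfg$n_samples))

  with_seed(cfg$seed, {
    activity <- matrix(stats::rbinom(cfg$n_samples * 5L, 1L,
                                     cfg$active_prob),
                       nrow = cfg$n_samples,
                       dimnames = list(samples, cfg$cell_types))
    x <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, 0, cfg$noise_sd),
                nrow = cfg$n_genes, dimnames = list(genes, samples))
    for (ct in cfg$cell_types) {
      idx <- match(programs[[ct]], genes)
      on_s <- activity[, ct] == 1L
      x[idx, on_s] <- x[idx, on_s] + cfg$program_effect
    }

    # seed lists for the tiered standards; shared Th1/Th2 seeds drawn once
    shared <- intersect(programs$Th1, programs$Th2)
    n_shared_seed <- round(cfg$standard_size * length(shared) /
                             cfg$genes_per_program)
    shared_seed <- sample(shared, n_shared_seed)
    seed_lists <- lapply(cfg$cell_types, function(ct) {
      uniq <- setdiff(programs[[ct]], shared)
      k <- cfg$standard_size -
        if (ct %in% c("Th1", "Th2")) n_shared_seed else 0L
      c(sample(uniq, k),
        if (ct %in% c("Th1", "Th2")) shared_seed else character())
    })
    names(seed_lists) <- cfg$cell_types

    list(expression = expression_matrix(x), programs = programs,
         standards = build_standards(seed_lists), activity = activity,
         seed_lists = seed_lists)
  })
}

#' Configuration for the synthetic tumor cohort
#'
#' Samples mix a tumor baseline, an ER program scaled by a latent ER
#' activity, and immune programs weighted by true infiltration fractions.
#' Each cell type's fraction is Beta-distributed around a mean
#' `m0 + infiltration_sd * u_s - er_slope * a_s`, where `u_s` is a shared
#' latent infiltration factor and `a_s` the latent ER activity (both standard
#' normal), so total infiltration is anti-correlated with ER activity
#' (defaults give Pearson r around -0.4). CAAI-positive samples have all
#' fractions multiplied by `caai_reduction`. Survival is exponential with
#' log-hazard `b0 + b1 * total_fraction`, with `b1 < 0` only in the ER-
#' stratum. A paired pre/day-90 treatment arm multiplies day-90 fractions by
#' `treatment_uplift`.
#'
#' @param n_samples cross-sectional cohort size (default 300).
#' @param n_genes gene-universe size; must cover the planted signatures
#'   (default 4000, matching the compendium universe).
#' @param er_program_size planted ER program size (default 50).
#' @param er_positive_frac ER+ share (default 0.76, the METABRIC-like
#'   340/1417 ER- share).
#' @param er_expr_effect expression shift of an ER-program gene per unit of
#'   latent ER activity (default 1.0).
#' @param m0 baseline per-cell-type infiltration fraction (default 0.15).
#' @param infiltration_sd sd of the shared infiltration factor on the
#'   fraction scale (default 0.12).
#' @param er_slope decrease of each cell type's mean fraction per unit of ER
#'   activity (default 0.06).
#' @param beta_concentration Beta concentration of fractions around their
#'   mean (default 80).
#' @param infiltration_amplitude expression shift of a signature gene per
#'   unit of its cell type's fraction (default 8).
#' @param noise_sd baseline expression noise (default 1.0).
#' @param caai_positive_frac CAAI+ share (default 0.15).
#' @param caai_reduction multiplicative infiltration reduction in CAAI+
#'   samples (default 0.5).
#' @param b0 baseline log-hazard (default log(0.1)).
#' @param b1 named log-hazard slope on total infiltration per ER stratum
#'   (default c("ER-" = -1.5, "ER+" = 0)).
#' @param censoring_rate rate of the independent exponential censoring
#'   process relative to exp(b0) (default 0.1, roughly 20 percent censored
#'   given the infiltration-lowered event hazards).
#' @param n_pairs patients in the paired pre/day-90 arm (default 29, i.e. 58
#'   biopsies); pairs are generated ER+ and excluded from survival.
#' @param treatment_uplift multiplicative day-90 fraction increase
#'   (default 1.4).
#' @param seed RNG seed.
#' @return a `TumorCohortConfig` list.
#' @export
tumor_cohort_config <- function(n_samples = 300L, n_genes = 4000L,
                                er_program_size = 50L,
                                er_positive_frac = 0.76,
                                er_expr_effect = 1.0, m0 = 0.15,
                                infiltration_sd = 0.12, er_slope = 0.06,
                                beta_concentration = 80,
                                infiltration_amplitude = 8,
                                noise_sd = 1.0, caai_positive_frac = 0.15,
                                caai_reduction = 0.5, b0 = log(0.1),
                                b1 = c("ER-" = -1.5, "ER+" = 0),
                                censoring_rate = 0.1, n_pairs = 29L,
                                treatment_uplift = 1.4, seed = 1L) {
  stopifnot(er_positive_frac > 0, er_positive_frac < 1,
            caai_positive_frac >= 0, caai_positive_frac < 1,
            caai_reduction > 0, caai_reduction <= 1,
            beta_concentration > 0, censoring_rate >= 0,
            treatment_uplift > 0, all(c("ER-", "ER+") %in% names(b1)))
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 er_program_size = as.integer(er_program_size),
                 er_positive_frac = er_positive_frac,
                 er_expr_effect = er_expr_effect, m0 = m0,
                 infiltration_sd = infiltration_sd, er_slope = er_slope,
                 beta_concentration = beta_concentration,
                 infiltration_amplitude = infiltration_amplitude,
                 noise_sd = noise_sd,
                 caai_positive_frac = caai_positive_frac,
                 caai_reduction = caai_reduction, b0 = b0, b1 = b1,
                 censoring_rate = censoring_rate,
                 n_pairs = as.integer(n_pairs),
                 treatment_uplift = treatment_uplift,
                 seed = as.integer(seed)),
            class = "TumorCohortConfig")
}

rbeta_mean <- function(n, mean, kappa) {
  stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
}

#' Generate a synthetic tumor cohort
#'
#' @param cfg a [tumor_cohort_config()].
#' @param signatures named list of cell-type gene sets to plant as immune
#'   programs; all genes must lie in the cohort's gene universe.
#' @return list with `expression` (raw `ExpressionMatrix`),
#'   `annotations` (a `CohortAnnotation` carrying ER status, subtype,
#'   infiltration category, CAAI, survival, timepoint and the true
#'   per-cell-type fractions), and `er_genes` (the planted ER program, usable
#'   as the ER signature for scoring).
#' @export
generate_tumor_cohort <- function(cfg = tumor_cohort_config(), signatures) {
  stopifnot(inherits(cfg, "TumorCohortConfig"), is.list(signatures),
            !is.null(names(signatures)))
  genes <- gene_universe(cfg$n_genes)
  missing <- setdiff(unique(unlist(signatures)), genes)
  if (length(missing))
    stop2("signature gene(s) not in the cohort gene universe: ",
          paste(utils::head(missing, 5L), collapse = ", "))

  with_seed(cfg$seed, {
    n_cross <- cfg$n_samples
    n_all <- n_cross + 2L * cfg$n_pairs
    sample_id <- sprintf("tum%04d", seq_len(n_all))
    patient_id <- c(sprintf("pt%04d", seq_len(n_cross)),
                    rep(sprintf("ptx%03d", seq_len(cfg$n_pairs)), each = 2L))
    timepoint <- c(rep("none", n_cross),
                   rep(c("pre", "day90"), times = cfg$n_pairs))

    er_thr <- stats::qnorm(1 - cfg$er_positive_frac)
    a <- stats::rnorm(n_cross)                     # latent ER activity
    # paired arm: ER+ patients (aromatase-inhibitor setting)
    a_pairs <- stats::qnorm(stats::runif(cfg$n_pairs,
                                         stats::pnorm(er_thr), 1))
    a <- c(a, rep(a_pairs, each = 2L))
    u <- c(stats::rnorm(n_cross), rep(stats::rnorm(cfg$n_pairs), each = 2L))
    er_status <- ifelse(a > er_thr, "ER+", "ER-")

    caai <- c(ifelse(stats::runif(n_cross) < cfg$caai_positive_frac,
                     "positive", "negative"),
              rep("unknown", 2L * cfg$n_pairs))

    frac <- sapply(LYMPHOCYTES, function(ct) {
      m <- pmin(pmax(cfg$m0 + cfg$infiltration_sd * u - cfg$er_slope * a,
                     0.01), 0.9)
      f <- rbeta_mean(n_all, m, cfg$beta_concentration)
      f
    })
    rownames(frac) <- sample_id
    # paired arm: day-90 fractions are the pre fractions times the uplift
    pre_idx <- which(timepoint == "pre")
    frac[pre_idx + 1L, ] <- pmin(frac[pre_idx, ] * cfg$treatment_uplift, 0.97)
    frac[caai == "positive", ] <- frac[caai == "positive", ] *
      cfg$caai_reduction
    total_f <- rowSums(frac)

    # ordinal infiltration categories from fixed quantile cuts of the
    # cross-sectional total fraction (balanced by construction)
    cuts <- stats::quantile(total_f[seq_len(n_cross)], c(0.25, 0.5, 0.75),
                            type = 7)
    infiltration <- cut(total_f, c(-Inf, cuts, Inf),
                        labels = INFILTRATION_LEVELS)

    # subtype: predominantly ER- subtypes for low a, luminal for high a
    subtype <- ifelse(er_status == "ER-",
                      sample(c("basal", "HER2", "normal-like"), n_all,
                             replace = TRUE, prob = c(0.6, 0.3, 0.1)),
                      ifelse(stats::runif(n_all) < 0.6, "luminal A",
                             "luminal B"))

    # survival (cross-sectional only)
    b1 <- ifelse(er_status[seq_len(n_cross)] == "ER-", cfg$b1[["ER-"]],
                 cfg$b1[["ER+"]])
    haz <- exp(cfg$b0 + b1 * total_f[seq_len(n_cross)])
    t_event <- stats::rexp(n_cross, haz)
    t_cens <- if (cfg$censoring_rate > 0)
      stats::rexp(n_cross, cfg$censoring_rate * exp(cfg$b0))
    else rep(Inf, n_cross)
    surv_time <- c(pmin(t_event, t_cens), rep(NA_real_, 2L * cfg$n_pairs))
    event <- c(as.integer(t_event <= t_cens), rep(NA_integer_, 2L * cfg$n_pairs))

    # expression: baseline + ER program * a + sum_c f_c * program_c + noise
    er_pool <- setdiff(genes, unique(unlist(signatures)))
    er_genes <- sort(sample(er_pool, cfg$er_program_size))
    x <- matrix(stats::rnorm(cfg$n_genes * n_all, 0, cfg$noise_sd),
                nrow = cfg$n_genes, dimnames = list(genes, sample_id))
    x[er_genes, ] <- x[er_genes, ] +
      rep(cfg$er_expr_effect * a, each = length(er_genes))
    for (ct in names(signatures)) {
      idx <- match(unique(signatures[[ct]]), genes)
      fc <- if (ct %in% colnames(frac)) frac[, ct] else total_f / ncol(frac)
      x[idx, ] <- x[idx, ] +
        rep(cfg$infiltration_amplitude * fc, each = length(idx))
    }

    ann <- data.frame(sample_id = sample_id, patient_id = patient_id,
                      er_status = er_status, subtype = subtype,
                      infiltration_category = as.character(infiltration),
                      caai_status = caai, survival_time = surv_time,
                      event = event, timepoint = timepoint,
                      er_activity_true = a, stringsAsFactors = FALSE)
    for (ct in LYMPHOCYTES)
      ann[[paste0("true_fraction_", ct)]] <- frac[, ct]
    ann$true_fraction_total <- total_f

    list(expression = expression_matrix(x),
         annotations = cohort_annotation(ann), er_genes = er_genes)
  })
}

#' Write a directory of tiny hand-verifiable fixtures
#'
#' Produces <= 10-gene, <= 8-sample plain-text fixtures used by the unit
#' tests: a 3 x 3 expression TSV whose first row is (1, 2, 3), a GCT twin, a
#' 2-signature GMT, a small annotation table, and a 6-subject survival table
#' with a hand-checkable log-rank layout.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
generate_toy_fixtures <- function(dir = tempfile("toyfix")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "toy_matrix.tsv"),
             gct = file.path(dir, "toy_matrix.gct"),
             gmt = file.path(dir, "toy_sets.gmt"),
             annotations = file.path(dir, "toy_annotations.tsv"),
             survival = file.path(dir, "toy_survival.tsv"))

  m <- matrix(c(1, 2, 3,
                4, 4, 7,
                5, 1, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3")))
  write_expression_matrix(expression_matrix(m), paths[["matrix"]])
  writeLines(c("#1.2", "3\t3",
               paste(c("Name", "Description", colnames(m)), collapse = "\t"),
               vapply(rownames(m), function(g)
                 paste(c(g, "na", m[g, ]), collapse = "\t"), character(1))),
             paths[["gct"]])
  write_gmt(list(SET1 = c("gA", "gB"), SET2 = c("gC")), paths[["gmt"]])

  ann <- data.frame(sample_id = c("s1", "s2", "s3"),
                    patient_id = c("p1", "p2", "p3"),
                    er_status = c("ER+", "ER-", "ER+"),
                    infiltration_category = c("absent", "severe", "mild"),
                    timepoint = "none", stringsAsFactors = FALSE)
  write_annotations(cohort_annotation(ann), paths[["annotations"]])

  surv <- data.frame(sample_id = sprintf("v%d", 1:6),
                     group = c("A", "A", "A", "B", "B", "B"),
                     time = c(1, 3, 5, 2, 4, 6),
                     event = c(1L, 1L, 0L, 1L, 1L, 1L),
                     stringsAsFactors = FALSE)
  utils::write.table(surv, paths[["survival"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
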