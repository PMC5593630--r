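# Shared fixtures. The default-scale compendium/cohort run is expensive, so
# it is built once per session and memoised for every test that needs it.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A tiny deterministic z-scored matrix with known rows.
toy_zmatrix <- function() {
  m <- matrix(c(-1, 0, 1,
                 1, 1, 1,
                 0, -1, -2), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3")))
  expression_matrix(m, zscored = TRUE)
}

# Small compendium for fast derivation tests: same generative structure at
# reduced scale.
small_compendium <- function(seed = 5, noise_sd = 1.0) {
  generate_compendium(compendium_config(
    n_samples = 120L, n_genes = 600L, genes_per_program = 40L,
    overlap_Th1_Th2 = 10L, standard_size = 20L, noise_sd = noise_sd,
    seed = seed))
}

# Default-parameter compendium plus derived signatures, shared by the
# acceptance-scale tests.
default_derivation <- function() {
  memo("default_derivation", {
    comp <- generate_compendium(compendium_config(seed = 101L))
    zc <- suppressWarnings(zscore_transform(comp$expression))
    params <- derivation_params(seed = 101L)
    markers <- lapply(comp$standards[c("Bcell", "CTL", "Th1", "Th2")],
                      function(s) suppressWarnings(nanodissect(zc, s, params)))
    list(comp = comp, z = zc, params = params, markers = markers,
         signatures = lapply(markers, `[[`, "signature"))
  })
}

# Default-parameter tumor cohort scored with the derived signatures.
default_cohort <- function() {
  memo("default_cohort", {
    d <- default_derivation()
    coh <- generate_tumor_cohort(tumor_cohort_config(seed = 202L),
                                 d$signatures)
    zt <- suppressWarnings(zscore_transform(coh$expression))
    st <- suppressMessages(score_table(zt, d$signatures,
                                       er_signature = coh$er_genes))
    list(cohort = coh, z = zt, scores = st, signatures = d$signatures)
  })
}

# Reduced-universe cohort for multi-seed meta-tests: planted programs are
# the true compendium programs of a small universe.
quick_cohort <- function(seed, ...) {
  progs <- allocate_small_programs()
  cfg <- tumor_cohort_config(n_genes = 700L, seed = seed, ...)
  generate_tumor_cohort(cfg, progs)
}

allocate_small_programs <- function() {
  genes <- sprintf("g%05d", 1:700)
  list(Bcell = genes[1:120], CTL = genes[121:240],
       Th1 = genes[241:360], Th2 = genes[331:450])
}
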