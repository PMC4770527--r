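## Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, maker(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## Compact cohort: 7 epitypes of 10 tumors, 800 probes; default noise.
small_config <- function(seed = 101, ...) {
  cohort_config(n_tumors = 70, n_normals = 24, n_probes = 800,
                pattern_sites = c(basal_meth = 10L, luminal_meth = 15L,
                                  global_hypo = 15L, luminal_hypo = 20L,
                                  basal_hypo = 8L),
                marker_sites = 10L, n_cn_probes = 400L,
                n_filler_genes = 40L, seed = seed, ...)
}

small_cohort <- function() fixture("small", function() generate_cohort(small_config()))

## Same layout with low noise and no censoring: the exact-recovery fixture.
lownoise_cohort <- function() fixture("lownoise", function()
  generate_cohort(small_config(noise_sd = 0.01, missing_rate = 0, seed = 202)))

## The full-size fixture used by the acceptance checks: defaults of
## cohort_config() (120 tumors, 96 normals, 5000 probes, noise_sd 0.05).
acceptance_cohort <- function() fixture("acceptance", function()
  generate_cohort(cohort_config(seed = 11)))

## Full-size low-noise fixture for the selection-exactness check.
acceptance_lownoise_cohort <- function() fixture("acceptance_lownoise", function()
  generate_cohort(cohort_config(noise_sd = 0.01, missing_rate = 0, seed = 12)))

## Normalized tumor/normal split, cached alongside the cohort.
split_normalized <- function(cohort, key) {
  fixture(key, function() {
    norm <- peak_normalize(cohort$beta)
    si <- cohort$sample_info
    list(norm = norm,
         tumors = beta_matrix(norm$beta[, si$sample_id[si$cohort == "tumor"],
                                        drop = FALSE],
                              norm$assay_type, TRUE),
         normals = beta_matrix(norm$beta[, si$sample_id[si$cohort == "normal"],
                                         drop = FALSE],
                               norm$assay_type, TRUE))
  })
}
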