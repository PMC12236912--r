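# shared builders for small test objects

tiny_arch <- function(dropout = 0) {
  arch_config(in_channels = 2L, input_dims = c(6L, 6L, 6L),
              block_filters = c(3L, 4L), fc_widths = 5L,
              dropout_rate = dropout)
}

# a random batch tensor with given subject count and dims
random_batch <- function(n, dims = c(6, 6, 6), nc = 2, seed = 1) {
  set.seed(seed)
  data <- array(rnorm(n * nc * prod(dims)), c(n, nc, dims))
  structure(list(data = data, subject_ids = sprintf("T%03d", seq_len(n))),
            class = "batch_tensor")
}

# a small rendered cohort shared across tests (rendered lazily, cached)
small_cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_control = 12, n_clinical = 8, n_sites = 2,
                          seed = 42)
      coh <- sample_cohort(spec)
      pp <- phantom_params(grid_dims = c(16L, 18L, 16L),
                           brain_radii = c(6, 7, 6),
                           ventricle_base_radius = 1,
                           ventricle_age_slope = 0.02,
                           gm_base_thickness = 2.8,
                           gm_age_slope = 0.015)
      cache <<- list(spec = spec, cohort = coh, params = pp,
                     volumes = render_cohort(coh, pp))
    }
    cache
  }
})

site_table_path <- function(which) {
  system.file("extdata", "site_tables", paste0(which, "_sites.tsv"),
              package = "brainpad", mustWork = TRUE)
}
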