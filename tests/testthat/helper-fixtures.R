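# Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

fix_pore <- function() memo("pore", function() pore_model())

# a small reference set used across tests
fix_refs <- function() memo("refs", function() {
  make_reference(synth_config(n_refs = 4L, ref_length = 400L, seed = 3L))
})

noiseless_config <- function(seed = 1L) {
  synth_config(trace_sharpness = 1, noise_scale = 0, trace_perturb = 0,
               seed = seed)
}

# one noiseless read over the first fixture reference
fix_noiseless_read <- function() memo("noiseless_read", function() {
  refs <- fix_refs()
  nm <- names(refs$sequences)[1]
  set.seed(21)
  simulate_read(refs$sequences[[nm]], FALSE, fix_pore(), noiseless_config(),
                ref_name = nm)
})

# tiny model config: same architecture family, small widths, full 1280 input
tiny_encoder <- function(embed_dim = 16L) {
  encoder_config(channels = 4L, skip_channels = 6L, post_channels = 4L,
                 embed_dim = embed_dim, pool_stride = 32L)
}

tiny_heads <- function() head_config(q_dim = 4L, v_dim = 4L, stoich_hidden = 4L)

# labelled bag corpus at the default study conditions (m6A offset = 2 level
# SDs, 30 reads per bag), balanced between unmodified sites and the
# 20-100% mixing ratios. Shared by the training-recovery tests.
fix_training_bags <- function() memo("training_bags", function() {
  cfg <- synth_config(n_refs = 20L, ref_length = 500L, drach_density = 1 / 50,
                      reads_per_site = 30L, seed = 2024L)
  ratios <- rep(c(0, 0.2, 0, 0.4, 0, 0.6, 0, 0.8, 0, 1), length.out = 200L)
  simulate_site_bags(cfg, fix_pore(), ratios = ratios, n_sites = 200L)
})

# the trained model used by the classification/stoichiometry recovery tests;
# trained once per test run on the first 140 fixture bags
fix_trained_model <- function() memo("trained_model", function() {
  bags <- fix_training_bags()
  model <- m6a_model(seed = 2024L)
  model <- train_m6a_model(model, bags[1:140], epochs = 20L,
                           pretrain_epochs = 3L, seed = 2024L)
  train_stoichiometry(model, bags[1:140], epochs = 30L, seed = 2024L)
})

# mixed bags with ratios uniform in [0,1], for stoichiometry evaluation
fix_stoich_bags <- function() memo("stoich_bags", function() {
  cfg <- synth_config(n_refs = 10L, ref_length = 500L, drach_density = 1 / 50,
                      reads_per_site = 30L, seed = 2025L)
  ratios <- with_seed_local(2025L, runif(100))
  simulate_site_bags(cfg, fix_pore(), ratios = ratios, n_sites = 100L)
})

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

bag_labels <- function(bags) vapply(bags, function(b) b$label, integer(1))

predict_pmod <- function(model, bags) {
  vapply(bags, function(b) {
    aggregate_bag(encode_read(b$features, model), model)$p_mod
  }, numeric(1))
}
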