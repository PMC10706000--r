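# Shared fixtures and memoised trained models. Training runs are the
# expensive part of the suite, so each (configuration, seed) pair is trained
# at most once per session and reused by every test that needs it.

.helper_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .helper_env)) assign(key, force(expr), .helper_env)
  get(key, .helper_env)
}

toy_records <- function(n = 120, seed = 11) {
  memo(sprintf("records_%d_%d", n, seed),
       toy_dataset(synthetic_dataset_spec(n, seed = seed)))
}

# desk-scale study configuration: 2 decoder layers, width 64, sequence
# length 32, TPSA conditioning
toy_train_config <- function(seed = 101, use_graph_encoder = TRUE,
                             epochs = 40) {
  train_config(epochs = epochs, batch_size = 32, lr = 3e-3, seed = seed,
               decoder_layers = 2L, n_heads = 4L, d_model = 64L,
               max_len = 32L, d_align = 32L, dropout = 0,
               use_graph_encoder = use_graph_encoder, properties = "TPSA")
}

# the main toy model: trained once on 500 fixture molecules
toy_model <- function(seed = 101, use_graph_encoder = TRUE, epochs = 40,
                      n = 500) {
  memo(sprintf("model_%d_%s_%d_%d", seed, use_graph_encoder, epochs, n), {
    records <- memo(sprintf("records_%d_%d", n, 11),
                    toy_dataset(synthetic_dataset_spec(n, seed = 11)))
    train_model(records, toy_train_config(seed, use_graph_encoder, epochs))
  })
}

# small untrained sequence model for structural tests
tiny_gpt <- function(vocab_size = 16, seed = 3, properties = character(0)) {
  cfg <- minigpt_config(vocab_size = vocab_size, n_layers = 2L, n_heads = 2L,
                        d_model = 16L, max_len = 12L, d_align = 6L,
                        dropout = 0, properties = properties)
  set.seed(seed)
  list(config = cfg, params = minigpt_init(cfg))
}
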