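# shared small simulations, built once per test file
small_sim <- local({
  cache <- new.env()
  function(seed = 41, ...) {
    over <- list(...)
    key <- paste0("s", seed, "_", paste(names(over), unlist(over),
                                        collapse = "_"))
    key <- substr(gsub("[^a-z0-9_]", "", tolower(key)), 1, 60)
    if (is.null(cache[[key]])) {
      args <- utils::modifyList(
        list(n_founders = 60, n_gen = 3, n_litters = 18, m_wgs = 800,
             m_chip = 300, n_qtl = 60, seed = seed), over)
      cache[[key]] <- simulate_population(do.call(sim_config, args))
    }
    cache[[key]]
  }
})
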