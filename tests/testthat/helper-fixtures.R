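# Text-file fixtures built in code at test time.

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

make_net <- function(edge_lines) read_ppi(write_tmp(edge_lines))

make_annotations <- function(lines, index, min_count = 1L, max_count = 10000L) {
  read_annotations(write_tmp(lines), index, format = "tsv",
                   min_count = min_count, max_count = max_count)
}

make_domains <- function(lines, index) read_domains(write_tmp(lines), index)

make_complexes <- function(lines, index) {
  suppressMessages(read_complexes(write_tmp(lines), index))
}

# A small planted two-community dataset read back through the io module.
small_synth <- function(seed = 11, n = 60, modules = 3) {
  synthetic_dataset(synth_config(n_proteins = n, n_modules = modules,
                                 seed = seed),
                    min_count = 2L)
}

# The reference fixture of the test suite (shared by the acceptance tests).
reference_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sd <- synthetic_dataset(synth_config(seed = 42))
      tensor <- build_tensor_from_dataset(sd$dataset)
      M <- functional_similarity(sd$dataset, walk_config(), tensor = tensor)
      cache <<- list(dataset = sd$dataset, truth = sd$truth, tensor = tensor,
                     M = M)
    }
    cache
  }
})
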