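# Standard synthetic benchmark, built once per test run and shared.
# Conditions: 20 well-separated genomes (order-3 chain, Dirichlet 0.1),
# 100 kb each, 50 error-free reads per genome at 100/500/1000 bp,
# master seed 42; classified with the default k = 5 database.
.bench_cache <- new.env(parent = emptyenv())

standard_benchmark <- function() {
  if (is.null(.bench_cache$bench)) {
    .bench_cache$bench <- make_benchmark(
      n_genomes = 20L, genome_length = 1e5, order = 3L,
      concentration = 0.1, reads_per_genome = 50L,
      read_lengths = c(100L, 500L, 1000L), seed = 42L
    )
  }
  .bench_cache$bench
}

standard_db <- function() {
  if (is.null(.bench_cache$db)) {
    b <- standard_benchmark()
    .bench_cache$db <- build_database(as.list(b$genomes), k = 5L,
                                      taxonomy = b$lineage)
  }
  .bench_cache$db
}
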