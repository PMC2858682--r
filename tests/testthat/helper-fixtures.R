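# Shared synthetic fixtures, generated once per test run.

.fx_env <- new.env(parent = emptyenv())

# Default study fixture: 150 Mb genome, 82+82 training CNVs and a
# 82 MR + 200 benign test set, annotated, with a trained model.
default_fixture <- function() {
  if (!is.null(.fx_env$fx)) return(.fx_env$fx)
  g <- generate_genome(synth_genome_spec(), seed = 1)
  train_cnvs <- rbind(generate_cnv_set("mr", 82, g, seed = 2),
                      generate_cnv_set("benign", 82, g, seed = 3))
  test_cnvs <- rbind(generate_cnv_set("mr", 82, g, seed = 4),
                     generate_cnv_set("benign", 200, g, seed = 5))
  train <- annotate_cnvs(train_cnvs, g$tracks, g$genes)
  test <- annotate_cnvs(test_cnvs, g$tracks, g$genes)
  model <- train_nbtree(train, seed = 6)
  .fx_env$fx <- list(genome = g, train_cnvs = train_cnvs,
                     test_cnvs = test_cnvs, train = train, test = test,
                     model = model)
  .fx_env$fx
}

# Small genome for fast IO / pipeline tests.
small_genome_spec <- function() {
  synth_genome_spec(chrom_lengths = c(chrA = 8e6, chrB = 6e6),
                    patch_size = 1e6)
}
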