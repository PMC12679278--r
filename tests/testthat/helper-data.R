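# small in-code fixtures used across test files

# 2 genotypes x 2 environments x 2 replicates with known cell values
tiny_met <- function() {
  met_dataset(data.frame(
    genotype = rep(c("A", "B"), each = 4),
    environment = rep(rep(c("X", "Y"), each = 2), 2),
    replicate = rep(c("r1", "r2"), 4),
    y = c(10, 12, 20, 22, 14, 16, 16, 18)
  ))
}

# random g x e trait matrix with labels
random_matrix <- function(g, e, seed) {
  set.seed(seed)
  trait_matrix(matrix(rnorm(g * e), g, e,
                      dimnames = list(paste0("G", 1:g), paste0("E", 1:e))))
}

# brute-force winner: argmax over all genotypes of score inner product
brute_force_winners <- function(model) {
  gs <- model$genotype_scores[, 1:2, drop = FALSE]
  es <- model$environment_scores[, 1:2, drop = FALSE]
  apply(es, 1, function(ej) model$genotype_labels[which.max(gs %*% ej)])
}
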