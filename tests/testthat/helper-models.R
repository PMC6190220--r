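# Shared fixtures: published mean parameter sets and small builders.

table1_means <- function(label) {
  s <- cell_population_stats()
  r <- s[s$label == label, ]
  stopifnot(nrow(r) == 1L)
  maxwell_params(r$k0_mean, c(r$k1_mean, r$k2_mean), c(r$b1_mean, r$b2_mean))
}

param_vec <- function(p) {
  c(k0 = p$k0, k1 = p$k[1], b1 = p$b[1], k2 = p$k[2], b2 = p$b[2])
}

table1_truth <- function(label) {
  s <- cell_population_stats()
  r <- s[s$label == label, ]
  c(k0 = r$k0_mean, k1 = r$k1_mean, b1 = r$b1_mean, k2 = r$k2_mean, b2 = r$b2_mean)
}

# draw an n x 5 feature matrix (k0 k1 b1 k2 b2) for one cell type
draw_features <- function(label, n) {
  pop <- sample_population(label, n)
  t(vapply(pop, param_vec, numeric(5)))
}

# four classes separated by >= 6 pooled SDs in every coordinate
separated_stats <- function(i, gap = 6, sd = 0.5) {
  m <- 2 + gap * sd * i
  data.frame(label = paste0("C", i),
             k0_mean = m, k0_sd = sd, k1_mean = m, k1_sd = sd,
             b1_mean = m, b1_sd = sd, k2_mean = m, k2_sd = sd,
             b2_mean = m, b2_sd = sd)
}
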