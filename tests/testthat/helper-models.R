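# shared builders for synthetic structures used across test files

# CA-only chain segment laid along `dir` starting at `origin`
ca_segment <- function(resnos, origin = c(0, 0, 0), dir = c(1, 0, 0),
                       spacing = 3.8, chain = "A") {
  dir <- dir / sqrt(sum(dir^2))
  n <- length(resnos)
  pos <- t(sapply(seq_len(n) - 1, function(k) origin + k * spacing * dir))
  data.frame(elety = "CA", resid = "GLY", resno = resnos, chain = chain,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

# model with two CA segments at the switch ranges; flip_b reverses the
# N->C direction of the second segment
switch_model <- function(flip_b = FALSE) {
  a <- ca_segment(16:23, origin = c(0, 0, 0), dir = c(1, 0, 0))
  b_dir <- if (flip_b) c(-1, 0, 0) else c(1, 0, 0)
  b_origin <- if (flip_b) c(7 * 3.8, 6, 0) else c(0, 6, 0)
  b <- ca_segment(86:93, origin = b_origin, dir = b_dir)
  atomic_model(rbind(a, b))
}

# pair of cysteines with SG atoms at a given S-S distance
cys_pair <- function(ss_dist) {
  atomic_model(data.frame(
    elety = c("CA", "CB", "SG", "CA", "CB", "SG"),
    resid = "CYS",
    resno = c(22, 22, 22, 89, 89, 89),
    chain = "A",
    x = c(-3, -1.5, 0, 3 + ss_dist, 1.5 + ss_dist, ss_dist),
    y = 0, z = 0,
    stringsAsFactors = FALSE))
}

random_hit_sets <- function(seq_length, seed) {
  set.seed(seed)
  lapply(fibrilmetrics::amyloid_predictors(), function(p) {
    k <- sample(0:seq_length, 1)
    predictor_hits(p, sample(seq_len(seq_length), k), seq_length)
  })
}
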