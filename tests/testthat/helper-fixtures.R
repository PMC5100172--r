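# Shared fixtures, all built in code.

# Default synthetic population, built once per test run.
.fixture_env <- new.env(parent = emptyenv())
default_pop <- function() {
  if (is.null(.fixture_env$pop))
    .fixture_env$pop <- make_synthetic_population(seed = 1)
  .fixture_env$pop
}

# Hand-built wide participant record.  Scores are given per side as a
# 5-vector (C5..T1); defaults give an intact muscle everywhere.
make_record <- function(id, arm = 0, left_ml = "C5", right_ml = "C5",
                        base_L = rep(5, 5), base_R = rep(5, 5),
                        fu_L = rep(5, 5), fu_R = rep(5, 5)) {
  rec <- data.frame(id = id, arm = arm, left_ml = left_ml,
                    right_ml = right_ml, stringsAsFactors = FALSE)
  segs <- segments_uems()
  for (s in 1:5) {
    rec[[paste0("base_L_", segs[s])]] <- base_L[s]
    rec[[paste0("base_R_", segs[s])]] <- base_R[s]
    rec[[paste0("fu_L_", segs[s])]] <- fu_L[s]
    rec[[paste0("fu_R_", segs[s])]] <- fu_R[s]
  }
  rec
}

make_cohort <- function(...) do.call(rbind, list(...))

# Small long-format row set with full factor coverage is expensive to
# hand-write; this draws one from the generator under a fixed seed.
fixture_rows <- function(n_total = 40, beta_trt = 0, seed = 42) {
  build_transitional_rows(
    simulate_trial(default_pop(), n_total, beta_trt, seed = seed))
}

seq_index_of <- function(s) match(s, segments_uems())

muscle_cols_pub <- function(prefix)
  paste0(prefix, "_", rep(c("L", "R"), each = 5), "_", segments_uems())

with_seed_pub <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Independent zooming grid-search oracle for a 3-parameter cumulative
# logit fit (2 cutpoints + 1 slope): never calls the package optimizer.
grid_oracle_nll <- function(x, y, rounds = 8, span = 4, width = 21) {
  nll <- function(a1, a2, b) {
    if (a2 <= a1) return(Inf)
    alpha <- c(a1, a2)
    eta <- b * x
    pr <- plogis(c(alpha, Inf)[y] - eta) - plogis(c(-Inf, alpha)[y] - eta)
    if (any(pr <= 0)) return(Inf)
    -sum(log(pr))
  }
  centre <- c(0, 1, 0)
  best <- Inf
  for (r in seq_len(rounds)) {
    g1 <- seq(centre[1] - span, centre[1] + span, length.out = width)
    g2 <- seq(centre[2] - span, centre[2] + span, length.out = width)
    g3 <- seq(centre[3] - span, centre[3] + span, length.out = width)
    for (a1 in g1) for (a2 in g2) for (b in g3) {
      v <- nll(a1, a2, b)
      if (v < best) { best <- v; centre <- c(a1, a2, b) }
    }
    span <- span * 2.5 / (width - 1)   # zoom in around the incumbent
  }
  list(nll = best, par = centre)
}
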