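# Shared fixtures, generated in code.

# short synthetic subject (event series only)
quick_subject <- function(seed = 1, duration_s = 300, ...) {
  p <- utils::modifyList(sim_group_defaults(), list(...))
  simulate_subject(p, duration_s = duration_s, seed = seed)
}

# small two-group feature table with a known separating pair, built
# directly (no signal simulation) for classifier tests
toy_feature_table <- function(n_per_group = 15, delta = 2, seed = 99,
                              n_noise = 4) {
  set.seed(seed)
  n <- 2 * n_per_group
  g <- rep(c("A", "B"), each = n_per_group)
  f1 <- rnorm(n) + ifelse(g == "B", delta, 0)
  f2 <- rnorm(n) - ifelse(g == "B", delta, 0)
  noise <- matrix(rnorm(n * n_noise), n)
  X <- cbind(f1, f2, noise)
  colnames(X) <- c("SBP-dTTm-d", "SBP-dTTsd-u",
                   paste0("noise", seq_len(n_noise)))
  list(features = X, groups = g)
}

# full-enumeration two-sided Mann-Whitney oracle (no ties assumed)
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  u_from <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  obs <- u_from(seq_len(nx))
  us <- combn(length(pooled), nx, u_from)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# random rigid motion applied to a two-column point matrix
rigid_motion <- function(p, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  sweep(p %*% t(R), 2, shift, "+")
}
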