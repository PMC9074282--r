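## Independent brute-force oracles, deliberately implemented through paths
## disjoint from the package internals (explicit hat matrices, explicit
## loops), plus small fixture builders shared across test files.

## sequential ANOVA by explicit cumulative projection matrices
oracle_anova <- function(Y, data, terms) {
  for (v in unique(unlist(strsplit(terms, ":", fixed = TRUE))))
    data[[v]] <- factor(data[[v]])
  hat <- function(X) X %*% MASS::ginv(crossprod(X)) %*% t(X)
  n <- nrow(Y)
  H_prev <- matrix(1 / n, n, n)
  ss <- list(); df <- numeric(0)
  for (k in seq_along(terms)) {
    X <- model.matrix(stats::terms(stats::reformulate(terms[1:k]),
                                   keep.order = TRUE), data)
    Hk <- hat(X)
    P <- Hk - H_prev
    ss[[terms[k]]] <- colSums((P %*% Y) * Y)
    df[terms[k]] <- round(sum(diag(P)))
    H_prev <- Hk
  }
  resid_ss <- colSums(((diag(n) - H_prev) %*% Y) * Y)
  list(ss = ss, df = df, resid_ss = resid_ss,
       resid_df = n - round(sum(diag(H_prev))) )
}

## sleep-bout detection by an explicit per-minute loop
oracle_sleep_runs <- function(x, min_bout = 5) {
  starts <- integer(0); ends <- integer(0)
  run <- 0L
  for (i in seq_along(x)) {
    if (x[i] == 0) {
      run <- run + 1L
    } else {
      if (run >= min_bout) {
        starts <- c(starts, i - run); ends <- c(ends, i)
      }
      run <- 0L
    }
  }
  if (run >= min_bout) {
    starts <- c(starts, length(x) - run + 1L)
    ends <- c(ends, length(x) + 1L)
  }
  data.frame(start = starts, end = ends)
}

## small balanced study with direct control of the random draws
tiny_study <- function(n_lines = 4, n_transcripts = 3, seed = 1,
                       sd_line = 0.5, sd_treatline = 0.4, sd_resid = 0.6,
                       frac_lxt = 1, wolbachia_frac = 0.5) {
  simulate_expression(sim_design(
    n_lines = n_lines, n_transcripts = n_transcripts, n_replicates = 2,
    sd_line = sd_line, sd_sexline = 0.3, sd_treatline = sd_treatline,
    sd_sextreatline = 0.2, sd_resid = sd_resid, frac_lxt = frac_lxt,
    wolbachia_frac = wolbachia_frac, seed = seed))
}

## igraph builders for MCODE fixtures
clique_graph <- function(n, prefix = "v") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}
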