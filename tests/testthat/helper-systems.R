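# shared toy systems and small oracles used across test files

# random, dense-enough strongly connected transition matrix
rand_chain <- function(n, seed, density = 0.3) {
  set.seed(seed)
  repeat {
    P <- matrix(stats::rexp(n * n) * (matrix(stats::runif(n * n), n, n) < density),
                n, n)
    diag(P) <- diag(P) + 0.5
    P <- P / rowSums(P)
    g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
    if (igraph::components(g, mode = "strong")$no == 1L) return(P)
  }
}

# symmetric birth-death walk on 1..n with reflecting self-loops at the ends
gambler_chain <- function(n = 11) {
  P <- matrix(0, n, n)
  for (i in 2:(n - 1)) { P[i, i - 1] <- 0.5; P[i, i + 1] <- 0.5 }
  P[1, 1] <- 0.5; P[1, 2] <- 0.5
  P[n, n] <- 0.5; P[n, n - 1] <- 0.5
  P
}

# wrap a dense count matrix as the package's count_matrix class
as_counts <- function(M, lag = 1L) {
  structure(list(C = Matrix::Matrix(M, sparse = TRUE), lag = as.integer(lag),
                 pseudocount_mass = 0), class = "count_matrix")
}

# model object straight from a known transition matrix (for oracle tests)
model_from_P <- function(P, lag = 1L) {
  structure(list(T = P, pi = chain_stationary(P), lag = as.integer(lag),
                 states = seq_len(nrow(P)), dropped = integer(0)),
            class = "markov_model")
}

# adjusted Rand index between two labelings (independent re-implementation)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ind <- si * sj / n2
  (sij - exp_ind) / ((si + sj) / 2 - exp_ind)
}
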