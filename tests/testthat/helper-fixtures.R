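# Noiseless RUV-III model instance: Y = 1 mu + M X beta + W alpha, with
# beta = 0 on the control genes and W exactly mean-centered (W perp 1).
# Returns the pieces needed to check exact recovery.
make_noiseless <- function(m1 = 4L, reps_per = 2L, n = 30L, n_ctl = 10L,
                           k_true = 1L, seed = 1L) {
  set.seed(seed)
  m <- m1 * reps_per
  replicates <- rep(paste0("s", seq_len(m1)), each = reps_per)
  M <- build_mapping_matrix(replicates)
  mu <- rnorm(n, 5, 1)
  p <- 2L
  X <- diag(p)[rep(seq_len(p), length.out = m1), , drop = FALSE]
  beta <- matrix(rnorm(p * n), p, n)
  ctl <- seq_len(n_ctl)
  beta[, ctl] <- 0
  W <- matrix(rnorm(m * k_true), m, k_true)
  W <- scale(W, scale = FALSE)               # W perp 1
  alpha <- matrix(rnorm(k_true * n), k_true, n)
  clean <- matrix(mu, m, n, byrow = TRUE) + M %*% X %*% beta
  Y <- clean + W %*% alpha
  dimnames(Y) <- list(paste0("a", seq_len(m)), paste0("g", seq_len(n)))
  dimnames(clean) <- dimnames(Y)
  list(Y = Y, clean = clean, replicates = replicates, ctl = ctl,
       W = W, alpha = alpha, M = M, k_true = k_true)
}

# Random expression matrix with a replicate structure (some samples
# duplicated), for property-style checks.
random_replicated <- function(m1 = 4L, dup = 2L, n = 10L, seed = 1L) {
  set.seed(seed)
  replicates <- c(rep(paste0("s", seq_len(dup)), each = 2L),
                  paste0("s", seq(dup + 1L, m1)))
  m <- length(replicates)
  Y <- matrix(rnorm(m * n), m, n,
              dimnames = list(paste0("a", seq_len(m)), paste0("g", seq_len(n))))
  list(Y = Y, replicates = replicates)
}
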