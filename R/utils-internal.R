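# Internal helpers shared across modules. Nothing here is exported.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed means "use the current stream".
seeded <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# All n! permutations of 1..n as an (n! x n) integer matrix. Only sensible for
# n <= 9 (the exact-test path); callers guard the size.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 10)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- nrow(sub)
    out[row:(row + block - 1L), 1L] <- k
    rest <- seq_len(n)[-k]
    out[row:(row + block - 1L), -1L] <- matrix(rest[sub], block, n - 1L)
    row <- row + block
  }
  out
}

# Spearman rho with midrank ties.
spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# Two-sided Spearman test: exact permutation enumeration for n <= exact_max
# (valid under ties), t-approximation otherwise.
spearman_test <- function(x, y, exact_max = 9L) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 paired observations")
  rho <- spearman_rho(x, y)
  if (is.na(rho)) {
    return(list(rho = NA_real_, p = NA_real_, method = "undefined (constant input)"))
  }
  if (n <= exact_max) {
    rx <- rank(x)
    ry <- rank(y)
    perms <- all_permutations(n)
    # rho for each permutation of ry against fixed rx, via the product-moment
    # identity on ranks (mean/sd of a permuted rank vector are unchanged)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    sums <- matrix(ryc[perms], nrow(perms), n) %*% rxc
    rho_perm <- as.vector(sums) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact permutation")
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    list(rho = rho, p = min(1, p), method = "t approximation")
  }
}

lower_tri <- function(m) m[lower.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", name))
  }
  invisible(x)
}
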