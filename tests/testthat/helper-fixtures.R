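# small fixtures and independent oracles shared across test files

# tibble with item columns hl1..hlk from a persons x items matrix
make_resp <- function(mat) {
  mat <- as.matrix(mat)
  colnames(mat) <- paste0("hl", seq_len(ncol(mat)))
  tibble::as_tibble(mat)
}

# generator config with no social gradient (pure N(0, sd) trait)
null_config <- function(n, ...) {
  sim_config(n_persons = n,
             gradient = c(sex = 0, age = 0, education = 0, status = 0,
                          findep = 0),
             ...)
}

# all complete category-count profiles (nVD, nD, nE, nVE) summing to k
count_profiles <- function(k = 12) {
  grid <- expand.grid(n1 = 0:k, n2 = 0:k, n3 = 0:k)
  grid <- grid[rowSums(grid) <= k, ]
  grid$n4 <- k - rowSums(grid)
  as.matrix(grid[, c("n1", "n2", "n3", "n4")])
}

# independent brute-force coding of the type D level rule text, applied to
# one complete count profile (counts of codes 1..4 over k items)
oracle_level_d <- function(counts, k = 12) {
  p_ve <- 100 * counts[4] / k
  p_e <- 100 * counts[3] / k
  p_diff <- 100 * (counts[1] + counts[2]) / k
  if (p_ve >= 50 && p_diff < 8.334) return("excellent")
  if (p_ve + p_e > 83.33) return("sufficient")
  if (p_ve < 8.334 && p_diff >= 50) return("inadequate")
  "problematic"
}

# expand a count profile into one response row (order is irrelevant for
# scoring and level assignment)
profile_row <- function(counts) {
  make_resp(matrix(rep(1:4, times = counts), nrow = 1))
}

# brute-force ESF oracle: enumerate all binary response patterns
esf_brute <- function(eps) {
  k <- length(eps)
  g <- numeric(k + 1)
  for (code in 0:(2^k - 1)) {
    x <- as.integer(intToBits(code))[1:k]
    g[sum(x) + 1] <- g[sum(x) + 1] + prod(eps^x)
  }
  g
}

# brute-force well-conditioned check: enumerate all ordered partitions
well_conditioned_brute <- function(x) {
  k <- ncol(x)
  for (code in 1:(2^k - 2)) {
    s1 <- which(as.integer(intToBits(code))[1:k] == 1)
    s2 <- setdiff(seq_len(k), s1)
    found <- FALSE
    for (i in s1) for (j in s2) {
      if (any(!is.na(x[, i]) & !is.na(x[, j]) & x[, i] == 1 & x[, j] == 0)) {
        found <- TRUE
        break
      }
    }
    if (!found) return(FALSE)
  }
  TRUE
}
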