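# Independent brute-force reference implementations used as oracles.
# Deliberately written with plain nested loops and no shared code with the
# package internals.

brute_ifs <- function(symbols, K, alpha) {
  L <- length(symbols)
  I <- matrix(0, L, 2)
  prev <- c(0, 0)
  for (t in seq_len(L)) {
    k <- symbols[t]
    prev <- alpha * prev + c(cos(2 * pi * k / K), sin(2 * pi * k / K))
    I[t, ] <- prev
  }
  I
}

# times whose trailing history matches `pattern` (current state first)
brute_cluster_times <- function(symbols, pattern) {
  N <- length(pattern)
  L <- length(symbols)
  if (N == 0) return(seq_len(L))
  times <- integer(0)
  for (t in seq_len(L)) {
    if (t < N) next
    ok <- TRUE
    for (j in seq_len(N)) {
      if (symbols[t - j + 1] != pattern[j]) { ok <- FALSE; break }
    }
    if (ok) times <- c(times, t)
  }
  times
}

brute_hrqa <- function(symbols, K, alpha, pattern, B = 10,
                       hrr = "squared", addresses = NULL) {
  if (is.null(addresses)) addresses <- brute_ifs(symbols, K, alpha)
  N <- length(pattern)
  L <- length(symbols)
  times <- brute_cluster_times(symbols, pattern)
  m <- length(times)
  out <- c(HRR = 0, HMean = 0, HVar = 0, HSkew = 0, HKurtosis = 0,
           HENT = 0, HGini = 0)
  if (m == 0) return(out)
  out["HRR"] <- switch(hrr, squared = m^2 / L^2, as_printed = m / L^2,
                       proportion = m / L)
  if (m == 1) return(out)
  d <- numeric(0)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      dx <- addresses[times[i], 1] - addresses[times[j], 1]
      dy <- addresses[times[i], 2] - addresses[times[j], 2]
      d <- c(d, sqrt(dx^2 + dy^2) / alpha^N)
    }
  }
  np <- length(d)
  mu <- sum(d) / np
  v <- sum((d - mu)^2) / np
  out["HMean"] <- mu
  out["HVar"] <- v
  if (v > 0) {
    out["HSkew"] <- sum((d - mu)^3) / (np * v^1.5)
    out["HKurtosis"] <- sum((d - mu)^4) / (np * v^2)
  }
  maxd <- max(d)
  if (maxd == 0) {
    pr <- 1
  } else {
    cnt <- numeric(B)
    for (x in d) {
      b <- ceiling(x * B / maxd)
      if (b < 1) b <- 1
      if (b > B) b <- B
      cnt[b] <- cnt[b] + 1
    }
    pr <- cnt / np
  }
  ent <- 0
  for (pb in pr) if (pb > 0) ent <- ent - pb * log(pb)
  out["HENT"] <- ent
  out["HGini"] <- 1 - sum(pr^2)
  out
}

brute_davies_bouldin <- function(points, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  cent <- list(); scat <- numeric(k)
  for (g in seq_len(k)) {
    sub <- points[labels == labs[g], , drop = FALSE]
    cent[[g]] <- colMeans(sub)
    s <- 0
    for (i in seq_len(nrow(sub)))
      s <- s + sqrt(sum((sub[i, ] - cent[[g]])^2))
    scat[g] <- s / nrow(sub)
  }
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      r <- (scat[i] + scat[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
      if (r > worst) worst <- r
    }
    total <- total + worst
  }
  total / k
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

rand_symbols <- function(L, K) sample.int(K, L, replace = TRUE)
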