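# Independent oracles used to check the package implementation. These are
# written against first principles (brute force, enumeration, closed forms)
# and never call the code paths they verify.

KB <- 0.0019872041

# --- quaternion-based Kabsch (Horn eigen method), independent of the SVD
# implementation in the package
oracle_kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  fitted <- sweep(A %*% t(R), 2, -cr)
  list(R = R, fitted = fitted,
       rmsd = sqrt(mean(rowSums((fitted - ref)^2))))
}

rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2)); a <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# --- brute-force O(N*M) cross-selection scans
oracle_min_distance <- function(xyz, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < best) best <- d
  }
  best
}

oracle_contact_pairs <- function(xyz, ia, ib, cutoff) {
  out <- list()
  for (i in ia) for (j in ib) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff)
      out[[length(out) + 1]] <- c(i, j)
  }
  if (length(out) == 0) matrix(integer(), 0, 2) else do.call(rbind, out)
}

# --- closed-form binding free energy on a reference profile by fine
# quadrature of exp(-G/kT) (independent of the package's trapezoid path)
oracle_dg <- function(pmf, threshold, lower, upper, kT = KB * 300,
                      dx = 5e-4) {
  f <- function(a, b) {
    xs <- seq(a, b, by = dx)
    r <- exp(-dnacoop::pmf_eval(pmf, xs) / kT)
    sum((head(r, -1) + tail(r, -1)) / 2) * dx
  }
  -kT * log(f(lower, threshold) / f(threshold, upper))
}

# --- MBAR-style self-consistent estimator of window free energies (no
# histogram), cross-check for the WHAM offsets
oracle_mbar_f <- function(dataset, subsample = 10L, tol = 1e-8,
                          max_iter = 5000L) {
  w <- dataset$windows
  kT <- dataset$thermo$kT
  xs <- lapply(w$samples, function(s) s[seq(1, length(s), by = subsample)])
  x <- unlist(xs)
  N <- vapply(xs, length, integer(1))
  K <- nrow(w)
  u <- vapply(seq_len(K), function(i) w$k[i] * (x - w$center[i])^2 / kT,
              numeric(length(x)))
  f <- rep(0, K)
  for (it in seq_len(max_iter)) {
    lw <- sweep(-u, 2, f, "+")               # log(exp(f_j - u_j))
    m <- apply(lw, 1, max)
    denom <- m + log(rowSums(exp(lw - m) * rep(N, each = length(x))))
    fnew <- vapply(seq_len(K), function(i) {
      v <- -u[, i] - denom
      mv <- max(v)
      -(mv + log(sum(exp(v - mv))))
    }, numeric(1))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  f * kT
}

# --- exhaustive simple-path enumeration on a small weighted graph
oracle_all_paths <- function(edges, source, target) {
  adj <- list()
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]; w <- edges$weight[r]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, w = w))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, w = w))
  }
  res <- list()
  walk <- function(node, path, len) {
    if (node == target) {
      res[[length(res) + 1]] <<- list(path = path, length = len)
      return(invisible())
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      if (nb$to[r] %in% path) next
      walk(nb$to[r], c(path, nb$to[r]), len + nb$w[r])
    }
  }
  walk(source, source, 0)
  res
}

# --- brute-force best 2-partition modularity (unweighted)
oracle_best_2partition <- function(edges, ids) {
  m <- nrow(edges)
  deg <- setNames(rep(0, length(ids)), ids)
  for (r in seq_len(m)) {
    deg[edges$from[r]] <- deg[edges$from[r]] + 1
    deg[edges$to[r]] <- deg[edges$to[r]] + 1
  }
  modularity_of <- function(mem) {
    q <- 0
    for (r in seq_len(m))
      if (mem[edges$from[r]] == mem[edges$to[r]]) q <- q + 1 / m
    for (cc in unique(mem)) {
      s <- sum(deg[names(mem)[mem == cc]]) / (2 * m)
      q <- q - s^2
    }
    q
  }
  best <- -Inf; best_mem <- NULL
  n <- length(ids)
  for (mask in 0:(2^(n - 1) - 1)) {
    mem <- setNames(c(0, as.integer(intToBits(mask))[seq_len(n - 1)]), ids)
    q <- modularity_of(mem)
    if (q > best) { best <- q; best_mem <- mem }
  }
  list(modularity = best, membership = best_mem)
}

# --- AR(1) series with known SE of the mean
gen_ar1 <- function(n, phi, sd_innov = 1) {
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd_innov / sqrt(1 - phi^2))
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1, sd = sd_innov)
  x
}
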