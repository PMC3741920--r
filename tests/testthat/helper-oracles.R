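# Independent oracles used to cross-check the package implementations.
# These are written as direct, brute-force transcriptions and must not
# share code with the implementations they verify.

# per-pixel four-direction run counter (runs exclude the pixel itself)
bruteDirectionMap <- function(A) {
  nx <- nrow(A); ny <- ncol(A)
  H <- matrix(0, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    if (A[x, y] == 0) next
    runs <- numeric(4)
    i <- x - 1; while (i >= 1 && A[i, y] == 1) { runs[1] <- runs[1] + 1; i <- i - 1 }
    i <- x + 1; while (i <= nx && A[i, y] == 1) { runs[2] <- runs[2] + 1; i <- i + 1 }
    j <- y - 1; while (j >= 1 && A[x, j] == 1) { runs[3] <- runs[3] + 1; j <- j - 1 }
    j <- y + 1; while (j <= ny && A[x, j] == 1) { runs[4] <- runs[4] + 1; j <- j + 1 }
    H[x, y] <- sum(sqrt(runs))
  }
  H
}

# recursive PIP detection, written top-down: vertical distance from the
# chord, recurse while the maximum exceeds T, then prune the flattest
# interior point while below theta_min
brutePips <- function(L, A, T, theta_min = 5 * pi / 180) {
  recur <- function(s, e) {
    if (e - s < 2) return(integer(0))
    mid <- (s + 1):(e - 1)
    denom <- L[e] - L[s]
    chord <- if (abs(denom) < 1e-12) rep(A[s], length(mid))
             else A[s] + (L[mid] - L[s]) * (A[e] - A[s]) / denom
    vd <- abs(A[mid] - chord)
    if (max(vd) <= T) return(integer(0))
    k <- mid[which.max(vd)]
    c(recur(s, k), k, recur(k, e))
  }
  pips <- sort(unique(c(1L, length(L), recur(1L, length(L)))))
  angleAt <- function(ids, i) {
    p0 <- c(L[ids[i - 1]], A[ids[i - 1]])
    p1 <- c(L[ids[i]], A[ids[i]])
    p2 <- c(L[ids[i + 1]], A[ids[i + 1]])
    a <- p1 - p0; b <- p2 - p1
    acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
  }
  repeat {
    if (length(pips) <= 2) break
    angs <- vapply(2:(length(pips) - 1), function(i) angleAt(pips, i), numeric(1))
    if (all(angs >= theta_min)) break
    pips <- pips[-(which.min(angs) + 1)]
  }
  pips
}

# AUC as the fraction of concordant positive/negative pairs, ties half
bruteAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  sp <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (p in sp) for (q in sn)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# random simple star-shaped polygon around the origin
randomStarPolygon <- function(n = 60, r0 = 50, amp = 0.4) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- r0 * (1 + runif(n, -amp, amp))
  cbind(r * cos(th), r * sin(th))
}

# filled-disk mask helper in the package's [x, y] convention
diskMask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  xy <- expand.grid(x = 1:n, y = 1:n)
  matrix(as.integer((xy$x - c0)^2 + (xy$y - c0)^2 <= r^2), n, n)
}

# small, quick phantom for unit tests
quickPhantomConfig <- function(...) {
  defaults <- list(lumen_radius = 90, n_lobes = 0, n_epithelial = 24,
                   n_stromal = 30, cytoplasm_offset_mean = 10, rng_seed = 1)
  do.call(phantomConfig, utils::modifyList(defaults, list(...)))
}
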